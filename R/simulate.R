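# Synthetic binned ChIP-like datasets with planted depletion, binomial
# read downsampling, and confusion-matrix benchmarking of a caller.

#' Specification of a synthetic binned dataset
#'
#' The generator emulates the structure of broad-histone-mark binned
#' counts: a uniform 10 kb grid on one synthetic chromosome, a genic
#' compartment, "covered" bins carrying signal versus low background, and
#' negative-binomial replicate counts with a shared per-bin mean. The
#' altered group starts from its own baseline draws and binomially thins
#' the counts of a chosen fraction of covered target-class bins, the
#' standard model of read downsampling. Defaults: a global one-sided loss
#' in which half of the covered intergenic bins are depleted to 30% of
#' their reads, mirroring knockouts that remove a broad mark from roughly
#' half of the signal-bearing genome.
#'
#' @param n_bins number of bins.
#' @param bin_width bin width in bp (default 10 kb).
#' @param genic_fraction fraction of bins classified genic.
#' @param covered_fraction fraction of bins carrying signal.
#' @param mean_covered,mean_background expected counts per bin.
#' @param dispersion negative-binomial dispersion (`size = 1/dispersion`).
#' @param replicates_per_group replicates in each group.
#' @param depletion_target `"intergenic_covered"` or `"genic_covered"`.
#' @param depletion_fraction fraction of covered target bins depleted, in
#'   `[0, 1]` (1 = every covered target bin, the global-loss scenario).
#' @param depletion_factor binomial keep-probability in `(0, 1)` for the
#'   depleted bins.
#' @param seed integer seed; the whole dataset is a pure function of the
#'   spec including the seed.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_bins = 50000L, bin_width = 10000L,
                            genic_fraction = 0.5, covered_fraction = 0.5,
                            mean_covered = 200, mean_background = 5,
                            dispersion = 0.1, replicates_per_group = 3L,
                            depletion_target = c("intergenic_covered",
                                                 "genic_covered"),
                            depletion_fraction = 0.5,
                            depletion_factor = 0.3, seed = 1L) {
  depletion_target <- match.arg(depletion_target)
  stopifnot(n_bins >= 10, genic_fraction > 0, genic_fraction < 1,
            covered_fraction > 0, covered_fraction < 1,
            depletion_fraction >= 0, depletion_fraction <= 1,
            depletion_factor > 0, depletion_factor < 1,
            mean_covered > 0, mean_background > 0, dispersion > 0,
            replicates_per_group >= 1)
  structure(as.list(environment()), class = "simulation_spec")
}

#' Simulate a two-group binned dataset with planted depletion
#'
#' @param spec a `simulation_spec`.
#' @return List with `original` and `altered` (both `track_set`s on the
#'   same grid) and `truth` (data frame with per-bin `status`
#'   depleted/invariant, `class` genic/intergenic, and `covered`).
#' @importFrom stats rnbinom rbinom
#' @export
simulate_trackset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_bins
  grid <- bin_grid(rep("chrS", n), (seq_len(n) - 1L) * spec$bin_width,
                   seq_len(n) * spec$bin_width, bin_width = spec$bin_width)
  genic <- seq_len(n) %in% sample(n, round(spec$genic_fraction * n))
  covered <- seq_len(n) %in% sample(n, round(spec$covered_fraction * n))
  target <- if (spec$depletion_target == "intergenic_covered")
    which(!genic & covered) else which(genic & covered)
  if (length(target) == 0) .stopf("depletion target class is empty")
  n_dep <- round(spec$depletion_fraction * length(target))
  depleted <- sort(sample(target, n_dep))
  mu <- ifelse(covered, spec$mean_covered, spec$mean_background)
  size <- 1 / spec$dispersion
  reps <- spec$replicates_per_group
  draw <- function() matrix(stats::rnbinom(n * reps, mu = mu, size = size),
                            nrow = n, ncol = reps)
  orig <- draw()
  alt <- draw()
  for (j in seq_len(reps))
    alt[depleted, j] <- stats::rbinom(length(depleted),
                                      size = alt[depleted, j],
                                      prob = spec$depletion_factor)
  mk <- function(counts, cond) {
    tracks <- lapply(seq_len(reps), function(j)
      .new_sample_track(grid, counts[, j], sprintf("%s_rep%d", cond, j),
                        condition = cond, replicate = as.character(j)))
    align_trackset(tracks)
  }
  truth <- data.frame(
    chrom = grid$chrom, start = grid$start, end = grid$end,
    status = ifelse(seq_len(n) %in% depleted, "depleted", "invariant"),
    class = ifelse(genic, "genic", "intergenic"),
    covered = covered, stringsAsFactors = FALSE)
  list(original = mk(orig, "original"), altered = mk(alt, "altered"),
       truth = truth)
}

#' Binomially downsample counts in selected bins
#'
#' Replaces the counts of the target bins by `Binomial(count, factor)`
#' draws in every sample; other bins are untouched. `factor = 1` is an
#' exact identity. This reproduces, on any real or synthetic track set,
#' the operation used to plant known depletions.
#'
#' @param ts a `track_set` of integer raw counts.
#' @param target_bins integer indices of bins to thin.
#' @param factor keep-probability in `(0, 1]`.
#' @param seed RNG seed.
#' @export
downsample_regions <- function(ts, target_bins, factor, seed = 1L) {
  stopifnot(inherits(ts, "track_set"), factor > 0, factor <= 1)
  if (factor == 1) return(ts)
  set.seed(seed)
  counts <- ts$counts
  if (any(counts[target_bins, ] != round(counts[target_bins, ])))
    .stopf("downsampling needs integer raw counts")
  for (j in seq_len(ncol(counts)))
    counts[target_bins, j] <- stats::rbinom(length(target_bins),
                                            size = counts[target_bins, j],
                                            prob = factor)
  ts$counts <- counts
  ts
}

#' Confusion counts of a differential-binding caller
#'
#' Scores calls against planted truth: TP are truly depleted bins called
#' significant with negative logFC; FP are significant calls on invariant
#' bins (either direction) plus truly depleted bins called upregulated; TN
#' are invariant bins not called; FN are depleted bins not called.
#'
#' @param calls a `rots_db` (or data frame with `fdr` and `logfc`).
#' @param truth the truth table from [simulate_trackset()], or any data
#'   frame with a `status` column, on the same bins in the same order.
#' @param fdr_cutoff significance threshold (default 0.05).
#' @return Object of class `confusion_counts` (list TP/FP/TN/FN).
#' @export
confusion_counts <- function(calls, truth, fdr_cutoff = 0.05) {
  if (nrow(calls) != nrow(truth))
    .stopf("calls cover %d bins but truth covers %d", nrow(calls), nrow(truth))
  dep <- truth$status == "depleted"
  sig <- calls$fdr < fdr_cutoff
  down <- sig & calls$logfc < 0
  up <- sig & calls$logfc > 0
  out <- list(TP = sum(dep & down),
              FP = sum((!dep & sig) | (dep & up)),
              TN = sum(!dep & !sig),
              FN = sum(dep & !sig))
  structure(out, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Benchmark metrics from confusion counts
#'
#' `precision = TP/(TP+FP)`, `specificity = TN/(TN+FP)`,
#' `sensitivity = TP/(TP+FN)`,
#' `F1 = 2 * precision * sensitivity / (precision + sensitivity)`.
#' A metric with zero denominator is reported as `NA` with a warning.
#'
#' @param c a `confusion_counts` object.
#' @return Named numeric vector (precision, specificity, sensitivity, f1).
#' @export
benchmark_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$TP + c$FP + c$TN + c$FN == 0) {
    .warnf("empty confusion table: all metrics undefined")
    return(c(precision = NA_real_, specificity = NA_real_,
             sensitivity = NA_real_, f1 = NA_real_))
  }
  div <- function(num, den) if (den > 0) num / den else {
    .warnf("metric undefined (zero denominator)"); NA_real_ }
  precision <- div(c$TP, c$TP + c$FP)
  specificity <- div(c$TN, c$TN + c$FP)
  sensitivity <- div(c$TP, c$TP + c$FN)
  f1 <- if (!is.na(precision) && !is.na(sensitivity) &&
            precision + sensitivity > 0)
    2 * precision * sensitivity / (precision + sensitivity) else NA_real_
  c(precision = precision, specificity = specificity,
    sensitivity = sensitivity, f1 = f1)
}

#' F1 score from a precision/sensitivity pair
#'
#' `F1 = 2 p s / (p + s)`, the harmonic mean used to summarize a caller's
#' precision and sensitivity (recall).
#'
#' @param precision,sensitivity values in `[0, 1]`.
#' @export
f1_score <- function(precision, sensitivity) {
  stopifnot(precision >= 0, precision <= 1,
            sensitivity >= 0, sensitivity <= 1)
  if (precision + sensitivity == 0) return(NA_real_)
  2 * precision * sensitivity / (precision + sensitivity)
}

#' End-to-end simulation benchmark under two normalizations
#'
#' Simulates a planted-depletion dataset, runs the full pipeline
#' (low-count filter, normalization, log2 transform, differential binding)
#' once with library-size-only normalization and once with TMM effective
#' library sizes, and scores both against the planted truth. The two-column
#' comparison of down/up call counts and metrics reflects how composition
#' normalization behaves when a genuine global one-sided loss is present.
#'
#' @param spec a `simulation_spec`.
#' @param fdr_cutoff significance threshold.
#' @param B,n_perm,a1_grid,k_grid differential-binding settings, see
#'   [run_differential()].
#' @param seed seed for the differential analysis (the simulation uses the
#'   spec's own seed).
#' @return Object of class `benchmark_report`: per-normalization confusion
#'   counts, metrics and call counts, plus the surviving-bin count.
#' @export
benchmark_run <- function(spec, fdr_cutoff = 0.05, B = 100L, n_perm = 100L,
                          a1_grid = .default_a1_grid, k_grid = NULL,
                          seed = 1L) {
  sim <- simulate_trackset(spec)
  all_tracks <- c(
    lapply(seq_len(ncol(sim$original$counts)), function(j)
      .new_sample_track(sim$original$grid, sim$original$counts[, j],
                        sim$original$samples$sample_id[j],
                        condition = "original",
                        replicate = sim$original$samples$replicate[j])),
    lapply(seq_len(ncol(sim$altered$counts)), function(j)
      .new_sample_track(sim$altered$grid, sim$altered$counts[, j],
                        sim$altered$samples$sample_id[j],
                        condition = "altered",
                        replicate = sim$altered$samples$replicate[j])))
  ts <- align_trackset(all_tracks)
  keep <- rowSums(ts$counts) >= 1
  ts <- filter_low_count(ts, 1)
  truth <- sim$truth[keep, , drop = FALSE]
  res <- list()
  for (method in c("library", "tmm")) {
    tracks <- normalize_trackset(ts, method)
    logs <- lapply(tracks, log_transform)
    fit <- run_differential(signal_matrix(logs), control = "original",
                            B = B, n_perm = n_perm, a1_grid = a1_grid,
                            k_grid = k_grid, fdr_cutoff = fdr_cutoff,
                            seed = seed)
    cc <- confusion_counts(fit, truth, fdr_cutoff)
    res[[method]] <- list(fit = fit, confusion = cc,
                          metrics = benchmark_metrics(cc),
                          n_down = sum(fit$direction == "down"),
                          n_up = sum(fit$direction == "up"))
  }
  structure(list(spec = spec, truth = truth, n_bins_evaluated = sum(keep),
                 library = res$library, tmm = res$tmm),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("benchmark on %d evaluated bins (%d depleted)\n",
              x$n_bins_evaluated, sum(x$truth$status == "depleted")))
  tab <- rbind(
    library = c(x$library$n_down, x$library$n_up,
                round(x$library$metrics, 3)),
    tmm = c(x$tmm$n_down, x$tmm$n_up, round(x$tmm$metrics, 3)))
  colnames(tab)[1:2] <- c("down", "up")
  print(tab)
  invisible(x)
}

#' Write a benchmark report as TSV
#'
#' @param report a `benchmark_report`.
#' @param path output path.
#' @export
write_benchmark_tsv <- function(report, path) {
  rows <- do.call(rbind, lapply(c("library", "tmm"), function(m) {
    r <- report[[m]]
    data.frame(normalization = m, TP = r$confusion$TP, FP = r$confusion$FP,
               TN = r$confusion$TN, FN = r$confusion$FN,
               down = r$n_down, up = r$n_up,
               precision = r$metrics["precision"],
               specificity = r$metrics["specificity"],
               sensitivity = r$metrics["sensitivity"],
               f1 = r$metrics["f1"], stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
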