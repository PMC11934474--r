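# normalization of raw binned counts: depth scaling, input correction,
# median-ratio / TMM factors, quantitative (spike-in / mass-spec) scaling

.new_norm_track <- function(grid, values, sample_id, space = "linear",
                            pseudocount = NA_real_,
                            condition = NA_character_,
                            replicate = NA_character_) {
  stopifnot(length(values) == length(grid))
  if (any(!is.finite(values))) .stopf("non-finite values in track '%s'", sample_id)
  structure(list(grid = grid, values = as.numeric(values),
                 sample_id = sample_id, space = space,
                 pseudocount = pseudocount, condition = condition,
                 replicate = replicate),
            class = "norm_track")
}

#' @export
print.norm_track <- function(x, ...) {
  cat(sprintf("norm_track '%s': %d bins, %s space\n", x$sample_id,
              length(x$grid), x$space))
  invisible(x)
}

#' Library-size (counts-per-million) normalization
#'
#' Scales each sample to counts per million over the grid bins:
#' `value_ij = count_ij / library_size_j * 1e6`. This is the default
#' normalization of the workflow: cross-sample composition corrections
#' (median-ratio, TMM) assume most bins are unchanged, an assumption broken
#' by global losses of broad histone marks, and may reduce the power to
#' detect genuine changes.
#'
#' @param ts a `track_set` of raw counts.
#' @return List of linear-space `norm_track`s, one per sample, with the
#'   library sizes attached as attribute `library_sizes`.
#' @export
library_size_normalize <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  lib <- colSums(ts$counts)
  if (any(lib <= 0))
    .stopf("zero library size for sample '%s'",
           ts$samples$sample_id[which(lib <= 0)[1]])
  out <- lapply(seq_len(ncol(ts$counts)), function(j) {
    .new_norm_track(ts$grid, ts$counts[, j] / lib[j] * 1e6,
                    ts$samples$sample_id[j],
                    condition = ts$samples$condition[j],
                    replicate = ts$samples$replicate[j])
  })
  names(out) <- ts$samples$sample_id
  attr(out, "library_sizes") <- lib
  out
}

#' Correct ChIP signal for input background
#'
#' Ratio mode (default) returns `log2((chip + c) / (input + c))` in log2
#' space; subtract mode returns `max(chip - input, 0)` in linear space.
#' Both tracks must be depth-normalized, linear-space, and on the same grid.
#'
#' @param chip,input linear-space `norm_track`s on the same grid.
#' @param mode `"ratio"` or `"subtract"`.
#' @param pseudocount stabilizing constant for ratio mode (default 0.5).
#' @export
input_correct <- function(chip, input, mode = c("ratio", "subtract"),
                          pseudocount = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(chip, "norm_track"), inherits(input, "norm_track"))
  if (!.grids_identical(chip$grid, input$grid))
    .stopf("input_correct: chip and input are on different grids")
  if (chip$space != "linear" || input$space != "linear")
    .stopf("input_correct expects linear-space tracks")
  if (mode == "ratio") {
    v <- log2((chip$values + pseudocount) / (input$values + pseudocount))
    .new_norm_track(chip$grid, v, chip$sample_id, space = "log2",
                    pseudocount = pseudocount, condition = chip$condition,
                    replicate = chip$replicate)
  } else {
    v <- pmax(chip$values - input$values, 0)
    .new_norm_track(chip$grid, v, chip$sample_id, space = "linear",
                    condition = chip$condition, replicate = chip$replicate)
  }
}

#' Median-ratio size factors
#'
#' Per-sample size factors as the median, over bins where all samples have
#' positive counts, of the ratio of the bin count to the bin's geometric
#' mean across samples. Dividing raw counts by these factors equalizes the
#' bulk of the count distribution across samples.
#'
#' @param counts bins-by-samples numeric matrix of raw counts.
#' @return Object of class `normalization_factors`: a data frame with
#'   `sample_id`, `library_size` and `size_factor` (geometric mean 1 is not
#'   imposed; the factors are the plain median ratios).
#' @export
median_ratio_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) .stopf("median-ratio factors need at least 2 samples")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    .stopf("no bin has positive counts in every sample; filter low-count bins first")
  loggeo <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(cnt)
    exp(stats::median(log(cnt) - loggeo)))
  out <- data.frame(sample_id = colnames(counts) %||%
                      paste0("sample", seq_len(ncol(counts))),
                    library_size = colSums(counts),
                    size_factor = as.numeric(sf),
                    stringsAsFactors = FALSE)
  structure(out, class = c("normalization_factors", "data.frame"),
            method = "median_ratio")
}

#' Trimmed mean of M-values (TMM) factors
#'
#' Composition-normalization factors computed from doubly trimmed,
#' precision-weighted log-ratios against a reference sample. The reference
#' (when not given) is the sample whose 75th-percentile count fraction is
#' closest to the mean of those across samples. For sample `k` versus
#' reference `r`, over bins with positive counts in both,
#' `M = log2((y_k/N_k)/(y_r/N_r))` and `A = (1/2) log2((y_k/N_k)(y_r/N_r))`;
#' the top and bottom `trim_m` by M and `trim_a` by A are dropped and the
#' factor is `2^(sum(w M)/sum(w))` with binomial precision weights
#' `w = (N_k - y_k)/(N_k y_k) + (N_r - y_r)/(N_r y_r)`. Factors are rescaled
#' to geometric mean 1; effective library sizes are `N_k * factor_k`.
#'
#' @param counts bins-by-samples matrix of raw counts.
#' @param ref_sample optional reference column name or index.
#' @param trim_m,trim_a two-sided trim fractions on M and A (defaults 0.3
#'   and 0.05, the canonical values).
#' @return `normalization_factors` data frame with `tmm_factor` and
#'   `effective_library_size` columns.
#' @export
tmm_factors <- function(counts, ref_sample = NULL, trim_m = 0.3,
                        trim_a = 0.05) {
  counts <- as.matrix(counts)
  m <- ncol(counts)
  if (m < 2) .stopf("TMM needs at least 2 samples")
  N <- colSums(counts)
  if (any(N <= 0)) .stopf("zero library size")
  if (is.null(ref_sample)) {
    f75 <- apply(counts, 2, function(y) stats::quantile(y / sum(y), 0.75))
    ref <- which.min(abs(f75 - mean(f75)))
  } else {
    ref <- if (is.character(ref_sample)) match(ref_sample, colnames(counts))
           else as.integer(ref_sample)
    if (is.na(ref) || ref < 1 || ref > m) .stopf("unknown reference sample")
  }
  yr <- counts[, ref]
  f <- numeric(m)
  for (k in seq_len(m)) {
    if (k == ref) { f[k] <- 1; next }
    yk <- counts[, k]
    use <- yk > 0 & yr > 0
    y1 <- yk[use]; y2 <- yr[use]
    M <- log2((y1 / N[k]) / (y2 / N[ref]))
    A <- 0.5 * log2((y1 / N[k]) * (y2 / N[ref]))
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (sum(keep) < 10)
      .stopf("fewer than 10 bins survive TMM trimming; use median-ratio or library-size normalization")
    w <- (N[k] - y1[keep]) / (N[k] * y1[keep]) +
         (N[ref] - y2[keep]) / (N[ref] * y2[keep])
    f[k] <- 2^(sum(w * M[keep]) / sum(w))
  }
  f <- f / .geometric_mean(f)
  out <- data.frame(sample_id = colnames(counts) %||%
                      paste0("sample", seq_len(m)),
                    library_size = N,
                    tmm_factor = f,
                    effective_library_size = N * f,
                    stringsAsFactors = FALSE)
  structure(out, class = c("normalization_factors", "data.frame"),
            method = "tmm", ref_sample = ref)
}

#' Normalize a track set by a chosen method
#'
#' Convenience wrapper producing per-sample linear-space tracks:
#' `"library"` gives counts per million; `"median_ratio"` divides raw counts
#' by median-ratio size factors; `"tmm"` gives counts per million computed
#' on TMM effective library sizes.
#'
#' @param ts a `track_set` of raw counts.
#' @param method normalization mode.
#' @return List of `norm_track`s with a `factors` attribute (a
#'   `normalization_factors` data frame for the factor-based modes).
#' @export
normalize_trackset <- function(ts, method = c("library", "median_ratio", "tmm")) {
  method <- match.arg(method)
  if (method == "library") return(library_size_normalize(ts))
  if (method == "median_ratio") {
    nf <- median_ratio_factors(ts$counts)
    out <- lapply(seq_len(ncol(ts$counts)), function(j)
      .new_norm_track(ts$grid, ts$counts[, j] / nf$size_factor[j],
                      ts$samples$sample_id[j],
                      condition = ts$samples$condition[j],
                      replicate = ts$samples$replicate[j]))
  } else {
    nf <- tmm_factors(ts$counts)
    out <- lapply(seq_len(ncol(ts$counts)), function(j)
      .new_norm_track(ts$grid,
                      ts$counts[, j] / nf$effective_library_size[j] * 1e6,
                      ts$samples$sample_id[j],
                      condition = ts$samples$condition[j],
                      replicate = ts$samples$replicate[j]))
  }
  names(out) <- ts$samples$sample_id
  attr(out, "factors") <- nf
  out
}

#' Quantitative scaling by spike-in reads or mass-spec percentage
#'
#' `"ms"` multiplies a depth-normalized track by the sample's genome-wide
#' modification percentage divided by 100, putting samples on a common
#' absolute scale when antibody efficiency or global modification levels
#' differ. `"chiprx"` multiplies by `1e6 / exogenous_mapped_reads`
#' (per-million of spike-in reads; the constant cancels in any two-sample
#' comparison).
#'
#' @param track linear-space, depth-normalized `norm_track`.
#' @param method `"chiprx"` or `"ms"`.
#' @param value exogenous mapped read count (chiprx) or genome-wide
#'   modification percentage (ms); must be positive.
#' @export
scale_quantitative <- function(track, method = c("chiprx", "ms"), value) {
  method <- match.arg(method)
  stopifnot(inherits(track, "norm_track"))
  if (track$space != "linear")
    .stopf("quantitative scaling applies to linear-space tracks")
  if (!is.numeric(value) || length(value) != 1 || value <= 0)
    .stopf("scale value must be a positive number")
  fac <- if (method == "ms") value / 100 else 1e6 / value
  .new_norm_track(track$grid, track$values * fac, track$sample_id,
                  condition = track$condition, replicate = track$replicate)
}

#' Log2-transform a linear-space track
#'
#' `value = log2(value + pseudocount)`; refuses to double-log.
#'
#' @param track linear-space `norm_track`.
#' @param pseudocount default 1 (on the counts-per-million scale).
#' @export
log_transform <- function(track, pseudocount = 1) {
  stopifnot(inherits(track, "norm_track"))
  if (track$space != "linear")
    .stopf("track '%s' is already in log2 space", track$sample_id)
  .new_norm_track(track$grid, log2(track$values + pseudocount),
                  track$sample_id, space = "log2", pseudocount = pseudocount,
                  condition = track$condition, replicate = track$replicate)
}

#' Write a normalization-factor report
#'
#' @param nf a `normalization_factors` data frame.
#' @param path output TSV path.
#' @export
write_factors_tsv <- function(nf, path) {
  utils::write.table(nf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
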