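# Reproducibility-optimized t-type differential binding.
#
# The per-bin statistic is d = |m| / (a1 + a2 * s), where m is the
# difference of group means (log2 signal) and s the pooled standard error.
# The pair (a1, a2) and the top-list size k are chosen to maximize the
# reproducibility Z-score: the overlap of top-k lists across bootstrap
# resamples that preserve the group structure, standardized against the
# same overlap under permuted group labels. Significance is assessed by a
# permutation FDR over distinct relabellings of the samples.

.group_mean_se <- function(X, cols1, cols2) {
  n1 <- length(cols1); n2 <- length(cols2)
  X1 <- X[, cols1, drop = FALSE]; X2 <- X[, cols2, drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- pmax(rowSums(X1 * X1) - n1 * m1 * m1, 0) / (n1 - 1)
  v2 <- pmax(rowSums(X2 * X2) - n2 * m2 * m2, 0) / (n2 - 1)
  s <- sqrt((1 / n1 + 1 / n2) * ((n1 - 1) * v1 + (n2 - 1) * v2) /
              (n1 + n2 - 2))
  list(m = m1 - m2, s = s)
}

.d_stat <- function(m, s, a1, a2) {
  num <- abs(m)
  den <- a1 + a2 * s
  d <- ifelse(den > 0, num / den, ifelse(num == 0, 0, Inf))
  as.numeric(d)
}

#' The t-type statistic for a given (a1, a2)
#'
#' `d = |mean(x1) - mean(x2)| / (a1 + a2 * s)` with `s` the pooled standard
#' error of the mean difference. `(a1, a2) = (0, 1)` gives the ordinary
#' absolute two-sample t statistic; `(1, 0)` gives the absolute mean
#' difference.
#'
#' @param x1,x2 bins-by-replicates matrices of log2 signal (>= 2 columns
#'   each).
#' @param a1,a2 non-negative statistic parameters, not both zero.
#' @return Numeric vector of per-bin statistics.
#' @export
rots_statistic <- function(x1, x2, a1, a2) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (ncol(x1) < 2 || ncol(x2) < 2)
    .stopf("the statistic needs at least two replicates per group")
  if (nrow(x1) != nrow(x2)) .stopf("x1 and x2 must cover the same bins")
  if (a1 < 0 || a2 < 0 || (a1 == 0 && a2 == 0))
    .stopf("(a1, a2) must be non-negative and not both zero")
  X <- cbind(x1, x2)
  st <- .group_mean_se(X, seq_len(ncol(x1)), ncol(x1) + seq_len(ncol(x2)))
  .d_stat(st$m, st$s, a1, a2)
}

# overlap of the top-k lists of two statistic vectors; ties resolved by bin
# order (radix order is stable)
.topk_overlap <- function(dA, dB, ks) {
  oA <- order(dA, decreasing = TRUE)
  oB <- order(dB, decreasing = TRUE)
  pos <- integer(length(dB))
  pos[oB] <- seq_along(oB)
  v <- pos[oA]
  vapply(ks, function(k) sum(v[seq_len(k)] <= k) / k, 0)
}

# one set of bootstrap-pair overlaps for a grid of alphas and k values.
# alphas: matrix with columns a1, a2. Returns R, R0 (mean overlap fraction,
# observed / permuted-label), S (sd of observed overlap fractions) and Z,
# each of dimension n_alpha x n_k.
.rots_overlap_table <- function(X, g1, g2, alphas, ks, B, seed) {
  n1 <- length(g1); n2 <- length(g2)
  cols <- c(g1, g2)
  na <- nrow(alphas); nk <- length(ks)
  # rankings with a2 = 0 do not depend on a1; collapse duplicates
  key <- ifelse(alphas[, 2] == 0, "m", sprintf("a%.10g", alphas[, 1]))
  ukey <- unique(key)
  ualpha <- alphas[match(ukey, key), , drop = FALSE]
  nu <- nrow(ualpha)
  obs <- array(0, c(nu, nk, B))
  nul <- array(0, c(nu, nk, B))
  set.seed(seed)
  for (b in seq_len(B)) {
    rA1 <- sample(g1, n1, replace = TRUE); rA2 <- sample(g2, n2, replace = TRUE)
    rB1 <- sample(g1, n1, replace = TRUE); rB2 <- sample(g2, n2, replace = TRUE)
    stA <- .group_mean_se(X, rA1, rA2)
    stB <- .group_mean_se(X, rB1, rB2)
    perm <- sample(cols)
    p1 <- perm[seq_len(n1)]; p2 <- perm[n1 + seq_len(n2)]
    pA1 <- sample(p1, n1, replace = TRUE); pA2 <- sample(p2, n2, replace = TRUE)
    pB1 <- sample(p1, n1, replace = TRUE); pB2 <- sample(p2, n2, replace = TRUE)
    ntA <- .group_mean_se(X, pA1, pA2)
    ntB <- .group_mean_se(X, pB1, pB2)
    for (u in seq_len(nu)) {
      a1 <- ualpha[u, 1]; a2 <- ualpha[u, 2]
      obs[u, , b] <- .topk_overlap(.d_stat(stA$m, stA$s, a1, a2),
                                   .d_stat(stB$m, stB$s, a1, a2), ks)
      nul[u, , b] <- .topk_overlap(.d_stat(ntA$m, ntA$s, a1, a2),
                                   .d_stat(ntB$m, ntB$s, a1, a2), ks)
    }
  }
  Ru <- apply(obs, c(1, 2), mean)
  R0u <- apply(nul, c(1, 2), mean)
  Su <- apply(obs, c(1, 2), stats::sd)
  expand <- match(key, ukey)
  R <- Ru[expand, , drop = FALSE]
  R0 <- R0u[expand, , drop = FALSE]
  S <- Su[expand, , drop = FALSE]
  Z <- ifelse(S > 0, (R - R0) / S, ifelse(R == R0, 0, -Inf))
  list(R = R, R0 = R0, S = S, Z = Z)
}

.check_design <- function(design, nsamp, control = NULL) {
  design <- as.character(design)
  if (length(design) != nsamp)
    .stopf("design has %d entries for %d samples", length(design), nsamp)
  lev <- unique(design)
  if (length(lev) != 2) .stopf("design must name exactly two groups")
  if (!is.null(control)) {
    if (!control %in% lev) .stopf("control group '%s' not in design", control)
    lev <- c(control, setdiff(lev, control))
  }
  g1 <- which(design == lev[1]); g2 <- which(design == lev[2])
  if (length(g1) < 2 || length(g2) < 2)
    .stopf(paste("differential binding with the reproducibility-optimized",
                 "statistic requires at least two replicates per group",
                 "(found %d vs %d); single-replicate samples support only",
                 "the exploratory analyses"), length(g1), length(g2))
  list(g1 = g1, g2 = g2, control = lev[1], treated = lev[2])
}

#' Reproducibility Z-score of a statistic configuration
#'
#' Draws `B` bootstrap pairs resampling replicates with replacement within
#' each group, computes the mean fraction `R_k` of shared bins between the
#' two top-k lists of each pair, and standardizes against the same quantity
#' `R0_k` under randomly permuted group labels:
#' `Z = (R_k - R0_k) / sd(observed overlaps)`.
#'
#' @param x bins-by-samples matrix of log2 signal.
#' @param design two-group factor/character vector over the columns.
#' @param a1,a2 statistic parameters.
#' @param k top-list size.
#' @param B number of bootstrap pairs.
#' @param seed RNG seed.
#' @param control optional control group name.
#' @return The Z score, with `R`, `R0` and `s` attached as attributes.
#' @export
reproducibility_z <- function(x, design, a1, a2, k, B = 100L, seed = 1L,
                              control = NULL) {
  x <- as.matrix(x)
  de <- .check_design(design, ncol(x), control)
  if (k > nrow(x)) .stopf("k = %d exceeds the number of bins (%d)", k, nrow(x))
  tab <- .rots_overlap_table(x, de$g1, de$g2,
                             matrix(c(a1, a2), 1), k, B, seed)
  structure(tab$Z[1, 1], R = tab$R[1, 1], R0 = tab$R0[1, 1], s = tab$S[1, 1])
}

.default_k_grid <- function(n) {
  hi <- max(10, floor(n / 4))
  ks <- unique(round(exp(seq(log(10), log(hi), length.out = 8))))
  ks[ks >= 1 & ks <= n]
}

.default_a1_grid <- c(0, 0.01, 0.05, 0.1, 0.25, 0.5, 1, 2, 3, 5)

#' Optimize the statistic parameters
#'
#' Exhaustive search over `a1_grid` x `a2_choices` x `k_grid` maximizing
#' the reproducibility Z-score. Ties are broken toward smaller a1, then
#' a2 = 1, then smaller k, making the search deterministic under a fixed
#' seed.
#'
#' @param x bins-by-samples matrix of log2 signal.
#' @param design two-group assignment of the columns.
#' @param a1_grid candidate offsets (must contain values so that (0,0) is
#'   avoided; the (a1=0, a2=0) cell is skipped).
#' @param a2_choices subset of c(0, 1).
#' @param k_grid candidate top-list sizes; default quasi-geometric up to a
#'   quarter of the bins.
#' @param B bootstrap pairs.
#' @param seed RNG seed.
#' @param control optional control group name.
#' @return List with `a1`, `a2`, `k`, `Z` and the full search `table`.
#' @export
optimize_params <- function(x, design, a1_grid = .default_a1_grid,
                            a2_choices = c(0, 1), k_grid = NULL, B = 100L,
                            seed = 1L, control = NULL) {
  x <- as.matrix(x)
  de <- .check_design(design, ncol(x), control)
  k_grid <- k_grid %||% .default_k_grid(nrow(x))
  if (any(k_grid > nrow(x))) .stopf("k grid exceeds the number of bins")
  grid <- expand.grid(a1 = a1_grid, a2 = a2_choices)
  grid <- grid[!(grid$a1 == 0 & grid$a2 == 0), , drop = FALSE]
  if (nrow(grid) == 0) .stopf("empty parameter grid")
  tab <- .rots_overlap_table(x, de$g1, de$g2,
                             as.matrix(grid), k_grid, B, seed)
  full <- data.frame(a1 = rep(grid$a1, times = length(k_grid)),
                     a2 = rep(grid$a2, times = length(k_grid)),
                     k = rep(k_grid, each = nrow(grid)),
                     R = as.vector(tab$R), R0 = as.vector(tab$R0),
                     s = as.vector(tab$S), Z = as.vector(tab$Z))
  o <- order(-full$Z, full$a1, -full$a2, full$k)
  best <- full[o[1], ]
  list(a1 = best$a1, a2 = best$a2, k = best$k, Z = best$Z, table = full)
}

# distinct two-group label splits; identity excluded (its null statistics
# are the observed ones and would floor the FDR at 1/n_splits), complements
# dropped when group sizes are equal (|m| is symmetric in the groups)
.all_splits <- function(g1, g2) {
  n <- length(g1) + length(g2)
  n1 <- length(g1)
  comb <- utils::combn(n, n1)
  keep <- logical(ncol(comb))
  for (j in seq_len(ncol(comb))) {
    s <- comb[, j]
    if (setequal(s, g1)) next
    if (n1 == length(g2) && setequal(s, g2)) next
    keep[j] <- TRUE
  }
  comb <- comb[, keep, drop = FALSE]
  if (n1 == length(g2)) {           # complement-equivalent splits
    seen <- character(0); cols <- integer(0)
    for (j in seq_len(ncol(comb))) {
      s <- sort(comb[, j]); cpl <- sort(setdiff(seq_len(n), s))
      key <- paste(pmin(paste(s, collapse = ","), paste(cpl, collapse = ",")))
      if (!key %in% seen) { seen <- c(seen, key); cols <- c(cols, j) }
    }
    comb <- comb[, cols, drop = FALSE]
  }
  comb
}

#' Permutation false discovery rate
#'
#' For each relabelling `p` of the samples into two groups of the original
#' sizes, null statistics `d_p` are computed with the optimized (a1, a2);
#' `FDR(g) = mean_p |{d_p >= d_g}| / |{d_obs >= d_g}|`, monotonized by a
#' running minimum from the largest observed statistic downward and clipped
#' to `[0, 1]`. When the requested number of permutations is at least the
#' number of distinct relabellings, all of them are enumerated exactly
#' (the identity relabelling is never used as a null draw).
#'
#' @param d_obs observed per-bin statistics.
#' @param x bins-by-samples matrix the statistics came from.
#' @param design two-group assignment of the columns.
#' @param a1,a2 the optimized statistic parameters.
#' @param n_perm requested permutation count.
#' @param seed RNG seed (used only when sampling permutations).
#' @param control optional control group name.
#' @return Per-bin FDR estimates in `[0, 1]`.
#' @export
fdr_estimate <- function(d_obs, x, design, a1, a2, n_perm = 100L, seed = 1L,
                         control = NULL) {
  x <- as.matrix(x)
  de <- .check_design(design, ncol(x), control)
  n <- ncol(x); n1 <- length(de$g1)
  splits <- .all_splits(de$g1, de$g2)
  if (ncol(splits) > n_perm) {
    set.seed(seed)
    use <- matrix(0L, n, 0)
    tries <- 0L
    while (ncol(use) < n_perm && tries < 50L * n_perm) {
      tries <- tries + 1L
      p <- sample(n)
      s <- sort(p[seq_len(n1)])
      if (setequal(s, de$g1)) next
      if (n1 == n - n1 && setequal(s, de$g2)) next
      use <- cbind(use, p)
    }
    perms <- use
    splitcols <- lapply(seq_len(ncol(perms)), function(j)
      list(g1 = perms[seq_len(n1), j], g2 = perms[n1 + seq_len(n - n1), j]))
  } else {
    splitcols <- lapply(seq_len(ncol(splits)), function(j) {
      s <- splits[, j]
      list(g1 = s, g2 = setdiff(seq_len(n), s))
    })
  }
  nb <- length(d_obs)
  sorted_obs <- sort(d_obs)
  r <- nb - findInterval(d_obs, sorted_obs, left.open = TRUE)  # |{d_obs >= d_g}|
  total_null <- numeric(nb)
  for (sp in splitcols) {
    st <- .group_mean_se(x, sp$g1, sp$g2)
    dn <- sort(.d_stat(st$m, st$s, a1, a2))
    total_null <- total_null +
      (nb - findInterval(d_obs, dn, left.open = TRUE))
  }
  fdr <- (total_null / length(splitcols)) / r
  # step-up monotonization: each bin takes the minimum over itself and all
  # weaker bins, so the FDR is non-increasing in d
  o <- order(d_obs, decreasing = TRUE)
  fdr[o] <- rev(cummin(rev(fdr[o])))
  pmin(pmax(fdr, 0), 1)
}

#' Per-bin two-group differential binding
#'
#' The full differential-binding fit: optimizes the t-type statistic on the
#' data, computes per-bin statistics, permutation FDR and log2 fold changes
#' (treated minus control), and labels each bin `down` (FDR < cutoff and
#' logFC < 0), `up` (FDR < cutoff and logFC > 0) or `ns`. Cluster letters,
#' when an assignment is supplied, are attached per bin; the clustering is
#' computed independently of differential status.
#'
#' @param x a `signal_matrix` (log2 space), a list of log2 `norm_track`s,
#'   or a bins-by-samples matrix.
#' @param design two-group assignment of the samples (character/factor over
#'   columns); with a `signal_matrix` input it defaults to the `condition`
#'   metadata.
#' @param assign optional `cluster_assignment` on the same bins.
#' @param control name of the control group (group 1 of the logFC sign
#'   convention); defaults to the first level encountered.
#' @param a1_grid,a2_choices,k_grid,B search-grid and bootstrap settings,
#'   see [optimize_params()].
#' @param n_perm permutation count for the FDR (exact enumeration is used
#'   whenever it needs fewer draws).
#' @param fdr_cutoff significance threshold for the direction labels.
#' @param seed seed governing all randomness; bootstrap and permutation
#'   draws use distinct sub-streams so either can be changed independently.
#' @return Object of class `rots_db`: a data frame with one row per bin
#'   (coordinates when known, cluster letter when given, `d`, `logfc`,
#'   `fdr`, `direction`) carrying the selected `(a1, a2, k)`, the
#'   reproducibility `Z` and the design as attributes.
#' @export
run_differential <- function(x, design = NULL, assign = NULL, control = NULL,
                             a1_grid = .default_a1_grid, a2_choices = c(0, 1),
                             k_grid = NULL, B = 100L, n_perm = 100L,
                             fdr_cutoff = 0.05, seed = 1L) {
  grid <- NULL
  if (inherits(x, "signal_matrix")) {
    if (x$space != "log2")
      .stopf("differential binding expects log2-space signal")
    design <- design %||% x$samples$condition
    grid <- x$grid
    X <- x$values
  } else if (is.list(x) && all(vapply(x, inherits, TRUE, "norm_track"))) {
    m <- signal_matrix(x)
    return(run_differential(m, design = design, assign = assign,
                            control = control, a1_grid = a1_grid,
                            a2_choices = a2_choices, k_grid = k_grid, B = B,
                            n_perm = n_perm, fdr_cutoff = fdr_cutoff,
                            seed = seed))
  } else {
    X <- as.matrix(x)
  }
  if (is.null(design)) .stopf("a two-group design is required")
  de <- .check_design(design, ncol(X), control)
  if (!is.null(assign)) {
    stopifnot(inherits(assign, "cluster_assignment"))
    if (length(assign$label) != nrow(X))
      .stopf("cluster assignment covers %d bins, data has %d",
             length(assign$label), nrow(X))
  }
  opt <- optimize_params(X, design, a1_grid = a1_grid,
                         a2_choices = a2_choices, k_grid = k_grid, B = B,
                         seed = seed, control = control)
  st <- .group_mean_se(X, de$g1, de$g2)
  d <- .d_stat(st$m, st$s, opt$a1, opt$a2)
  fdr <- fdr_estimate(d, X, design, opt$a1, opt$a2, n_perm = n_perm,
                      seed = seed + 1000003L, control = control)
  logfc <- rowMeans(X[, de$g2, drop = FALSE]) -
    rowMeans(X[, de$g1, drop = FALSE])
  direction <- rep("ns", nrow(X))
  direction[fdr < fdr_cutoff & logfc < 0] <- "down"
  direction[fdr < fdr_cutoff & logfc > 0] <- "up"
  out <- data.frame(
    chrom = if (!is.null(grid)) grid$chrom else NA_character_,
    start = if (!is.null(grid)) grid$start else NA_integer_,
    end = if (!is.null(grid)) grid$end else NA_integer_,
    cluster = if (!is.null(assign)) as.character(assign$label) else NA_character_,
    d = d, logfc = logfc, fdr = fdr, direction = direction,
    stringsAsFactors = FALSE)
  structure(out,
            class = c("rots_db", "data.frame"),
            alpha = c(a1 = opt$a1, a2 = opt$a2), k = opt$k, Z = opt$Z,
            design = list(control = de$control, treated = de$treated,
                          n1 = length(de$g1), n2 = length(de$g2)),
            fdr_cutoff = fdr_cutoff)
}

#' @export
print.rots_db <- function(x, ...) {
  a <- attr(x, "alpha"); de <- attr(x, "design")
  cat(sprintf("Differential binding (reproducibility-optimized statistic)\n"))
  cat(sprintf("  %s (n=%d) vs %s (n=%d), %d bins\n", de$treated, de$n2,
              de$control, de$n1, nrow(x)))
  cat(sprintf("  selected a1 = %g, a2 = %g, k = %d, Z = %.2f\n",
              a["a1"], a["a2"], attr(x, "k"), attr(x, "Z")))
  cat(sprintf("  at FDR < %g: %d down, %d up, %d unchanged\n",
              attr(x, "fdr_cutoff"), sum(x$direction == "down"),
              sum(x$direction == "up"), sum(x$direction == "ns")))
  invisible(x)
}

#' @export
summary.rots_db <- function(object, ...) {
  print(object)
  cat("\nstatistic quantiles:\n")
  print(stats::quantile(object$d, c(0.5, 0.9, 0.99, 1)))
  cat("logFC quantiles:\n")
  print(stats::quantile(object$logfc, c(0, 0.05, 0.5, 0.95, 1)))
  invisible(object)
}

#' MA-style plot of a differential-binding fit
#'
#' @param x a `rots_db` object.
#' @param file optional PNG path.
#' @param ... ignored.
#' @export
plot.rots_db <- function(x, file = NULL, ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700, res = 120, type = "cairo")
    on.exit(grDevices::dev.off())
  }
  col <- c(down = "#d95f02", up = "#1b9e77", ns = "grey60")[x$direction]
  graphics::plot(x$d, x$logfc, pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor(col, 0.5),
                 xlab = "optimized statistic d", ylab = "log2 fold change",
                 main = "Differential binding")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Export significant bins as BED files
#'
#' @param fit a `rots_db` with genomic coordinates.
#' @param dir output directory; writes `down.bed` and `up.bed`.
#' @param fdr_cutoff threshold (defaults to the fit's own cutoff).
#' @export
write_significant_beds <- function(fit, dir, fdr_cutoff = NULL) {
  stopifnot(inherits(fit, "rots_db"))
  if (anyNA(fit$chrom)) .stopf("fit carries no genomic coordinates")
  cutoff <- fdr_cutoff %||% attr(fit, "fdr_cutoff")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (dd in c("down", "up")) {
    sel <- fit$fdr < cutoff & (if (dd == "down") fit$logfc < 0 else fit$logfc > 0)
    writeLines(sprintf("%s\t%d\t%d\t%s\t%.4g", fit$chrom[sel], fit$start[sel],
                       fit$end[sel], dd, fit$fdr[sel]),
               file.path(dir, paste0(dd, ".bed")))
  }
  invisible(dir)
}
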