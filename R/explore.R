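# replicate diagnostics: PCA, correlation clustering, replicate merging

#' Build a bins-by-samples signal matrix from normalized tracks
#'
#' @param tracks list of `norm_track`s sharing one grid and one space
#'   (typically log2).
#' @return Object of class `signal_matrix`: list with `values` (matrix),
#'   `samples` (metadata), `grid`, `space`.
#' @export
signal_matrix <- function(tracks) {
  stopifnot(length(tracks) >= 1,
            all(vapply(tracks, inherits, TRUE, "norm_track")))
  grid <- tracks[[1]]$grid
  spaces <- unique(vapply(tracks, `[[`, "", "space"))
  if (length(spaces) != 1)
    .stopf("tracks mix signal spaces (%s)", paste(spaces, collapse = ", "))
  for (t in tracks[-1])
    if (!.grids_identical(grid, t$grid)) .stopf("tracks are on different grids")
  v <- vapply(tracks, `[[`, numeric(length(grid)), "values")
  v <- matrix(v, ncol = length(tracks),
              dimnames = list(NULL, vapply(tracks, `[[`, "", "sample_id")))
  samples <- data.frame(
    sample_id = vapply(tracks, `[[`, "", "sample_id"),
    condition = vapply(tracks, `[[`, "", "condition"),
    replicate = vapply(tracks, `[[`, "", "replicate"),
    stringsAsFactors = FALSE)
  structure(list(values = v, samples = samples, grid = grid, space = spaces),
            class = "signal_matrix")
}

#' Principal component analysis of sample profiles
#'
#' Projects samples onto the principal components of the bin-feature space,
#' optionally restricted to the most variable bins. Components follow a
#' fixed sign convention (the largest-magnitude loading is positive) so
#' results are reproducible bit-for-bit.
#'
#' @param m a `signal_matrix` (bins x samples).
#' @param center,scale. passed to the underlying decomposition; centering on
#'   and scaling off by default.
#' @param top_n_variable optionally restrict to this many bins by variance.
#' @param k number of components to keep (default all available).
#' @return Object of class `pca_result`: `coords` (samples x k),
#'   `variance_explained`, `samples`.
#' @export
pca_samples <- function(m, center = TRUE, scale. = FALSE,
                        top_n_variable = NULL, k = NULL) {
  stopifnot(inherits(m, "signal_matrix"))
  x <- m$values
  if (ncol(x) < 2 || nrow(x) < 2) .stopf("PCA needs >= 2 samples and >= 2 bins")
  if (!is.null(top_n_variable)) {
    v <- apply(x, 1, stats::var)
    keep <- order(v, decreasing = TRUE)[seq_len(min(top_n_variable, nrow(x)))]
    x <- x[sort(keep), , drop = FALSE]
  }
  kmax <- min(ncol(x) - 1L, nrow(x))
  k <- k %||% kmax
  if (k > kmax) .stopf("requested %d components; at most %d available", k, kmax)
  if (scale.) {
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0)) .stopf("zero-variance bins prevent scaling")
  }
  # samples are observations: transpose so prcomp sees samples x bins
  p <- stats::prcomp(t(x), center = center, scale. = scale.)
  tot <- sum(p$sdev^2)
  ve <- if (tot > 0) (p$sdev^2 / tot) else rep(0, length(p$sdev))
  coords <- p$x[, seq_len(k), drop = FALSE]
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {               # deterministic sign convention
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { coords[, j] <- -coords[, j]; rot[, j] <- -rot[, j] }
  }
  structure(list(coords = coords, variance_explained = ve[seq_len(k)],
                 samples = m$samples),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d components (%.1f%% variance on PC1)\n",
              nrow(x$coords), ncol(x$coords), 100 * x$variance_explained[1]))
  invisible(x)
}

#' Correlation matrix and hierarchical clustering of samples
#'
#' Pairwise correlation over bins, clustered hierarchically on the distance
#' `1 - r`. Ties are resolved deterministically by sample order.
#'
#' @param m a `signal_matrix`.
#' @param method `"pearson"` or `"spearman"`.
#' @param linkage `"average"` or `"complete"`.
#' @return Object of class `correlation_result`: `cor` (samples x samples),
#'   `hclust`, `linkage`.
#' @export
correlation_cluster <- function(m, method = c("pearson", "spearman"),
                                linkage = c("average", "complete")) {
  method <- match.arg(method); linkage <- match.arg(linkage)
  stopifnot(inherits(m, "signal_matrix"))
  if (ncol(m$values) < 2) .stopf("need >= 2 samples")
  sds <- apply(m$values, 2, stats::sd)
  if (any(sds == 0))
    .stopf("sample '%s' has zero variance; correlation undefined",
           colnames(m$values)[which(sds == 0)[1]])
  r <- stats::cor(m$values, method = method)
  hc <- stats::hclust(stats::as.dist(1 - r), method = linkage)
  structure(list(cor = r, hclust = hc, linkage = linkage, method = method),
            class = "correlation_result")
}

#' Average replicate tracks per bin
#'
#' Arithmetic per-bin mean of replicate tracks in whatever space the inputs
#' share (mean of logs differs from log of means; the default workflow
#' merges linear tracks and log-transforms afterwards).
#'
#' @param tracks list of `norm_track`s on one grid and in one space.
#' @param sample_id identifier for the merged track.
#' @return A `norm_track`; the constituent sample ids are kept in the
#'   `merged_from` attribute.
#' @export
merge_replicates <- function(tracks, sample_id = NULL) {
  if (inherits(tracks, "norm_track")) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1,
            all(vapply(tracks, inherits, TRUE, "norm_track")))
  grid <- tracks[[1]]$grid
  spaces <- unique(vapply(tracks, `[[`, "", "space"))
  if (length(spaces) != 1)
    .stopf("cannot merge tracks in different spaces (%s)",
           paste(spaces, collapse = " + "))
  for (t in tracks[-1])
    if (!.grids_identical(grid, t$grid)) .stopf("tracks are on different grids")
  v <- rowMeans(vapply(tracks, `[[`, numeric(length(grid)), "values"))
  out <- .new_norm_track(grid, v,
                         sample_id %||%
                           paste(vapply(tracks, `[[`, "", "sample_id"),
                                 collapse = "+"),
                         space = spaces,
                         condition = tracks[[1]]$condition)
  attr(out, "merged_from") <- vapply(tracks, `[[`, "", "sample_id")
  out
}

#' Plot sample PCA
#'
#' @param x a `pca_result`.
#' @param file optional PNG path; when given the plot is written there.
#' @param ... ignored.
#' @export
plot.pca_result <- function(x, file = NULL, ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700, res = 120, type = "cairo")
    on.exit(grDevices::dev.off())
  }
  cond <- factor(x$samples$condition)
  graphics::plot(x$coords[, 1], x$coords[, 2],
                 col = as.integer(cond) + 1, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$variance_explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)",
                                100 * (x$variance_explained[2] %||% 0)),
                 main = "Sample PCA")
  graphics::text(x$coords[, 1], x$coords[, 2], labels = x$samples$sample_id,
                 pos = 3, cex = 0.8)
  invisible(x)
}

#' Plot the correlation heatmap/dendrogram
#'
#' @param x a `correlation_result`.
#' @param file optional PNG path.
#' @param ... ignored.
#' @export
plot.correlation_result <- function(x, file = NULL, ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700, res = 120, type = "cairo")
    on.exit(grDevices::dev.off())
  }
  graphics::par(mfrow = c(1, 2))
  graphics::plot(x$hclust, main = sprintf("1 - %s, %s linkage",
                                          x$method, x$linkage),
                 xlab = "", sub = "")
  ord <- x$hclust$order
  graphics::image(seq_len(nrow(x$cor)), seq_len(ncol(x$cor)),
                  x$cor[ord, ord, drop = FALSE], axes = FALSE,
                  xlab = "", ylab = "", main = "Correlation")
  graphics::axis(1, seq_len(nrow(x$cor)), rownames(x$cor)[ord], las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, seq_len(ncol(x$cor)), colnames(x$cor)[ord], las = 2,
                 cex.axis = 0.7)
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}
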