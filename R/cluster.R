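# clustering of bins in the two-sample log-signal plane

#' Cluster bins in two-sample signal space
#'
#' Runs density-based hierarchical clustering (HDBSCAN) on the raw (x, y)
#' log2-signal coordinates of each bin — the same coordinates shown in the
#' genic/intergenic scatterplot, with no standardization. Bins in no dense
#' region are labelled `noise`. `min_samples` sets how conservative the
#' clustering is: the larger it is, the more points are declared noise and
#' clusters shrink to progressively denser cores. Clusters are relabelled
#' deterministically — descending size, ties by ascending centroid x then
#' y — and assigned letters A, B, C, ...
#'
#' @param points output of [scatter_data()] (needs columns `x`, `y`).
#' @param min_cluster_size smallest allowed cluster, >= 2.
#' @param min_samples conservativeness (core-distance neighbourhood size);
#'   defaults to `min_cluster_size`.
#' @return Object of class `cluster_assignment`: `label` (factor with
#'   levels A.. and `noise`), `summary` (per-cluster size and centroid),
#'   `points`, and the parameters used.
#' @export
cluster_bins <- function(points, min_cluster_size = 20L, min_samples = NULL) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  if (min_cluster_size < 2) .stopf("min_cluster_size must be >= 2")
  min_samples <- as.integer(min_samples %||% min_cluster_size)
  if (min_samples < 1) .stopf("min_samples must be >= 1")
  X <- cbind(points$x, points$y)
  if (nrow(X) < min_cluster_size) {
    .warnf("fewer points (%d) than min_cluster_size (%d): all noise",
           nrow(X), min_cluster_size)
    res <- list(labels = integer(nrow(X)), n_clusters = 0L)
  } else {
    res <- .hdbscan(X, min_cluster_size, min_samples)
  }
  if (res$n_clusters > 26L)
    .stopf("%d clusters exceed the 26 letters A-Z; increase min_cluster_size",
           res$n_clusters)
  lab <- res$labels
  if (res$n_clusters > 0L) {
    size <- tabulate(lab, nbins = res$n_clusters)
    cx <- vapply(seq_len(res$n_clusters), function(k) mean(points$x[lab == k]), 0)
    cy <- vapply(seq_len(res$n_clusters), function(k) mean(points$y[lab == k]), 0)
    o <- order(-size, cx, cy)
    letter_of <- integer(res$n_clusters)
    letter_of[o] <- seq_len(res$n_clusters)
    lev <- c(LETTERS[seq_len(res$n_clusters)], "noise")
    label <- factor(ifelse(lab == 0L, "noise", LETTERS[letter_of[pmax(lab, 1L)]]),
                    levels = lev)
    summary <- data.frame(cluster = LETTERS[seq_len(res$n_clusters)],
                          size = size[o], centroid_x = cx[o],
                          centroid_y = cy[o], stringsAsFactors = FALSE)
  } else {
    label <- factor(rep("noise", nrow(X)), levels = "noise")
    summary <- data.frame(cluster = character(0), size = integer(0),
                          centroid_x = numeric(0), centroid_y = numeric(0))
  }
  structure(list(label = label, summary = summary, points = points,
                 min_cluster_size = min_cluster_size,
                 min_samples = min_samples),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d clusters, %d noise of %d points\n",
              nrow(x$summary), sum(x$label == "noise"), length(x$label)))
  if (nrow(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Export one cluster's bins as BED
#'
#' @param assign a `cluster_assignment` computed on bins carrying
#'   coordinates (as produced by [scatter_data()]).
#' @param letter cluster letter, or `"noise"`.
#' @param path output BED path.
#' @export
export_cluster_bed <- function(assign, letter, path) {
  stopifnot(inherits(assign, "cluster_assignment"))
  if (!letter %in% levels(assign$label))
    .stopf("no cluster '%s' (have: %s)", letter,
           paste(levels(assign$label), collapse = ", "))
  keep <- assign$label == letter
  p <- assign$points[keep, , drop = FALSE]
  p <- p[order(p$chrom, p$start), , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\t%s", p$chrom, p$start, p$end, letter), path)
  invisible(path)
}

#' Density scatterplot of clustered bins
#'
#' Smoothed two-dimensional density of all bins with cluster memberships
#' overlaid in color, cluster letters at the centroids, and the y = x
#' reference diagonal, giving the genome-wide overview of enriched,
#' depleted and unchanged compartments.
#'
#' @param points the scatter data the assignment was computed on.
#' @param assign the matching `cluster_assignment`.
#' @param file optional PNG path.
#' @export
density_plot <- function(points, assign, file = NULL) {
  stopifnot(inherits(assign, "cluster_assignment"),
            nrow(points) == length(assign$label))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 900, res = 120, type = "cairo")
    on.exit(grDevices::dev.off())
  }
  graphics::smoothScatter(points$x, points$y, xlab = "sample A (log2)",
                          ylab = "sample B (log2)",
                          main = "Bin clusters in two-sample signal space")
  k <- nrow(assign$summary)
  if (k > 0) {
    cols <- grDevices::hcl.colors(max(k, 3), "Dark 3")
    for (i in seq_len(k)) {
      sel <- assign$label == assign$summary$cluster[i]
      graphics::points(points$x[sel], points$y[sel], pch = 16, cex = 0.3,
                       col = grDevices::adjustcolor(cols[i], 0.35))
      graphics::text(assign$summary$centroid_x[i],
                     assign$summary$centroid_y[i],
                     assign$summary$cluster[i], font = 2, cex = 1.4)
    }
  }
  graphics::abline(0, 1, lty = 2)
  invisible(assign)
}
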