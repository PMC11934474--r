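# Fisher enrichment of cluster bins in annotation region sets, against all
# bins or a genic-/intergenic-stratified background universe

#' Flag bins overlapping a region set
#'
#' A bin is flagged when it overlaps any region by at least one base pair
#' (the same rule as blacklist removal and LOLA-style support counting).
#'
#' @param grid a `bin_grid` (the universe of bins).
#' @param regions intervals in any form accepted by the interval readers
#'   (data frame, `GRanges`, BED path).
#' @return Logical vector, one flag per bin.
#' @export
overlap_flags <- function(grid, regions) {
  stopifnot(inherits(grid, "bin_grid"))
  df <- .read_intervals(regions, "annotation region")
  suppressWarnings(
    GenomicRanges::countOverlaps(.as_granges(grid), .as_granges(df),
                                 minoverlap = 1L)) > 0
}

#' Fisher enrichment of a cluster in annotation sets
#'
#' For each annotation set, builds the 2x2 table (cluster bins overlapping
#' / not, background bins overlapping / not) over the chosen universe and
#' applies a two-sided Fisher exact test. The universe is either every bin,
#' or only the genic / only the intergenic bins: stratifying the background
#' avoids spurious associations for annotation classes that live
#' predominantly in one compartment. The reported odds ratio is the sample
#' odds ratio `(a d)/(b c)`, Haldane-Anscombe corrected (+0.5 per cell)
#' when any cell is zero; the p-value always uses the uncorrected table.
#' q-values are Benjamini-Hochberg across the sets tested in one call.
#'
#' @param assign a `cluster_assignment` on the bins of `grid`.
#' @param letter cluster letter to test.
#' @param annotation_sets named list of region sets (each anything
#'   [overlap_flags()] accepts), or a directory of BED files whose names
#'   become the set names.
#' @param universe `"all"`, `"genic"` or `"intergenic"`.
#' @param cls `bin_classification` (required for a stratified universe).
#' @param grid the `bin_grid` the assignment refers to; defaults to the
#'   coordinates stored in the assignment's points.
#' @return Object of class `enrichment_result`: data frame with columns
#'   `set`, `a`, `b`, `c`, `d`, `odds_ratio`, `log2_or`, `p`, `q`,
#'   `direction`.
#' @export
fisher_cluster_enrichment <- function(assign, letter, annotation_sets,
                                      universe = c("all", "genic", "intergenic"),
                                      cls = NULL, grid = NULL) {
  universe <- match.arg(universe)
  stopifnot(inherits(assign, "cluster_assignment"))
  if (!letter %in% levels(assign$label)) .stopf("no cluster '%s'", letter)
  if (is.null(grid)) {
    p <- assign$points
    # bin_grid sorts internally; remember where each point lands
    reorder <- order(p$chrom, p$start)
    grid <- bin_grid(p$chrom[reorder], p$start[reorder], p$end[reorder])
  } else reorder <- seq_along(assign$label)
  in_cluster <- assign$label == letter
  keep <- rep(TRUE, length(assign$label))
  if (universe != "all") {
    if (is.null(cls)) .stopf("a bin classification is needed for a stratified universe")
    if (length(cls$label) != length(assign$label))
      .stopf("classification and assignment cover different bin sets")
    keep <- as.character(cls$label) == universe
  }
  if (!any(in_cluster & keep))
    .stopf("cluster '%s' is empty within the '%s' universe", letter, universe)
  if (is.character(annotation_sets) && length(annotation_sets) == 1 &&
      dir.exists(annotation_sets)) {
    files <- list.files(annotation_sets, pattern = "\\.bed$", full.names = TRUE)
    annotation_sets <- stats::setNames(as.list(files),
                                       sub("\\.bed$", "", basename(files)))
  }
  if (is.null(names(annotation_sets)) || any(!nzchar(names(annotation_sets))))
    .stopf("annotation sets must be named")
  rows <- list()
  for (nm in names(annotation_sets)) {
    flags_sorted <- overlap_flags(grid, annotation_sets[[nm]])
    flags <- flags_sorted
    flags[reorder] <- flags_sorted          # back to point order
    f <- flags[keep]; cl <- in_cluster[keep]
    a <- sum(cl & f); b <- sum(cl & !f)
    cc <- sum(!cl & f); d <- sum(!cl & !f)
    if (a + cc == 0) {
      .warnf("annotation set '%s' overlaps no universe bin; skipped", nm)
      next
    }
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
    if (a == 0 || b == 0 || cc == 0 || d == 0) {
      or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else {
      or <- (a * d) / (b * cc)
    }
    rows[[nm]] <- data.frame(set = nm, a = a, b = b, c = cc, d = d,
                             odds_ratio = or, log2_or = log2(or), p = p,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) .stopf("no testable annotation set")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$direction <- ifelse(res$odds_ratio > 1, "enriched", "depleted")
  structure(res, class = c("enrichment_result", "data.frame"),
            cluster = letter, universe = universe)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment of cluster %s against the %s universe:\n",
              attr(x, "cluster"), attr(x, "universe")))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

.signif_stars <- function(q) {
  ifelse(q < 1e-4, "****", ifelse(q < 1e-3, "***",
    ifelse(q < 0.01, "**", ifelse(q < 0.05, "*", ""))))
}

#' Bar plot of enrichment results
#'
#' log2 odds ratios per annotation set with significance stars on the
#' BH-adjusted q-values (* < 0.05, ** < 0.01, *** < 0.001, **** < 0.0001);
#' depleted sets point down.
#'
#' @param results an `enrichment_result`.
#' @param file optional PNG path.
#' @export
enrichment_plot <- function(results, file = NULL) {
  stopifnot(inherits(results, "enrichment_result"), nrow(results) >= 1)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700, res = 120, type = "cairo")
    on.exit(grDevices::dev.off())
  }
  lo <- results$log2_or
  col <- ifelse(lo >= 0, "#1b9e77", "#d95f02")
  bp <- graphics::barplot(lo, names.arg = results$set, col = col, las = 2,
                          ylab = "log2 odds ratio",
                          main = sprintf("Cluster %s (%s universe)",
                                         attr(results, "cluster"),
                                         attr(results, "universe")),
                          ylim = range(c(lo * 1.25, 0)))
  graphics::abline(h = 0)
  graphics::text(bp, lo + 0.05 * sign(lo) * max(abs(lo)),
                 .signif_stars(results$q))
  invisible(results)
}
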