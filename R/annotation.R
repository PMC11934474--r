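# genic/intergenic classification of bins and two-sample scatter data

#' Merge gene intervals into a genic union
#'
#' The genic compartment is the union of all gene intervals (strand
#' ignored); overlapping or book-ended intervals are merged. Intergenic is
#' its complement.
#'
#' @param gene_intervals gene records as a `chrom`/`start`/`end` data frame
#'   (0-based half-open), a `GRanges`, a BED file path, or a GFF3/GTF file
#'   path (from which records with feature type `"gene"` are taken).
#' @return Object of class `genic_union` (sorted, merged intervals).
#' @importFrom GenomicRanges reduce
#' @export
build_genic_union <- function(gene_intervals) {
  if (is.character(gene_intervals) && length(gene_intervals) == 1 &&
      grepl("\\.(gff3?|gtf)(\\.gz)?$", gene_intervals, ignore.case = TRUE)) {
    gr <- rtracklayer::import(gene_intervals)
    type <- as.character(S4Vectors::mcols(gr)$type)
    gr <- gr[!is.na(type) & type == "gene"]
    if (length(gr) == 0) .stopf("no 'gene' records in %s", gene_intervals)
    df <- .read_intervals(gr, "gene interval")
  } else {
    df <- .read_intervals(gene_intervals, "gene interval")
  }
  merged <- GenomicRanges::reduce(.as_granges(df))  # merges book-ended too
  structure(list(chrom = as.character(GenomicRanges::seqnames(merged)),
                 start = GenomicRanges::start(merged) - 1L,
                 end = GenomicRanges::end(merged)),
            class = "genic_union")
}

#' @export
length.genic_union <- function(x) length(x$start)

#' @export
print.genic_union <- function(x, ...) {
  cat(sprintf("genic_union: %d merged intervals, %d bp total\n",
              length(x), sum(x$end - x$start)))
  invisible(x)
}

#' Classify bins as genic or intergenic
#'
#' A bin is genic when at least `threshold` of its bases fall inside the
#' genic union (default majority overlap, 0.5; the boundary resolves to
#' genic).
#'
#' @param grid a `bin_grid`.
#' @param union a `genic_union`.
#' @param threshold overlap fraction in (0, 1].
#' @return Object of class `bin_classification`: `label` (factor
#'   genic/intergenic per bin), `overlap_fraction`, `threshold`, `grid`.
#' @importFrom GenomicRanges findOverlaps pintersect width
#' @importFrom S4Vectors queryHits subjectHits
#' @export
classify_bins <- function(grid, union, threshold = 0.5) {
  stopifnot(inherits(grid, "bin_grid"), inherits(union, "genic_union"))
  if (!(threshold > 0 && threshold <= 1)) .stopf("threshold must be in (0, 1]")
  gr <- .as_granges(grid)
  un <- .as_granges(union)
  frac <- numeric(length(grid))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, un))
  if (length(hits)) {
    ov <- GenomicRanges::width(GenomicRanges::pintersect(
      gr[S4Vectors::queryHits(hits)], un[S4Vectors::subjectHits(hits)]))
    bases <- tapply(ov, S4Vectors::queryHits(hits), sum)
    idx <- as.integer(names(bases))
    frac[idx] <- as.numeric(bases) / (grid$end[idx] - grid$start[idx])
  }
  label <- factor(ifelse(frac >= threshold, "genic", "intergenic"),
                  levels = c("genic", "intergenic"))
  structure(list(label = label, overlap_fraction = frac,
                 threshold = threshold, grid = grid),
            class = "bin_classification")
}

#' @export
print.bin_classification <- function(x, ...) {
  cat(sprintf("bin_classification: %d genic, %d intergenic (threshold %.2f)\n",
              sum(x$label == "genic"), sum(x$label == "intergenic"),
              x$threshold))
  invisible(x)
}

#' Two-sample scatter data with genic/intergenic labels
#'
#' Per-bin (x, y) log2 signal of two samples (e.g. wildtype on x, treated
#' on y) with the genic/intergenic class, the raw material of the
#' genic/intergenic scatterplot and of the bin clustering.
#'
#' @param a,b log2-space `norm_track`s on the same grid (a on x, b on y).
#' @param cls a `bin_classification` on the same grid.
#' @return data frame with `chrom`, `start`, `end`, `x`, `y`, `class`.
#' @export
scatter_data <- function(a, b, cls) {
  stopifnot(inherits(a, "norm_track"), inherits(b, "norm_track"),
            inherits(cls, "bin_classification"))
  if (!.grids_identical(a$grid, b$grid) || !.grids_identical(a$grid, cls$grid))
    .stopf("scatter_data: tracks/classification are on different grids")
  if (a$space != "log2" || b$space != "log2")
    .stopf("scatter_data expects log2-space tracks")
  data.frame(chrom = a$grid$chrom, start = a$grid$start, end = a$grid$end,
             x = a$values, y = b$values, class = cls$label,
             stringsAsFactors = FALSE)
}

#' Genic/intergenic scatterplot
#'
#' @param points output of [scatter_data()].
#' @param file optional PNG path.
#' @param xlab,ylab axis labels.
#' @export
scatter_plot <- function(points, file = NULL, xlab = "sample A (log2)",
                         ylab = "sample B (log2)") {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 900, res = 120, type = "cairo")
    on.exit(grDevices::dev.off())
  }
  col <- ifelse(points$class == "genic", "#1b9e77", "#7570b3")
  graphics::plot(points$x, points$y, col = grDevices::adjustcolor(col, 0.4),
                 pch = 16, cex = 0.4, xlab = xlab, ylab = ylab,
                 main = "Genic / intergenic bins")
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = c("genic", "intergenic"),
                   col = c("#1b9e77", "#7570b3"), pch = 16, bty = "n")
  invisible(points)
}

#' Export a bin classification as BED4
#'
#' @param cls a `bin_classification`.
#' @param path output path; the label goes in the name column.
#' @export
write_classification_bed <- function(cls, path) {
  g <- cls$grid
  writeLines(sprintf("%s\t%d\t%d\t%s", g$chrom, g$start, g$end,
                     as.character(cls$label)), path)
  invisible(path)
}
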