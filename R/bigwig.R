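#' Write a binned track as a bigWig file
#'
#' Emits one value per bin interval. Values are the raw counts of a
#' `sample_track` or the (linear- or log-space) values of a `norm_track`.
#'
#' @param track a `sample_track` or `norm_track`.
#' @param sizes named vector of chromosome lengths (see [read_chrom_sizes()]).
#' @param path output path.
#' @importFrom rtracklayer export.bw
#' @importFrom GenomeInfoDb seqlengths seqlengths<-
#' @export
write_bigwig <- function(track, sizes, path) {
  g <- track$grid
  if (length(g) == 0) .stopf("empty track")
  missing <- setdiff(unique(g$chrom), names(sizes))
  if (length(missing))
    .stopf("chromosome '%s' absent from the sizes table", missing[1])
  too_long <- g$end > sizes[g$chrom]
  if (any(too_long)) {
    i <- which(too_long)[1]
    .stopf("bin %s:%d-%d exceeds chromosome length %d",
           g$chrom[i], g$start[i], g$end[i], sizes[g$chrom[i]])
  }
  gr <- .as_granges(g)
  v <- if (inherits(track, "norm_track")) track$values else track$counts
  S4Vectors::mcols(gr)$score <- as.numeric(v)
  GenomeInfoDb::seqlengths(gr) <- sizes[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export.bw(gr, path)
  invisible(path)
}

#' Read per-bin values from a bigWig file
#'
#' Samples each grid bin as the mean of the bigWig signal over the bin
#' interval (uncovered bases contribute zero). Bins on chromosomes absent
#' from the file, or entirely uncovered, get value 0 with a warning.
#'
#' @param path bigWig file.
#' @param grid the `bin_grid` to sample on.
#' @param sample_id,condition,replicate metadata for the resulting track.
#' @param space signal space recorded on the returned track ("linear" or
#'   "log2"); bigWig files themselves do not record this.
#' @return A `norm_track`.
#' @importFrom rtracklayer import.bw BigWigFile
#' @export
read_bigwig_bins <- function(path, grid, sample_id = NULL,
                             condition = NA_character_,
                             replicate = NA_character_,
                             space = "linear") {
  if (!file.exists(path)) .stopf("cannot read bigWig file: %s", path)
  bw <- tryCatch(rtracklayer::import.bw(path),
                 error = function(e) .stopf("cannot read bigWig file %s: %s",
                                            path, conditionMessage(e)))
  gr <- .as_granges(grid)
  values <- numeric(length(grid))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, bw))
  if (length(hits)) {
    ov <- GenomicRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                                    bw[S4Vectors::subjectHits(hits)])
    contrib <- GenomicRanges::width(ov) *
      S4Vectors::mcols(bw)$score[S4Vectors::subjectHits(hits)]
    sums <- tapply(contrib, S4Vectors::queryHits(hits), sum)
    idx <- as.integer(names(sums))
    values[idx] <- as.numeric(sums) / (grid$end[idx] - grid$start[idx])
  }
  uncovered <- setdiff(seq_along(values),
                       unique(S4Vectors::queryHits(hits)))
  if (length(uncovered))
    .warnf("%d bin(s) not covered by %s; set to 0", length(uncovered),
           basename(path))
  .new_norm_track(grid, values,
                  sample_id %||% sub("\\.bw$|\\.bigwig$", "", basename(path)),
                  space = space, condition = condition, replicate = replicate)
}
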