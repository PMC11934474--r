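#' Uniform genomic bin grid
#'
#' A `bin_grid` is the shared coordinate frame of the whole workflow: an
#' ordered, non-overlapping set of uniform-width genomic windows in BED
#' semantics (0-based, half-open). Every interval must have width
#' `bin_width`, except possibly the last interval of each chromosome
#' (chromosome-end remainder).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param bin_width uniform window width in base pairs; inferred from the
#'   intervals when `NULL`.
#' @return An object of class `bin_grid`.
#' @export
bin_grid <- function(chrom, start, end, bin_width = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   stringsAsFactors = FALSE)
  .check_intervals(df, "bin")
  o <- order(df$chrom, df$start)
  df <- df[o, , drop = FALSE]
  # non-overlap within chromosome
  same <- df$chrom[-1] == df$chrom[-nrow(df)]
  if (any(same & df$start[-1] < df$end[-nrow(df)])) {
    i <- which(same & df$start[-1] < df$end[-nrow(df)])[1]
    .stopf("overlapping bins: %s:%d-%d and %s:%d-%d",
           df$chrom[i], df$start[i], df$end[i],
           df$chrom[i + 1], df$start[i + 1], df$end[i + 1])
  }
  w <- df$end - df$start
  last_of_chrom <- c(df$chrom[-1] != df$chrom[-nrow(df)], TRUE)
  if (is.null(bin_width)) {
    bw <- if (all(last_of_chrom)) max(w) else max(w[!last_of_chrom])
  } else bw <- as.integer(bin_width)
  if (any(w[!last_of_chrom] != bw))
    .stopf("mixed bin widths: expected %d bp, found %d bp (only the last bin per chromosome may be shorter)",
           bw, w[!last_of_chrom][which(w[!last_of_chrom] != bw)[1]])
  if (any(w > bw))
    .stopf("bin wider (%d bp) than the declared bin width (%d bp)", max(w), bw)
  structure(list(chrom = df$chrom, start = df$start, end = df$end,
                 bin_width = bw),
            class = "bin_grid")
}

#' @export
length.bin_grid <- function(x) length(x$start)

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid: %d bins of %d bp on %d chromosome(s)\n",
              length(x), x$bin_width, length(unique(x$chrom))))
  invisible(x)
}

#' @export
format.bin_grid <- function(x, ...) {
  sprintf("%s:%d-%d", x$chrom, x$start, x$end)
}

.grids_identical <- function(a, b) {
  identical(a$chrom, b$chrom) && identical(a$start, b$start) &&
    identical(a$end, b$end)
}

.new_sample_track <- function(grid, counts, sample_id,
                              condition = NA_character_,
                              replicate = NA_character_) {
  stopifnot(length(counts) == length(grid))
  if (any(counts < 0)) .stopf("negative counts in sample '%s'", sample_id)
  structure(list(grid = grid, counts = as.numeric(counts),
                 sample_id = sample_id, condition = condition,
                 replicate = replicate),
            class = "sample_track")
}

#' @export
print.sample_track <- function(x, ...) {
  cat(sprintf("sample_track '%s': %d bins, total raw count %.0f\n",
              x$sample_id, length(x$grid), sum(x$counts)))
  invisible(x)
}

#' Read binned signal from a BED file
#'
#' Reads a tab-delimited BED file of uniform genomic windows carrying a raw
#' read count, the standard upstream product of counting aligned reads into
#' fixed windows. The count lives in a configurable column (default 4, the
#' BED "name" slot, where binned-coverage exporters place values).
#'
#' @param path path to a tab-delimited BED file without header.
#' @param count_column 1-based column index holding the non-negative count.
#' @param sample_id sample identifier; defaults to the file base name.
#' @param condition,replicate optional sample metadata.
#' @return A `sample_track` (its grid accessible as `$grid`).
#' @export
read_binned_bed <- function(path, count_column = 4L, sample_id = NULL,
                            condition = NA_character_,
                            replicate = NA_character_) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "", colClasses = "character")
  if (ncol(df) < 3) .stopf("%s: not a BED file (fewer than 3 columns)", path)
  if (ncol(df) < count_column)
    .stopf("%s: no count column %d (file has %d columns); counts are required",
           path, count_column, ncol(df))
  counts <- suppressWarnings(as.numeric(df[[count_column]]))
  if (anyNA(counts))
    .stopf("%s line %d: non-numeric count '%s'", path, which(is.na(counts))[1],
           df[[count_column]][which(is.na(counts))[1]])
  if (any(counts < 0))
    .stopf("%s line %d: negative count", path, which(counts < 0)[1])
  start <- suppressWarnings(as.integer(df[[2]]))
  end <- suppressWarnings(as.integer(df[[3]]))
  if (anyNA(start) || anyNA(end))
    .stopf("%s line %d: non-integer coordinates", path,
           which(is.na(start) | is.na(end))[1])
  o <- order(df[[1]], start)
  grid <- bin_grid(df[[1]][o], start[o], end[o])
  .new_sample_track(grid, counts[o],
                    sample_id %||% sub("\\.bed$", "", basename(path)),
                    condition, replicate)
}

#' Write a binned track back to BED
#'
#' @param track a `sample_track` or `norm_track`.
#' @param path output path. Values are written in column 4.
#' @export
write_binned_bed <- function(track, path) {
  v <- if (inherits(track, "norm_track")) track$values else track$counts
  g <- track$grid
  lines <- sprintf("%s\t%d\t%d\t%s", g$chrom, g$start, g$end,
                   formatC(v, format = "g", digits = 15))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble samples sharing one grid into a track set
#'
#' Verifies that all tracks were binned on the identical grid (same
#' chromosome/start/end sequence) and collects their counts into a
#' bins-by-samples matrix.
#'
#' @param tracks list of `sample_track` objects.
#' @return A `track_set` with fields `grid`, `counts` (matrix) and `samples`
#'   (metadata data frame).
#' @export
align_trackset <- function(tracks) {
  if (inherits(tracks, "sample_track")) tracks <- list(tracks)
  if (length(tracks) < 1) .stopf("need at least one track")
  stopifnot(all(vapply(tracks, inherits, TRUE, "sample_track")))
  grid <- tracks[[1]]$grid
  for (t in tracks[-1]) {
    if (!.grids_identical(grid, t$grid)) {
      if (length(t$grid) != length(grid))
        .stopf("grid mismatch: sample '%s' has %d bins, '%s' has %d",
               tracks[[1]]$sample_id, length(grid), t$sample_id, length(t$grid))
      i <- which(grid$chrom != t$grid$chrom | grid$start != t$grid$start |
                   grid$end != t$grid$end)[1]
      .stopf("grid mismatch at bin %d: '%s' has %s:%d-%d, '%s' has %s:%d-%d",
             i, tracks[[1]]$sample_id, grid$chrom[i], grid$start[i], grid$end[i],
             t$sample_id, t$grid$chrom[i], t$grid$start[i], t$grid$end[i])
    }
  }
  ids <- vapply(tracks, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) .stopf("duplicated sample_id '%s'", ids[duplicated(ids)][1])
  counts <- vapply(tracks, `[[`, numeric(length(grid)), "counts")
  counts <- matrix(counts, ncol = length(tracks),
                   dimnames = list(NULL, ids))
  samples <- data.frame(
    sample_id = ids,
    condition = vapply(tracks, `[[`, "", "condition"),
    replicate = vapply(tracks, `[[`, "", "replicate"),
    stringsAsFactors = FALSE)
  structure(list(grid = grid, counts = counts, samples = samples),
            class = "track_set")
}

#' Split a track set back into its sample tracks
#'
#' The inverse of [align_trackset()]: one `sample_track` per column,
#' carrying the sample metadata. Useful for recombining tracks from several
#' sets (e.g. the two groups returned by [simulate_trackset()]).
#'
#' @param ts a `track_set`.
#' @return List of `sample_track`s.
#' @export
trackset_tracks <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  lapply(seq_len(ncol(ts$counts)), function(j)
    .new_sample_track(ts$grid, ts$counts[, j], ts$samples$sample_id[j],
                      condition = ts$samples$condition[j],
                      replicate = ts$samples$replicate[j]))
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d bins x %d samples (%s)\n", length(x$grid),
              ncol(x$counts), paste(x$samples$sample_id, collapse = ", ")))
  invisible(x)
}

.subset_trackset <- function(ts, keep) {
  grid <- ts$grid
  g <- bin_grid(grid$chrom[keep], grid$start[keep], grid$end[keep],
                bin_width = grid$bin_width)
  structure(list(grid = g, counts = ts$counts[keep, , drop = FALSE],
                 samples = ts$samples),
            class = "track_set")
}

#' Remove bins overlapping blacklist regions
#'
#' Bins overlapping any blacklist interval by at least one base pair are
#' removed from the grid and from every sample, the standard treatment of
#' artifact-prone regions (e.g. the ENCODE blacklist).
#'
#' @param ts a `track_set`.
#' @param blacklist intervals as a data frame with `chrom`/`start`/`end`
#'   (0-based half-open), a `GRanges`, or a path to a BED3 file.
#' @return The filtered `track_set`; the number of removed bins is reported
#'   via `message()`.
#' @importFrom GenomicRanges countOverlaps
#' @export
apply_blacklist <- function(ts, blacklist) {
  stopifnot(inherits(ts, "track_set"))
  bl <- .read_intervals(blacklist)
  # disjoint chromosome sets are legitimate (e.g. a blacklist for another
  # contig); silence the seqlevel-merge notice
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(.as_granges(ts$grid), .as_granges(bl),
                                 minoverlap = 1L))
  drop <- hits > 0
  message(sprintf("apply_blacklist: removed %d of %d bins", sum(drop),
                  length(drop)))
  if (all(drop)) .stopf("blacklist removed every bin")
  if (!any(drop)) return(ts)
  .subset_trackset(ts, !drop)
}

#' Drop bins with low total raw count
#'
#' Removes bins whose raw count summed across all samples falls below
#' `min_total`. Summing across samples (rather than filtering per sample)
#' avoids discarding bins with signal in only one condition, which are
#' exactly the differential ones.
#'
#' @param ts a `track_set` of raw counts.
#' @param min_total non-negative threshold; the default 1 drops bins with
#'   zero signal everywhere.
#' @export
filter_low_count <- function(ts, min_total = 1) {
  stopifnot(inherits(ts, "track_set"), min_total >= 0)
  keep <- rowSums(ts$counts) >= min_total
  if (!any(keep))
    .stopf("filter_low_count: no bin reaches a summed count of %g", min_total)
  if (all(keep)) return(ts)
  .subset_trackset(ts, keep)
}

# interval input in any of the accepted forms -> data.frame(chrom,start,end),
# 0-based half-open
.read_intervals <- function(x, what = "interval") {
  if (is.character(x) && length(x) == 1) {
    df <- utils::read.table(x, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, comment.char = "#",
                            quote = "")
    df <- data.frame(chrom = as.character(df[[1]]),
                     start = as.integer(df[[2]]),
                     end = as.integer(df[[3]]), stringsAsFactors = FALSE)
  } else if (methods::is(x, "GRanges")) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                     start = GenomicRanges::start(x) - 1L,
                     end = GenomicRanges::end(x), stringsAsFactors = FALSE)
  } else if (is.data.frame(x)) {
    df <- data.frame(chrom = as.character(x$chrom),
                     start = as.integer(x$start),
                     end = as.integer(x$end), stringsAsFactors = FALSE)
  } else .stopf("cannot read %ss from class '%s'", what, class(x)[1])
  .check_intervals(df, what)
  df
}

#' Read a chromosome-sizes table
#'
#' @param path two-column tab-separated file: chromosome name, length in bp.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  sizes <- as.integer(df[[2]])
  names(sizes) <- as.character(df[[1]])
  if (any(sizes <= 0)) .stopf("non-positive chromosome length in %s", path)
  sizes
}
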