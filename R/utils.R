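# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
.as_granges <- function(x) {
  # intervals are kept 0-based half-open internally (BED semantics);
  # GRanges is 1-based closed, hence start + 1
  if (methods::is(x, "GRanges")) return(x)
  if (inherits(x, "bin_grid") || inherits(x, "genic_union")) {
    return(GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end)))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    return(GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end)))
  }
  .stopf("cannot interpret object of class '%s' as genomic intervals", class(x)[1])
}

.check_intervals <- function(df, what = "interval") {
  if (nrow(df) == 0) .stopf("empty %s set", what)
  if (any(is.na(df$start)) || any(is.na(df$end)))
    .stopf("%s set contains missing coordinates", what)
  if (any(df$start < 0)) .stopf("%s with negative start", what)
  if (any(df$end <= df$start)) .stopf("%s with end <= start", what)
  if (any(!nzchar(df$chrom))) .stopf("%s with empty chromosome name", what)
  invisible(df)
}

.geometric_mean <- function(x) exp(mean(log(x)))
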