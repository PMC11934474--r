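# fixtures built in code; no stored data

# a small track written to a temp BED file
write_bed_fixture <- function(lines, file = tempfile(fileext = ".bed")) {
  writeLines(lines, file)
  file
}

# uniform grid + per-sample counts as a track_set
make_trackset <- function(counts, bin_width = 10000L, chrom = "chr1",
                          conditions = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  grid <- bin_grid(rep(chrom, n), (seq_len(n) - 1L) * bin_width,
                   seq_len(n) * bin_width, bin_width = bin_width)
  tracks <- lapply(seq_len(ncol(counts)), function(j)
    broadbins:::.new_sample_track(grid, counts[, j], paste0("s", j),
                                  condition = conditions[j] %||% NA_character_))
  align_trackset(tracks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# log2 norm_track directly from values
make_log_track <- function(values, id, bin_width = 10000L,
                           condition = NA_character_) {
  n <- length(values)
  grid <- bin_grid(rep("chr1", n), (seq_len(n) - 1L) * bin_width,
                   seq_len(n) * bin_width, bin_width = bin_width)
  broadbins:::.new_norm_track(grid, values, id, space = "log2",
                              condition = condition)
}

make_linear_track <- function(values, id, bin_width = 10000L,
                              condition = NA_character_) {
  n <- length(values)
  grid <- bin_grid(rep("chr1", n), (seq_len(n) - 1L) * bin_width,
                   seq_len(n) * bin_width, bin_width = bin_width)
  broadbins:::.new_norm_track(grid, values, id, space = "linear",
                              condition = condition)
}

# the two-blob clustering fixture (400 + 200 points, 10-sigma separation)
blob_points <- function(seed = 42, with_background = FALSE) {
  set.seed(seed)
  X <- rbind(cbind(rnorm(400, 0, 0.5), rnorm(400, 0, 0.5)),
             cbind(rnorm(200, 5, 0.5), rnorm(200, 5, 0.5)))
  if (with_background)
    X <- rbind(X, cbind(runif(60, -4, 9), runif(60, -4, 9)))
  n <- nrow(X)
  data.frame(chrom = "chrS", start = (seq_len(n) - 1L) * 10000L,
             end = seq_len(n) * 10000L, x = X[, 1], y = X[, 2],
             class = factor(rep("intergenic", n),
                            levels = c("genic", "intergenic")))
}

# 2 conditions x 2 replicates sharing a per-bin baseline profile, with a
# planted between-condition shift in 30% of bins
planted_shift_matrix <- function(n = 500, shift = 3, seed = 19) {
  set.seed(seed)
  mu <- rnorm(n, 5, 2)                   # common bin profile
  base <- mu + matrix(rnorm(n * 4), n, 4)
  shifted <- seq_len(round(0.3 * n))
  base[shifted, 3:4] <- base[shifted, 3:4] - shift
  colnames(base) <- c("wt_1", "wt_2", "ko_1", "ko_2")
  tracks <- lapply(1:4, function(j)
    make_log_track(base[, j], colnames(base)[j],
                   condition = rep(c("wt", "ko"), each = 2)[j]))
  signal_matrix(tracks)
}

# brute-force interval overlap (per-base / pairwise scan oracles)
brute_overlap_any <- function(grid_df, regions_df) {
  vapply(seq_len(nrow(grid_df)), function(i) {
    any(regions_df$chrom == grid_df$chrom[i] &
          pmax(regions_df$start, grid_df$start[i]) <
            pmin(regions_df$end, grid_df$end[i]))
  }, logical(1))
}

# two-sided Fisher p by exhaustive hypergeometric enumeration
fisher_p_enum <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  probs <- vapply(lo:hi, function(x) dhyper(x, m1, m2, k), 0)
  obs <- dhyper(a, m1, m2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
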