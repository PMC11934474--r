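# region-set overlap flags and Fisher enrichment with stratified background

make_assignment <- function(labels, n = length(labels), bin_width = 10000L) {
  pts <- data.frame(chrom = "chr1", start = (seq_len(n) - 1L) * bin_width,
                    end = seq_len(n) * bin_width,
                    x = 0, y = 0)
  lv <- c(sort(setdiff(unique(labels), "noise")), "noise")
  structure(list(label = factor(labels, levels = lv), summary = NULL,
                 points = pts, min_cluster_size = 2, min_samples = 1),
            class = "cluster_assignment")
}

test_that("overlap flags follow the 1 bp rule and match a brute-force scan", {
  grid <- bin_grid("chr1", 0L, 10000L)
  expect_true(overlap_flags(grid, data.frame(chrom = "chr1", start = 9999,
                                             end = 10005)))
  expect_false(overlap_flags(grid, data.frame(chrom = "chr1", start = 10000,
                                              end = 10005)))
  set.seed(73)
  n <- 80L
  g <- bin_grid(rep("chr1", n), (seq_len(n) - 1L) * 100L, seq_len(n) * 100L)
  st <- sample(0:8000, 30)
  regions <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                        start = st, end = st + sample(10:500, 30, TRUE))
  expect_equal(overlap_flags(g, regions),
               brute_overlap_any(data.frame(chrom = g$chrom, start = g$start,
                                            end = g$end), regions))
})

test_that("the contingency table and odds ratio follow the worked example", {
  # cluster of 10 bins, 8 overlapping; background of 90, 12 overlapping
  labels <- c(rep("A", 10), rep("noise", 90))
  assign <- make_assignment(labels)
  flagged_bins <- c(1:8, 11:22)
  regions <- data.frame(chrom = "chr1",
                        start = (flagged_bins - 1L) * 10000L + 100L,
                        end = (flagged_bins - 1L) * 10000L + 200L)
  res <- fisher_cluster_enrichment(assign, "A", list(myset = regions))
  expect_equal(c(res$a, res$b, res$c, res$d), c(8, 2, 12, 78))
  expect_equal(res$odds_ratio, 26)
  expect_equal(res$direction, "enriched")
  expect_equal(res$p, fisher_p_enum(8, 2, 12, 78), tolerance = 1e-9)
  expect_gte(res$q, res$p)
})

test_that("Fisher p-values match exhaustive hypergeometric enumeration for n <= 60", {
  set.seed(79)
  for (i in 1:25) {
    nn <- sample(8:60, 1)
    a <- sample(0:nn, 1); rest <- nn - a
    b <- sample(0:rest, 1); rest <- rest - b
    cc <- sample(0:rest, 1); d <- rest - cc
    if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
    p_impl <- stats::fisher.test(matrix(c(a, b, cc, d), 2,
                                        byrow = TRUE))$p.value
    expect_equal(p_impl, fisher_p_enum(a, b, cc, d), tolerance = 1e-9,
                 label = sprintf("table (%d,%d,%d,%d)", a, b, cc, d))
  }
})

test_that("an annotation saturating the universe is degenerate but finite", {
  labels <- c(rep("A", 5), rep("noise", 15))
  assign <- make_assignment(labels)
  all_regions <- data.frame(chrom = "chr1", start = 0, end = 20 * 10000)
  res <- fisher_cluster_enrichment(assign, "A", list(sat = all_regions))
  expect_equal(c(res$b, res$d), c(0, 0))
  expect_true(is.finite(res$odds_ratio))
  expect_equal(res$p, 1)
})

test_that("equal overlap proportions give OR 1 and p 1", {
  labels <- c(rep("A", 10), rep("noise", 40))
  assign <- make_assignment(labels)
  flagged <- c(1:5, 11:30)                # 5/10 in cluster, 20/40 outside
  regions <- data.frame(chrom = "chr1", start = (flagged - 1L) * 10000L + 1L,
                        end = (flagged - 1L) * 10000L + 50L)
  res <- fisher_cluster_enrichment(assign, "A", list(s = regions))
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p, 1)
})

test_that("marginals are conserved across annotation sets and universes", {
  set.seed(83)
  n <- 120L
  labels <- sample(c("A", "B", "noise"), n, TRUE, prob = c(0.3, 0.2, 0.5))
  assign <- make_assignment(labels)
  cls <- structure(list(
    label = factor(sample(c("genic", "intergenic"), n, TRUE),
                   levels = c("genic", "intergenic")),
    overlap_fraction = NULL, threshold = 0.5, grid = NULL),
    class = "bin_classification")
  sets <- lapply(1:3, function(i) {
    bins <- sample(n, 30)
    data.frame(chrom = "chr1", start = (bins - 1L) * 10000L + 5L,
               end = (bins - 1L) * 10000L + 60L)
  })
  names(sets) <- paste0("set", 1:3)
  res_all <- fisher_cluster_enrichment(assign, "A", sets)
  expect_true(all(res_all$a + res_all$b + res_all$c + res_all$d == n))
  res_gen <- fisher_cluster_enrichment(assign, "A", sets, universe = "genic",
                                       cls = cls)
  n_genic <- sum(cls$label == "genic")
  expect_true(all(res_gen$a + res_gen$b + res_gen$c + res_gen$d == n_genic))
})

test_that("a genic-only annotation is not called enriched against the genic-stratified universe", {
  set.seed(89)
  reps <- 20
  lors <- numeric(reps)
  for (r in seq_len(reps)) {
    n <- 400L
    genic <- seq_len(n) <= 200L          # first half genic
    labels <- rep("noise", n)
    labels[sample(which(genic), 60)] <- "A"      # uniform subset of genic
    labels[sample(which(!genic), 60)] <- "A"
    assign <- make_assignment(labels)
    cls <- structure(list(label = factor(ifelse(genic, "genic", "intergenic"),
                                         levels = c("genic", "intergenic")),
                          overlap_fraction = NULL, threshold = 0.5,
                          grid = NULL), class = "bin_classification")
    ann_bins <- sample(which(genic), 80)         # annotation entirely genic
    regions <- data.frame(chrom = "chr1", start = (ann_bins - 1L) * 10000L + 2L,
                          end = (ann_bins - 1L) * 10000L + 70L)
    res <- fisher_cluster_enrichment(assign, "A", list(g = regions),
                                     universe = "genic", cls = cls)
    lors[r] <- res$log2_or
  }
  expect_lt(abs(mean(lors)), 0.2)
})

test_that("the enrichment plot writes a non-empty figure", {
  labels <- c(rep("A", 20), rep("noise", 80))
  assign <- make_assignment(labels)
  sets <- list(
    up = data.frame(chrom = "chr1", start = (0:15) * 10000 + 3,
                    end = (0:15) * 10000 + 90),
    down = data.frame(chrom = "chr1", start = (30:90) * 10000 + 3,
                      end = (30:90) * 10000 + 90))
  res <- fisher_cluster_enrichment(assign, "A", sets)
  expect_true(any(res$direction == "depleted"))
  f <- tempfile(fileext = ".png")
  enrichment_plot(res, file = f)
  expect_gt(file.info(f)$size, 1000)
})
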