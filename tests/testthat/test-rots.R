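# the reproducibility-optimized t-type statistic, bootstrap optimization,
# permutation FDR, and the full differential-binding fit

test_that("the statistic reduces to |mean difference| and to the pooled |t|", {
  # denominator 1: absolute mean difference
  expect_equal(rots_statistic(matrix(c(2, 2), 1), matrix(c(0, 0), 1), 1, 0), 2)
  # identical groups: zero everywhere
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(rots_statistic(x, x, 1, 1), rep(0, 10))
  # (0, 1) equals the textbook pooled two-sample |t|
  set.seed(14)
  x1 <- matrix(rnorm(300, 1), 100, 3)
  x2 <- matrix(rnorm(400), 100, 4)
  d <- rots_statistic(x1, x2, 0, 1)
  oracle <- vapply(seq_len(100), function(i)
    abs(stats::t.test(x1[i, ], x2[i, ], var.equal = TRUE)$statistic), 0)
  expect_equal(d, oracle, tolerance = 1e-12)
  expect_error(rots_statistic(x1, x2, 0, 0), "both zero")
  expect_error(rots_statistic(x1[, 1, drop = FALSE], x2, 1, 0), "replicates")
})

test_that("rankings under (0,1) and (1,0) match the oracle statistics they reduce to", {
  set.seed(15)
  x <- matrix(rnorm(600), 100, 6)
  g1 <- 1:3; g2 <- 4:6
  d_m <- rots_statistic(x[, g1], x[, g2], 1, 0)
  expect_equal(order(d_m), order(abs(rowMeans(x[, g1]) - rowMeans(x[, g2]))))
  d_t <- rots_statistic(x[, g1], x[, g2], 0, 1)
  tt <- vapply(seq_len(100), function(i)
    abs(stats::t.test(x[i, g1], x[i, g2], var.equal = TRUE)$statistic), 0)
  expect_equal(order(d_t), order(tt))
})

test_that("top-k overlap of a ranking with itself is 1", {
  d <- rnorm(50)
  expect_equal(broadbins:::.topk_overlap(d, d, c(1, 5, 25)), rep(1, 3))
})

test_that("the reproducibility Z is near zero on noise and large on planted signal", {
  set.seed(23)
  noise <- matrix(rnorm(1000 * 6), 1000, 6)
  des <- rep(c("a", "b"), each = 3)
  for (s in c(1, 2)) {
    z <- reproducibility_z(noise, des, a1 = 1, a2 = 0, k = 100, B = 60,
                           seed = s)
    expect_lt(abs(as.numeric(z)), 3)
  }
  planted <- noise
  planted[1:200, 4:6] <- planted[1:200, 4:6] + 5
  zp <- reproducibility_z(planted, des, a1 = 1, a2 = 0, k = 200, B = 60,
                          seed = 1)
  expect_gt(as.numeric(zp), 5)
})

test_that("the parameter search is exhaustive and respects tie-breaking", {
  set.seed(31)
  x <- matrix(rnorm(400 * 6), 400, 6)
  x[1:80, 4:6] <- x[1:80, 4:6] - 3
  des <- rep(c("c", "t"), each = 3)
  # singleton grid returns its only candidate
  single <- optimize_params(x, des, a1_grid = 1, a2_choices = 0, k_grid = 50,
                            B = 40, seed = 2)
  expect_equal(c(single$a1, single$a2, single$k), c(1, 0, 50))
  # small grid: the winner equals the argmax of independently recomputed Z
  opt <- optimize_params(x, des, a1_grid = c(0, 0.5, 1), a2_choices = c(0, 1),
                         k_grid = c(40, 80), B = 40, seed = 7)
  tab <- opt$table
  indep <- mapply(function(a1, a2, k)
    as.numeric(reproducibility_z(x, des, a1, a2, k, B = 40, seed = 7)),
    tab$a1, tab$a2, tab$k)
  expect_equal(tab$Z, unname(indep), tolerance = 1e-12)
  best <- tab[order(-tab$Z, tab$a1, -tab$a2, tab$k), ][1, ]
  expect_equal(c(opt$a1, opt$a2, opt$k), c(best$a1, best$a2, best$k))
})

test_that("the selected statistic ranks planted bins above 95% of null bins", {
  set.seed(37)
  x <- matrix(rnorm(1000 * 6), 1000, 6)
  x[1:150, 4:6] <- x[1:150, 4:6] - 4
  des <- rep(c("c", "t"), each = 3)
  opt <- optimize_params(x, des, B = 50, seed = 5)
  d <- rots_statistic(x[, 1:3], x[, 4:6], opt$a1, opt$a2)
  cut95 <- stats::quantile(d[151:1000], 0.95)
  expect_gt(mean(d[1:150] > cut95), 0.95)
})

test_that("exact 2v2 permutation FDR matches an independent enumeration", {
  set.seed(41)
  x <- matrix(rnorm(80), 20, 4)
  x[1:4, 3:4] <- x[1:4, 3:4] + 4
  des <- c("c", "c", "t", "t")
  d_obs <- rots_statistic(x[, 1:2], x[, 3:4], 0.5, 1)
  fdr <- fdr_estimate(d_obs, x, des, 0.5, 1, n_perm = 10000, seed = 3)
  # oracle: the two distinct non-identity splits, raw ratios, step-up
  splits <- list(c(1, 3), c(1, 4))
  null_counts <- rep(0, 20)
  for (s in splits) {
    dn <- rots_statistic(x[, s], x[, setdiff(1:4, s)], 0.5, 1)
    null_counts <- null_counts +
      vapply(d_obs, function(v) sum(dn >= v), 0)
  }
  r <- vapply(d_obs, function(v) sum(d_obs >= v), 0)
  raw <- (null_counts / 2) / r
  o <- order(d_obs, decreasing = TRUE)
  raw[o] <- rev(cummin(rev(raw[o])))
  expect_equal(fdr, pmin(raw, 1), tolerance = 1e-12)
})

test_that("the FDR column is monotone in d, bounded, and smallest at the top bin", {
  set.seed(43)
  x <- matrix(rnorm(500 * 6), 500, 6)
  x[1:50, 4:6] <- x[1:50, 4:6] - 3
  des <- rep(c("c", "t"), each = 3)
  d <- rots_statistic(x[, 1:3], x[, 4:6], 1, 1)
  fdr <- fdr_estimate(d, x, des, 1, 1, seed = 4)
  expect_true(all(fdr >= 0 & fdr <= 1))
  o <- order(d, decreasing = TRUE)
  expect_true(all(diff(fdr[o]) >= -1e-12))
  expect_equal(fdr[which.max(d)], min(fdr))
})

test_that("a null fit calls almost nothing and a planted fit calls the planted bins", {
  set.seed(47)
  des <- rep(c("c", "t"), each = 3)
  null_fit <- run_differential(matrix(rnorm(2000 * 6), 2000, 6), des,
                               control = "c", B = 60, seed = 13)
  expect_lte(mean(null_fit$fdr < 0.05), 0.06)
  x <- matrix(rnorm(2000 * 6), 2000, 6)
  x[1:200, 4:6] <- x[1:200, 4:6] - 4
  fit <- run_differential(x, des, control = "c", B = 60, seed = 13)
  down <- which(fit$direction == "down")
  expect_gt(length(down), 150)
  expect_gt(mean(down <= 200), 0.95)          # dominated by planted bins
  expect_lte(sum(fit$direction == "up"), 2)
})

test_that("logFC follows the treated-minus-control sign convention", {
  x <- cbind(matrix(3, 4, 2), matrix(5, 4, 2))
  x <- x + matrix(rnorm(16, sd = 0.01), 4)
  fit <- run_differential(x, c("ctl", "ctl", "trt", "trt"), control = "ctl",
                          a1_grid = 1, a2_choices = 0, k_grid = 2, B = 30,
                          seed = 1)
  expect_equal(mean(fit$logfc), 2, tolerance = 0.05)
})

test_that("single-replicate groups are refused with an explanatory error", {
  x <- matrix(rnorm(30), 10, 3)
  expect_error(run_differential(x, c("c", "c", "t"), control = "c"),
               "two replicates")
})

test_that("identical seeds reproduce a fit exactly", {
  set.seed(53)
  x <- matrix(rnorm(300 * 6), 300, 6)
  des <- rep(c("c", "t"), each = 3)
  f1 <- run_differential(x, des, control = "c", B = 40, seed = 8)
  f2 <- run_differential(x, des, control = "c", B = 40, seed = 8)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
})
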