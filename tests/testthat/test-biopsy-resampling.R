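# Core subsampling, out-of-bag differences, block pooling, ROC and loess.

test_that("slide reference statistics use the sample SD", {
  r <- slide_reference(c(2, 4))
  expect_equal(r$core_mean, 3)
  expect_equal(r$core_sd, sqrt(2))
  r2 <- slide_reference(c(5, 5, 5))
  expect_equal(r2$core_mean, 5)
  expect_equal(r2$core_sd, 0)
  r1 <- slide_reference(7)
  expect_equal(r1$core_mean, 7)
  expect_true(is.na(r1$core_sd))
  expect_error(slide_reference(numeric(0)), ">= 1 core")
})

test_that("constant cores give exact estimates and zero out-of-bag differences", {
  sub <- subsample_cores(rep(6, 20), 3, "mean", n_reps = 50L, seed = 1)
  expect_true(all(sub$estimates == 6))
  expect_equal(sub$within_1sd_rate, 1)
  expect_true(all(sub$oob_diffs == 0))
})

test_that("k = 1 within-1-SD rate matches exhaustive enumeration over 16 cores", {
  set.seed(70)
  vals <- round(runif(16, 0, 30), 2)
  expected <- mean(abs(vals - mean(vals)) <= sd(vals))
  sub <- subsample_cores(vals, 1, "mean", n_reps = 4000L, seed = 2)
  expect_true(all(sub$estimates %in% vals))
  se <- sqrt(expected * (1 - expected) / 4000)
  expect_lt(abs(sub$within_1sd_rate - expected), 4 * se + 1e-12)
  # oob differences for k = 1 are enumerable too: v_i - mean(v[-i])
  oob_vals <- vapply(seq_along(vals), function(i)
    vals[i] - mean(vals[-i]), numeric(1L))
  nearest <- vapply(sub$oob_diffs, function(d) min(abs(d - oob_vals)),
                    numeric(1L))
  expect_lt(max(nearest), 1e-9)
})

test_that("mean-summary out-of-bag differences are centered at zero", {
  set.seed(71)
  vals <- rnorm(40, 10, 2)
  sub <- subsample_cores(vals, 3, "mean", n_reps = 1000L, seed = 3)
  se <- sub$oob_diff_sd / sqrt(sub$n_reps)
  expect_lt(abs(sub$oob_diff_mean), 4 * se)
})

test_that("max-summary estimates dominate mean-summary estimates draw by draw", {
  set.seed(72)
  vals <- runif(25, 0, 20)
  smean <- subsample_cores(vals, 4, "mean", n_reps = 300L, seed = 4)
  smax <- subsample_cores(vals, 4, "max", n_reps = 300L, seed = 4)
  expect_true(all(smax$estimates >= smean$estimates))
  # positive bias of the max relative to the parent mean
  expect_gt(mean(smax$estimates), smean$reference$core_mean)
})

test_that("restricted mode enforces the 15-core floor and a nonempty out-of-bag set", {
  expect_error(subsample_cores(rnorm(10, 5), 2, "mean", seed = 1),
               "restricted")
  expect_silent(s <- subsample_cores(rnorm(10, 5) + 10, 2, "mean",
                                     n_reps = 10L, seed = 1,
                                     restricted = FALSE))
  expect_error(subsample_cores(rnorm(16, 5), 16, "mean", seed = 1),
               "out-of-bag")
  expect_error(subsample_cores(rnorm(16, 5), 0, "mean", seed = 1), "k must")
})

test_that("block pooling concatenates cores and matches direct statistics", {
  bp <- block_pool(list(c(2, 4), c(6, 8)))
  expect_equal(bp$core_mean, 5)
  expect_equal(bp$core_sd, sd(c(2, 4, 6, 8)))
  expect_equal(bp$n_cores, 4L)
  # single slide degenerates to the slide reference
  one <- block_pool(list(c(3, 9, 6)))
  ref <- slide_reference(c(3, 9, 6))
  expect_equal(one$core_mean, ref$core_mean)
  expect_equal(one$core_sd, ref$core_sd)
  # cell-weighted mean
  bw <- block_pool(list(c(10, 0)), n_cells = list(c(300, 100)))
  expect_equal(bw$weighted_mean, 7.5)
  expect_error(block_pool(list()), "empty block")
})

test_that("ROC flags single-class cutoffs and is perfect with exhaustive sampling", {
  units <- list(a = c(1, 2, 1.5), b = c(2, 3, 2.5))   # truths 1.5 and 2.5
  r <- roc_over_cutoffs(units, ks = 3, summary_stats = "mean",
                        cutoffs = c(10), n_reps = 20L, seed = 5,
                        restricted = FALSE)
  expect_true(is.na(r$sensitivity))     # no true-high unit at cutoff 10
  expect_equal(r$specificity, 100)
  # k = n_cores with the mean: estimate equals truth at every cutoff
  r2 <- roc_over_cutoffs(units, ks = 3, summary_stats = "mean",
                         cutoffs = c(1, 2), n_reps = 20L, seed = 6,
                         restricted = FALSE)
  expect_equal(r2$accuracy, c(100, 100))
  expect_equal(r2$sensitivity, c(100, 100))
})

test_that("two-unit ROC matches exhaustive enumeration", {
  # unit A cores {3,5}: truth 4 -> high at cutoff 4 (>= rule); draws call
  # high with probability 1/2. unit B cores {1,3}: truth 2 -> low; draws
  # always call low.
  units <- list(A = c(3, 5), B = c(1, 3))
  r <- roc_over_cutoffs(units, ks = 1, summary_stats = "mean", cutoffs = 4,
                        n_reps = 2000L, seed = 7, restricted = FALSE)
  expect_equal(r$specificity, 100)
  se <- 100 * sqrt(0.25 / 2000)
  expect_lt(abs(r$sensitivity - 50), 4 * se)
  expect_lt(abs(r$accuracy - 75), 4 * se / 2)
})

test_that("loess reproduces straight lines and matches a direct tricube solve", {
  set.seed(73)
  x <- sort(runif(24, 0, 30))
  y_line <- 2 + 0.5 * x
  cv <- loess_sd_curve(x, y_line, scale = "raw", n_grid = 11)
  expect_equal(cv$fit, 2 + 0.5 * cv$grid, tolerance = 1e-8)
  # one grid point against the weighted normal-equations oracle
  y <- y_line + rnorm(24, 0, 0.3)
  cv2 <- loess_sd_curve(x, y, span = 0.75, scale = "raw", n_grid = 7)
  i <- 4L
  expect_equal(cv2$fit[i],
               oracle_tricube_fit(x, y, cv2$grid[i], span = 0.75),
               tolerance = 1e-8)
  # log2 scale maps the grid back to percents with the 0.1 offset
  cvl <- loess_sd_curve(x, y, scale = "log2", n_grid = 7)
  expect_equal(cvl$x, 2^cvl$grid - 0.1, tolerance = 1e-12)
  expect_error(loess_sd_curve(c(1, 2, 3), c(1, 2, 3)), "at least")
  expect_error(loess_sd_curve(x, y, span = 1.5), "span")
})

test_that("sampling more cores improves mean-summary precision but not max bias", {
  set.seed(74)
  slides <- replicate(8, rnorm(40, runif(1, 3, 25), 2), simplify = FALSE)
  stats_at <- function(k, ss) {
    res <- vapply(seq_along(slides), function(i) {
      s <- subsample_cores(slides[[i]], k, ss, n_reps = 400L,
                           seed = 100 + i)
      c(s$oob_diff_sd, s$within_1sd_rate,
        mean(s$estimates) - s$reference$core_mean)
    }, numeric(3L))
    rowMeans(res)
  }
  mean_k <- vapply(1:5, stats_at, numeric(3L), ss = "mean")
  max_k <- vapply(c(2L, 5L), stats_at, numeric(3L), ss = "max")
  # oob variability shrinks with k for the mean summary
  expect_true(all(diff(mean_k[1L, ]) < 0))
  # within-1-SD rates do not deteriorate with k
  expect_gt(mean_k[2L, 5L], mean_k[2L, 1L])
  # max summary (k >= 2) is positively biased, and more so with k
  expect_true(all(max_k[3L, ] > 0))
  expect_gt(max_k[3L, 2L], max_k[3L, 1L])
})
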