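test_that("Bland-Altman matches the hand-computed fixture", {
  g2 <- c(0.20, 0.25, 0.30, 0.35)
  d <- c(0.01, 0.03, -0.01, 0.05)
  pairs <- data.frame(rafh_g1 = g2 + d, rafh_g2 = g2)
  ba <- bland_altman(pairs)
  expect_equal(ba$mean_diff, 0.02)
  expect_equal(ba$sd_diff, sqrt(sum((d - 0.02)^2) / 3))
  expect_equal(ba$sd_diff, 0.02582, tolerance = 1e-4)
  expect_equal(ba$loa_low, 0.02 - 1.96 * ba$sd_diff)
  expect_equal(ba$loa_high, 0.02 + 1.96 * ba$sd_diff)

  same <- data.frame(rafh_g1 = c(0.1, 0.2, 0.3), rafh_g2 = c(0.1, 0.2, 0.3))
  ba0 <- bland_altman(same)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  expect_error(bland_altman(same[1, ]), ">= 2")
})

test_that("a constant grader shift moves the mean difference, not the SD", {
  set.seed(11)
  pairs <- data.frame(rafh_g1 = runif(30, 0.1, 0.5),
                      rafh_g2 = runif(30, 0.1, 0.5))
  ba <- bland_altman(pairs)
  shifted <- pairs
  shifted$rafh_g1 <- shifted$rafh_g1 + 0.05
  ba2 <- bland_altman(shifted)
  expect_equal(ba2$mean_diff, ba$mean_diff + 0.05)
  expect_equal(ba2$sd_diff, ba$sd_diff)
})

test_that("ICC(A,1) equals the two-way ANOVA mean-square oracle", {
  set.seed(12)
  g1 <- round(runif(10, 0.1, 0.6), 3)
  pairs <- data.frame(rafh_g1 = g1,
                      rafh_g2 = round(g1 + rnorm(10, 0.01, 0.05), 3))
  res <- icc_absolute_agreement(pairs)

  # independent oracle: mean squares from aov() on the long layout
  long <- data.frame(y = c(pairs$rafh_g1, pairs$rafh_g2),
                     subj = factor(rep(1:10, 2)),
                     rater = factor(rep(1:2, each = 10)))
  ms <- summary(stats::aov(y ~ subj + rater, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 10; k <- 2
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(res$icc, icc_oracle, tolerance = 1e-10)
})

test_that("ICC hits its theoretical anchors", {
  g1 <- seq(0.1, 0.5, length.out = 12)
  expect_equal(icc_absolute_agreement(
    data.frame(rafh_g1 = g1, rafh_g2 = g1))$icc, 1)

  set.seed(13)
  big <- data.frame(rafh_g1 = runif(2000), rafh_g2 = runif(2000))
  expect_lt(abs(icc_absolute_agreement(big)$icc), 0.05)

  flat <- data.frame(rafh_g1 = rep(0.3, 8), rafh_g2 = rep(0.3, 8))
  res <- icc_absolute_agreement(flat)
  expect_true(res$degenerate)
  expect_true(is.na(res$icc))
})

test_that("ICC rises with shared subject variance and survives grader swap", {
  set.seed(14)
  iccs <- vapply(c(0.02, 0.05, 0.1, 0.2), function(s) {
    truth <- rnorm(400, 0.3, s)
    icc_absolute_agreement(
      data.frame(rafh_g1 = truth + rnorm(400, 0, 0.04),
                 rafh_g2 = truth + rnorm(400, 0, 0.04)))$icc
  }, numeric(1))
  expect_true(all(diff(iccs) > 0))

  pairs <- data.frame(rafh_g1 = runif(50, 0.2, 0.6))
  pairs$rafh_g2 <- pairs$rafh_g1 + rnorm(50, 0.02, 0.03)
  swapped <- data.frame(rafh_g1 = pairs$rafh_g2, rafh_g2 = pairs$rafh_g1)
  expect_equal(bland_altman(swapped)$mean_diff,
               -bland_altman(pairs)$mean_diff)
  expect_equal(icc_absolute_agreement(swapped)$icc,
               icc_absolute_agreement(pairs)$icc, tolerance = 1e-12)
})

test_that("discordance flags are strict LoA exceedances", {
  pairs <- data.frame(rafh_g1 = c(0.2, 0.3, 0.4, 0.25),
                      rafh_g2 = c(0.21, 0.29, 0.41, 0.26),
                      image_id = c("a", "b", "c", "d"))
  ba <- bland_altman(pairs)
  fl <- flag_discordant(pairs, ba)
  expect_equal(fl$n_flagged, 0)

  # a difference exactly on the limit is NOT flagged
  art <- data.frame(rafh_g1 = c(0.3, 0.35), rafh_g2 = c(0.25, 0.25))
  summ <- list(loa_low = -0.1, loa_high = 0.10)
  fl2 <- flag_discordant(art, summ)
  expect_equal(fl2$n_flagged, 0)
  summ$loa_high <- 0.0999
  expect_equal(flag_discordant(art, summ)$n_flagged, 1)
})

test_that("grader mean lies within the pair and requires complete pairs", {
  pairs <- data.frame(rafh_g1 = c(0.2, 0.3), rafh_g2 = c(0.4, 0.3))
  expect_equal(mean_grader_rafh(pairs), c(0.3, 0.3))
  set.seed(15)
  p2 <- data.frame(rafh_g1 = runif(20), rafh_g2 = runif(20))
  m <- mean_grader_rafh(p2)
  expect_true(all(m >= pmin(p2$rafh_g1, p2$rafh_g2) &
                    m <= pmax(p2$rafh_g1, p2$rafh_g2)))
  p2$rafh_g2[3] <- NA
  expect_error(mean_grader_rafh(p2), "missing")
})
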