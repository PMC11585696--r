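test_that("Spearman rho hits the monotone anchors", {
  x <- c(1, 3, 4, 7, 9, 12, 15)
  y <- x^3 + 2
  expect_equal(spearman_assoc(x, y)$rho, 1)
  expect_equal(spearman_assoc(x, rev(y))$rho, -1)
  res <- spearman_assoc(rep(1, 5), 1:5)
  expect_true(res$degenerate)
  expect_true(is.na(res$rho))
  expect_error(spearman_assoc(1:2, 1:2), ">= 3")
})

test_that("tied 8-point fixture matches rank-formula and permutation oracles", {
  x <- c(1, 2, 2, 3, 4, 4, 4, 5)
  y <- c(2, 1, 3, 3, 5, 4, 6, 6)
  res <- spearman_assoc(x, y)
  expect_equal(res$method, "exact permutation")

  # independent rho oracle: stats::cor.test's average-rank estimate
  oracle_rho <- unname(suppressWarnings(
    stats::cor.test(x, y, method = "spearman"))$estimate)
  expect_equal(res$rho, oracle_rho, tolerance = 1e-12)

  # exhaustive permutation oracle for the two-sided p
  perms <- all_perms(8)
  ry <- rank(y)
  rhos <- apply(perms, 1, function(p) stats::cor(rank(x), ry[p]))
  p_oracle <- mean(abs(rhos) >= abs(res$rho) - 1e-12)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(41)
  x <- runif(25, 1, 5)
  y <- runif(25, 1, 5)
  base <- spearman_assoc(x, y)
  tr <- spearman_assoc(exp(x), y^3)
  expect_equal(tr$rho, base$rho)
  expect_equal(tr$p_value, base$p_value)
})

test_that("correlation panel covers 3 metrics x 4 strata", {
  sim <- simulate_cohort(cohort_sim_config(seed = 6))
  g <- suppressMessages(cohort_growth(split_eyes(sim$records)))
  panel <- tertile_correlation_panel(g)
  expect_equal(nrow(panel), 12)
  expect_setequal(unique(panel$stratum), c("all", "T1", "T2", "T3"))
  expect_true(all(abs(panel$rho) <= 1, na.rm = TRUE))
  expect_equal(sum(panel$n[panel$metric == "area_rate" &
                             panel$stratum != "all"]),
               panel$n[panel$metric == "area_rate" &
                         panel$stratum == "all"])
})

test_that("univariate baseline model recovers the generating sqrt-area slope", {
  est <- vapply(1:8, function(s) {
    sim <- simulate_cohort(cohort_sim_config(seed = 400 + s,
                                             n_participants = 186))
    fit <- fit_univariate_baseline(sim$records, "sqrt_ga_area")
    fit$fixed$estimate[fit$fixed$term == "sqrt_ga_area"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.065), 0.0065)   # bias under 10% of truth
})

test_that("null covariates stay null in the univariate screen", {
  set.seed(42)
  hits <- 0
  for (r in 1:30) {
    df <- visit_rows(
      participant_id = rep(sprintf("P%03d", 1:100), each = 2),
      eye = rep(c("OD", "OS"), 100), time_years = 0,
      rafh_g1 = 0.25, rafh_g2 = 0.25, ga_area_mm2 = 4)
    u_p <- rnorm(100, 0, 0.05)[rep(1:100, each = 2)]
    noise <- u_p + rnorm(200, 0, 0.04)
    df$rafh_g1 <- pmin(1, pmax(0, 0.25 + noise))
    df$rafh_g2 <- df$rafh_g1
    df$bmi <- rnorm(200, 27, 4)[rep(seq(1, 200, 2), each = 2)]
    fit <- fit_univariate_baseline(df, "bmi")
    row <- fit$fixed[fit$fixed$term == "bmi", ]
    hits <- hits + (abs(row$estimate) < 2 * row$se)
  }
  expect_gte(hits / 30, 0.9)
})

test_that("all-single-eyed cohorts degrade to ordinary regression", {
  df <- visit_rows(participant_id = sprintf("P%03d", 1:40), eye = "OD",
                   time_years = 0, ga_area_mm2 = runif(40, 1, 9))
  df$rafh_g1 <- df$rafh_g2 <- 0.1 + 0.05 * sqrt(df$ga_area_mm2)
  fit <- suppressWarnings(fit_univariate_baseline(df, "sqrt_ga_area"))
  expect_true(fit$converged)
  expect_true(length(fit$fallbacks) > 0)
  expect_equal(unname(fit$ranef_var["participant"]), 0)
  expect_equal(fit$fixed$estimate[2], 0.05, tolerance = 1e-8)
})

test_that("multivariate model takes exactly the screened covariates", {
  sim <- simulate_cohort(cohort_sim_config(seed = 9))
  screen <- screen_baseline_covariates(sim$records)
  multi <- fit_multivariate_baseline(sim$records, screen)
  expect_false(isTRUE(multi$no_model))
  expect_true("sqrt_ga_area" %in% multi$selected)
  expect_true(all(vapply(screen[multi$selected], covariate_p,
                         numeric(1)) < 0.05))
})

test_that("an empty screen yields an explicit no-model sentinel", {
  # covariate exactly balanced against the outcome: estimate 0, p = 1
  df <- visit_rows(participant_id = sprintf("P%03d", 1:40), eye = "OD",
                   time_years = 0)
  df$rafh_g1 <- df$rafh_g2 <- rep(c(0.2, 0.3), 20)
  df$age <- rep(c(70, 80, 80, 70), 10)
  screen <- screen_baseline_covariates(df, covariates = "age")
  multi <- fit_multivariate_baseline(df, screen)
  expect_true(multi$no_model)
})

test_that("noise-free longitudinal data recover the slope exactly", {
  df <- do.call(rbind, lapply(1:12, function(p) {
    arm <- if (p <= 6) "metformin" else "observation"
    visit_rows(participant_id = sprintf("P%03d", p), arm = arm,
               time_years = c(0, 0.5, 1, 1.5),
               ga_area_mm2 = 4, rafh_g1 = 0.2, rafh_g2 = 0.2)
  }))
  s <- ifelse(df$arm == "metformin", 0.07, 0.05)
  df$rafh_g1 <- df$rafh_g2 <- 0.2 + s * df$time_years
  # the fit ladder lands on OLS here; R warns about the perfect fit
  fit <- suppressWarnings(suppressMessages(
    fit_longitudinal_rafh(df, with_arm = TRUE)))
  fx <- fit$fixed
  expect_equal(fx$estimate[fx$term == "time_years"], 0.05,
               tolerance = 1e-6)
  expect_equal(unname(fit$arm_slopes["metformin"]), 0.07,
               tolerance = 1e-6)

  pooled <- suppressWarnings(suppressMessages(
    fit_longitudinal_rafh(df, with_arm = FALSE)))
  expect_equal(pooled$fixed$estimate[pooled$fixed$term == "time_years"],
               0.06, tolerance = 1e-6)
})

test_that("visit windows and adherence exclusions restrict the data", {
  sim <- simulate_cohort(cohort_sim_config(seed = 16))
  rec <- sim$records
  fit18 <- suppressMessages(fit_longitudinal_rafh(rec, with_arm = TRUE))
  expect_equal(fit18$window_years, 1.5)
  expect_equal(fit18$n_obs, sum(rec$time_years <= 1.5))
  fit24 <- suppressMessages(fit_longitudinal_rafh(rec, with_arm = FALSE))
  expect_equal(fit24$n_obs, sum(rec$time_years <= 2.0))

  rec$adherence_pct[rec$participant_id == rec$participant_id[1]] <- 50
  fit_adh <- suppressMessages(
    fit_longitudinal_rafh(rec, with_arm = TRUE, adherence_min_pct = 75))
  n_adherent <- sum(tapply(rec$adherence_pct, rec$participant_id, min) >= 75)
  expect_lt(fit_adh$n_participants, length(unique(rec$participant_id)))
  expect_equal(fit_adh$n_participants, n_adherent)
})
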