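#' Spearman rank correlation with exact small-sample p
#'
#' rho is the Pearson correlation of average (midrank) ranks. The two-sided
#' p-value uses the t approximation for n > 10 and the exact permutation
#' distribution (all pairings enumerated) for n <= 10, where the
#' approximation is unreliable.
#'
#' @param x,y numeric vectors of equal length (pairs with missing values
#'   are dropped).
#' @return list with `rho`, `p_value`, `n`, `method`, and `degenerate`
#'   (TRUE with `rho = NA` when either variable is constant).
#' @export
spearman_assoc <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("Spearman correlation needs >= 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "none", degenerate = TRUE))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 10) {
    p <- .spearman_perm_p(rx, ry)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = min(1, p), n = n, method = method,
       degenerate = FALSE)
}

#' Correlation panel: baseline RAFH vs growth rates, overall and by tertile
#'
#' Spearman correlation of baseline RAFH with each of the three growth
#' metrics, computed on all eyes and within each baseline-area tertile.
#'
#' @param growth growth table from [cohort_growth()] (must carry
#'   `baseline_rafh` and `tertile`).
#' @return data frame with columns metric, stratum (`all`, `T1`-`T3`),
#'   rho, p_value, n.
#' @export
tertile_correlation_panel <- function(growth) {
  stopifnot(all(c("baseline_rafh", "tertile", "area_rate", "sqrt_rate",
                  "perim_adj_rate") %in% names(growth)))
  metrics <- c("area_rate", "sqrt_rate", "perim_adj_rate")
  strata <- list(all = rep(TRUE, nrow(growth)),
                 T1 = growth$tertile == 1,
                 T2 = growth$tertile == 2,
                 T3 = growth$tertile == 3)
  if (any(vapply(strata, sum, 0L) < 3)) {
    stop("every tertile needs >= 3 eyes for the correlation panel")
  }
  rows <- list()
  for (m in metrics) {
    for (s in names(strata)) {
      keep <- strata[[s]]
      sp <- spearman_assoc(growth$baseline_rafh[keep], growth[[m]][keep])
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, stratum = s, rho = sp$rho, p_value = sp$p_value,
        n = sp$n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- baseline mixed models -------------------------------------------------

#' Baseline (first-visit) records with derived model covariates
#'
#' One row per eye at its first visit, with the grader-mean RAFH outcome
#' and derived covariates: `sqrt_ga_area` (mm), `ga_focality`
#' (unifocal/multifocal from the focus count), and yes/no factors with
#' "no" / female / group 1 / unifocal as reference levels.
#'
#' @param records flat cohort table (see [cohort_schema()]).
#' @return baseline data frame ready for the mixed models.
#' @export
baseline_records <- function(records) {
  records <- validate_records(records)
  key <- paste(records$participant_id, records$eye, sep = ":")
  first <- unlist(lapply(split(seq_len(nrow(records)), key), function(idx) {
    idx[which.min(records$time_years[idx])]
  }), use.names = FALSE)
  b <- records[first, , drop = FALSE]
  b$rafh <- (b$rafh_g1 + b$rafh_g2) / 2
  b$sqrt_ga_area <- sqrt(b$ga_area_mm2)
  b$ga_focality <- factor(ifelse(b$focus_count > 1, "multifocal",
                                 "unifocal"),
                          levels = c("unifocal", "multifocal"))
  b$sex <- factor(b$sex, levels = c("female", "male"))
  for (cn in c("smoking", "cvd", "foveal_involvement")) {
    b[[cn]] <- factor(b[[cn]], levels = c("no", "yes"))
  }
  b$faf_pattern_group <- factor(b$faf_pattern_group, levels = c(1, 2))
  rownames(b) <- NULL
  b
}

#' Covariates screened against baseline RAFH
#' @export
baseline_covariates <- function() {
  c("focus_count", "sqrt_ga_area", "ga_perimeter_mm", "bmi", "age", "sex",
    "cvd", "smoking", "faf_pattern_group", "foveal_involvement",
    "ga_focality")
}

wald_table <- function(est, se) {
  z <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             ci_low = unname(est - 1.96 * se),
             ci_high = unname(est + 1.96 * se),
             p_value = unname(2 * pnorm(-abs(z))))
}

new_model_fit <- function(fixed, ranef_var, data, method, converged,
                          fallbacks = character()) {
  structure(list(
    fixed = fixed,
    ranef_var = ranef_var,
    n_obs = nrow(data),
    n_eyes = length(unique(paste(data$participant_id, data$eye))),
    n_participants = length(unique(data$participant_id)),
    method = method,
    converged = converged,
    fallbacks = fallbacks
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<model_fit> %s | %d obs, %d eyes, %d participants%s\n",
              x$method, x$n_obs, x$n_eyes, x$n_participants,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(format(x$fixed, digits = digits), ...)
  if (length(x$ranef_var)) {
    cat("random-effect variances:\n")
    print(round(x$ranef_var, 6))
  }
  if (length(x$fallbacks)) {
    cat("fallbacks applied:", paste(x$fallbacks, collapse = " -> "), "\n")
  }
  invisible(x)
}

# Fit an lmer model, capturing convergence warnings; returns NULL on error.
fit_lmer_checked <- function(formula, data) {
  msgs <- character()
  fit <- withCallingHandlers(
    tryCatch(lme4::lmer(formula, data = data, REML = TRUE),
             error = function(e) NULL),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  if (is.null(fit)) return(NULL)
  conv_fail <- any(grepl("failed to converge|convergence code",
                         c(msgs, unlist(fit@optinfo$conv$lme4$messages)),
                         ignore.case = TRUE))
  # boundary (singular) fits are legitimate zero-variance estimates
  if (conv_fail) return(NULL)
  fit
}

lmer_model_fit <- function(fit, data, method, fallbacks = character()) {
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  rv <- setNames(vc$vcov, paste(vc$grp, ifelse(is.na(vc$var1), "", vc$var1)))
  new_model_fit(wald_table(est, se), rv, data, method, TRUE, fallbacks)
}

lm_model_fit <- function(formula, data, method, fallbacks) {
  fit <- lm(formula, data = data)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  new_model_fit(wald_table(est, se), c(participant = 0), data, method, TRUE,
                fallbacks)
}

#' Univariate baseline association model
#'
#' Linear mixed model of grader-mean baseline RAFH on a single covariate
#' with a random intercept for participant (two eyes of one person are
#' correlated). REML estimation; Wald z inference (CI = estimate
#' +/- 1.96 SE). When every participant contributes a single eye the
#' participant variance is unidentifiable and the fit degenerates to
#' ordinary least squares (recorded in `fallbacks`).
#'
#' @param records flat cohort table; reduced internally to first visits
#'   via [baseline_records()] (a data frame already carrying a `rafh`
#'   column and one row per eye is used as is).
#' @param covariate one of [baseline_covariates()].
#' @return a `model_fit`; the covariate's own row is the second row of
#'   `$fixed`.
#' @export
fit_univariate_baseline <- function(records, covariate) {
  b <- if (!is.null(records$rafh) && !is.null(records$sqrt_ga_area)) {
    records
  } else {
    baseline_records(records)
  }
  stopifnot(covariate %in% names(b))
  fml <- as.formula(paste("rafh ~", covariate, "+ (1 | participant_id)"))
  single_eyed <- max(table(b$participant_id)) < 2
  fallbacks <- character()
  fit <- if (single_eyed) NULL else fit_lmer_checked(fml, b)
  if (is.null(fit)) {
    fallbacks <- "ols (participant random effect unidentified or fit failed)"
    return(lm_model_fit(as.formula(paste("rafh ~", covariate)), b,
                        paste("baseline univariate:", covariate), fallbacks))
  }
  lmer_model_fit(fit, b, paste("baseline univariate:", covariate))
}

covariate_p <- function(fit) {
  # single-contrast covariates: the non-intercept row carries the test
  min(fit$fixed$p_value[-1])
}

#' Univariate screen across all baseline covariates
#'
#' @param records flat cohort table.
#' @param covariates covariate names (default [baseline_covariates()]).
#' @return list of `model_fit`, named by covariate.
#' @export
screen_baseline_covariates <- function(records,
                                       covariates = baseline_covariates()) {
  b <- baseline_records(records)
  fits <- lapply(covariates, function(cv) fit_univariate_baseline(b, cv))
  names(fits) <- covariates
  fits
}

#' Multivariable baseline model from the univariate screen
#'
#' All covariates with univariate p < `alpha` (default 0.05) enter jointly;
#' no further selection is performed. When nothing passes the screen an
#' explicit sentinel is returned instead of a fit.
#'
#' @param records flat cohort table.
#' @param univariate_fits output of [screen_baseline_covariates()].
#' @param alpha screening threshold.
#' @return a `model_fit`, or a list with `no_model = TRUE` when no
#'   covariate passes.
#' @export
fit_multivariate_baseline <- function(records, univariate_fits,
                                      alpha = 0.05) {
  ps <- vapply(univariate_fits, covariate_p, numeric(1))
  selected <- names(ps)[!is.na(ps) & ps < alpha]
  if (length(selected) == 0) {
    return(list(no_model = TRUE,
                reason = sprintf("no covariate reached p < %g", alpha)))
  }
  b <- baseline_records(records)
  fml <- as.formula(paste("rafh ~", paste(selected, collapse = " + "),
                          "+ (1 | participant_id)"))
  fallbacks <- character()
  fit <- if (max(table(b$participant_id)) < 2) NULL else {
    fit_lmer_checked(fml, b)
  }
  if (is.null(fit)) {
    fallbacks <- "ols (participant random effect unidentified or fit failed)"
    out <- lm_model_fit(
      as.formula(paste("rafh ~", paste(selected, collapse = " + "))), b,
      "baseline multivariate", fallbacks)
  } else {
    out <- lmer_model_fit(fit, b, "baseline multivariate")
  }
  out$selected <- selected
  out
}

# ---- longitudinal model ----------------------------------------------------

#' Longitudinal mixed model of RAFH over time
#'
#' Models grader-mean RAFH with fixed effects of time (plus treatment arm
#' and the time-by-arm interaction when `with_arm = TRUE`), a crossed
#' random intercept for participant, a random intercept for eye nested in
#' participant, and an (uncorrelated) random slope on time for eye. The
#' treatment question is read off the interaction row. Visits are
#' restricted to `window_years`: 1.5 years for the treatment model (the
#' on-treatment window) and 2.0 years for the pooled-slope model.
#'
#' Non-convergence triggers an explicit fallback ladder — drop the eye
#' slope, then the eye intercept, then all random effects — each step
#' recorded in `$fallbacks`; singular (zero-variance) fits are accepted as
#' boundary estimates, not failures.
#'
#' @param records flat cohort table.
#' @param window_years maximum visit time retained; default 1.5 when
#'   `with_arm`, else 2.0.
#' @param with_arm include arm and time-by-arm fixed effects.
#' @param adherence_min_pct when given, participants with
#'   `adherence_pct` below this are excluded (sensitivity analysis;
#'   conventionally 75).
#' @return a `model_fit`; when `with_arm = TRUE` it also carries
#'   `arm_slopes` (per-arm fitted RAFH change per year) and
#'   `interaction_p`.
#' @export
fit_longitudinal_rafh <- function(records, window_years = NULL,
                                  with_arm = TRUE,
                                  adherence_min_pct = NULL) {
  records <- validate_records(records)
  if (is.null(window_years)) window_years <- if (with_arm) 1.5 else 2.0
  d <- records[records$time_years <= window_years + 1e-9, , drop = FALSE]
  if (!is.null(adherence_min_pct)) {
    low <- tapply(d$adherence_pct, d$participant_id,
                  function(v) any(v < adherence_min_pct, na.rm = TRUE))
    drop_ids <- names(low)[low]
    d <- d[!(d$participant_id %in% drop_ids), , drop = FALSE]
  }
  d$rafh <- (d$rafh_g1 + d$rafh_g2) / 2
  d$arm <- factor(d$arm, levels = c("observation", "metformin"))
  d$eye_uid <- paste(d$participant_id, d$eye, sep = ":")
  fixed <- if (with_arm) "rafh ~ time_years * arm" else "rafh ~ time_years"
  ladders <- list(
    full = "+ (1 | participant_id) + (1 | eye_uid) + (0 + time_years | eye_uid)",
    drop_eye_slope = "+ (1 | participant_id) + (1 | eye_uid)",
    drop_eye_intercept = "+ (1 | participant_id)",
    ols = ""
  )
  fallbacks <- character()
  out <- NULL
  for (step in names(ladders)) {
    if (step != "full") fallbacks <- c(fallbacks, step)
    if (step == "ols") {
      out <- lm_model_fit(as.formula(fixed), d,
                          "longitudinal RAFH", fallbacks)
      break
    }
    fit <- fit_lmer_checked(as.formula(paste(fixed, ladders[[step]])), d)
    if (!is.null(fit)) {
      out <- lmer_model_fit(fit, d, "longitudinal RAFH", fallbacks)
      break
    }
  }
  if (length(out$fallbacks)) {
    message("longitudinal fit fallbacks: ",
            paste(out$fallbacks, collapse = " -> "))
  }
  out$window_years <- window_years
  if (with_arm) {
    fx <- out$fixed
    t_row <- fx[fx$term == "time_years", ]
    i_row <- fx[grepl("^time_years:arm", fx$term), ]
    out$arm_slopes <- c(observation = t_row$estimate,
                        metformin = t_row$estimate + i_row$estimate)
    out$interaction_p <- i_row$p_value
  }
  out
}
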