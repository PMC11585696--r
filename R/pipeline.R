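#' Pipeline configuration
#'
#' Aggregates every tunable constant of the analysis, all defaulting to
#' the values the method prescribes: +40 grey-level threshold offset,
#' 450-um rim, 500-um background window, 1.5-year on-treatment window,
#' 2.0-year pooled-slope window, 75% adherence threshold for the
#' sensitivity model.
#'
#' @param offset detection threshold offset (grey levels).
#' @param rim_width_um rim band width (um).
#' @param window_um background window side (um).
#' @param background_mode `"local"` or `"global"`.
#' @param arm_window_years visit window for the treatment model (years).
#' @param pooled_window_years visit window for the pooled-slope model.
#' @param adherence_min_pct adherence threshold for the sensitivity run.
#' @param conf confidence level for intervals.
#' @param seed RNG seed recorded into the report.
#' @export
rafh_config <- function(offset = 40, rim_width_um = 450, window_um = 500,
                        background_mode = c("local", "global"),
                        arm_window_years = 1.5, pooled_window_years = 2.0,
                        adherence_min_pct = 75, conf = 0.95, seed = 1L) {
  background_mode <- match.arg(background_mode)
  structure(as.list(environment()), class = "rafh_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full cohort analysis pipeline
#'
#' Stages, in order: two-grader agreement with discordance flags; grader
#' averaging; per-eye growth rates with baseline-area tertiles; the
#' tertile-stratified Spearman panel; the univariate baseline covariate
#' screen and the multivariable model built from it; the pooled
#' longitudinal RAFH slope (2-year window); the treatment model with the
#' time-by-arm interaction (1.5-year window) plus its adherence-restricted
#' sensitivity refit. Any stage failure aborts with a stage-named error.
#'
#' @param records flat cohort table (data frame) or a path to a cohort CSV.
#' @param config a [rafh_config()].
#' @param report_path optional path; when given the report is also written
#'   as JSON.
#' @return a `rafh_report` list mirroring the stages above.
#' @export
run_pipeline <- function(records, config = rafh_config(),
                         report_path = NULL) {
  if (is.character(records)) {
    records <- bind_series(stage("read_cohort", read_cohort_table(records)))
  }
  records <- stage("validate", validate_records(records))
  if (anyNA(records$rafh_g2) || is.null(records$rafh_g2)) {
    stop("pipeline stage 'agreement' failed: rafh_g2 missing",
         call. = FALSE)
  }
  agree <- stage("agreement", grader_agreement(records, conf = config$conf))
  series <- stage("growth", split_eyes(records))
  growth <- stage("growth", cohort_growth(series))
  panel <- stage("correlations", tertile_correlation_panel(growth))
  screen <- stage("baseline_models", screen_baseline_covariates(records))
  multi <- stage("baseline_models",
                 fit_multivariate_baseline(records, screen))
  pooled <- stage("longitudinal",
                  fit_longitudinal_rafh(records,
                                        config$pooled_window_years,
                                        with_arm = FALSE))
  arm_fit <- stage("longitudinal",
                   fit_longitudinal_rafh(records, config$arm_window_years,
                                         with_arm = TRUE))
  adh_fit <- stage("longitudinal",
                   fit_longitudinal_rafh(records, config$arm_window_years,
                                         with_arm = TRUE,
                                         adherence_min_pct =
                                           config$adherence_min_pct))
  report <- structure(list(
    config = unclass(config),
    n_images = nrow(records),
    n_eyes = length(unique(paste(records$participant_id, records$eye))),
    n_participants = length(unique(records$participant_id)),
    agreement = unclass(agree),
    growth = growth,
    correlations = panel,
    baseline_screen = lapply(screen, function(f) {
      list(fixed = f$fixed, p_value = covariate_p(f),
           fallbacks = f$fallbacks)
    }),
    multivariate = if (isTRUE(multi$no_model)) multi else {
      list(fixed = multi$fixed, selected = multi$selected,
           fallbacks = multi$fallbacks)
    },
    longitudinal = list(
      pooled_slope = pooled$fixed[pooled$fixed$term == "time_years", ],
      pooled_fit = pooled$fixed,
      arm_slopes = arm_fit$arm_slopes,
      interaction_p = arm_fit$interaction_p,
      arm_fit = arm_fit$fixed,
      adherence_interaction_p = adh_fit$interaction_p,
      adherence_n_participants = adh_fit$n_participants
    ),
    versions = list(rafh = as.character(packageVersion("rafh")),
                    R = paste(R.version$major, R.version$minor, sep = "."),
                    lme4 = as.character(packageVersion("lme4")))
  ), class = "rafh_report")
  if (!is.null(report_path)) {
    jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                         digits = NA, force = TRUE, pretty = TRUE)
  }
  report
}

#' @export
print.rafh_report <- function(x, ...) {
  cat(sprintf("RAFH pipeline report: %d images, %d eyes, %d participants\n",
              x$n_images, x$n_eyes, x$n_participants))
  cat(sprintf("  agreement: ICC %.3f (%.3f-%.3f), LoA [%.3f, %.3f], %d flagged (%.1f%%)\n",
              x$agreement$icc, x$agreement$icc_ci_low,
              x$agreement$icc_ci_high, x$agreement$loa_low,
              x$agreement$loa_high, x$agreement$n_flagged,
              x$agreement$pct_flagged))
  ov <- x$correlations[x$correlations$stratum == "all", ]
  cat(sprintf("  Spearman (all eyes): area %.2f, sqrt %.2f, perimeter-adjusted %.2f\n",
              ov$rho[ov$metric == "area_rate"],
              ov$rho[ov$metric == "sqrt_rate"],
              ov$rho[ov$metric == "perim_adj_rate"]))
  cat(sprintf("  RAFH drift: %.4f units/year; arm slopes obs %.4f / met %.4f (interaction p = %.3f)\n",
              x$longitudinal$pooled_slope$estimate,
              x$longitudinal$arm_slopes[["observation"]],
              x$longitudinal$arm_slopes[["metformin"]],
              x$longitudinal$interaction_p))
  invisible(x)
}
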