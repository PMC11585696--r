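#' @title GA growth-rate metrics
#' @name growth_metrics
#' @description Three per-eye growth rates, each defined from the first and
#'   last visit only (no regression over intermediate visits): the raw area
#'   growth rate in mm^2/year, the square-root transformed rate in mm/year
#'   (which removes the baseline-size dependence of circular-front growth),
#'   and the perimeter-adjusted rate in mm/year (area growth divided by the
#'   mean perimeter, approximating the border's mean radial expansion
#'   speed).
NULL

first_last <- function(series, col) {
  stopifnot(is.data.frame(series))
  if (nrow(series) < 2) stop("growth rate needs >= 2 visits")
  s <- series[order(series$time_years), , drop = FALSE]
  dt <- s$time_years[nrow(s)] - s$time_years[1]
  if (dt <= 0) stop("first and last visit times coincide")
  list(first = s[[col]][1], last = s[[col]][nrow(s)], dt = dt)
}

#' GA area growth rate (mm^2/year)
#' @param series an `eye_series` (or any per-eye data frame with
#'   `time_years` and `ga_area_mm2`).
#' @return (last area - first area) / elapsed years.
#' @export
area_growth_rate <- function(series) {
  fl <- first_last(series, "ga_area_mm2")
  (fl$last - fl$first) / fl$dt
}

#' Square-root transformed GA growth rate (mm/year)
#'
#' Square roots are taken of the total lesion area (summed over foci)
#' before differencing.
#' @inheritParams area_growth_rate
#' @export
sqrt_growth_rate <- function(series) {
  fl <- first_last(series, "ga_area_mm2")
  if (fl$first < 0 || fl$last < 0) stop("areas must be non-negative")
  (sqrt(fl$last) - sqrt(fl$first)) / fl$dt
}

#' Perimeter-adjusted GA growth rate (mm/year)
#'
#' Area growth rate divided by the mean of the first- and last-visit
#' perimeters.
#' @inheritParams area_growth_rate
#' @export
perimeter_adjusted_growth_rate <- function(series) {
  fl <- first_last(series, "ga_perimeter_mm")
  pbar <- (fl$first + fl$last) / 2
  if (pbar <= 0) stop("mean perimeter must be positive")
  area_growth_rate(series) / pbar
}

#' All growth metrics for one eye
#'
#' @inheritParams area_growth_rate
#' @return one-row data frame: participant_id, eye, arm, baseline_area_mm2,
#'   baseline_rafh (grader mean at first visit), dt_years, area_rate,
#'   sqrt_rate, perim_adj_rate.
#' @export
growth_rates <- function(series) {
  s <- series[order(series$time_years), , drop = FALSE]
  fl <- first_last(s, "ga_area_mm2")
  data.frame(
    participant_id = s$participant_id[1],
    eye = s$eye[1],
    arm = s$arm[1],
    baseline_area_mm2 = s$ga_area_mm2[1],
    baseline_rafh = mean(c(s$rafh_g1[1], s$rafh_g2[1])),
    dt_years = fl$dt,
    area_rate = area_growth_rate(s),
    sqrt_rate = sqrt_growth_rate(s),
    perim_adj_rate = perimeter_adjusted_growth_rate(s)
  )
}

#' Growth table for a whole cohort
#'
#' Computes [growth_rates()] for every eligible eye (>= 2 visits; single
#' visit eyes are dropped with a message) and appends baseline-area
#' tertiles.
#'
#' @param series list of `eye_series` from [read_cohort_table()] or
#'   [split_eyes()].
#' @return data frame of per-eye growth metrics with a `tertile` column.
#' @export
cohort_growth <- function(series) {
  eligible <- vapply(series, function(s) nrow(s) >= 2, logical(1))
  if (any(!eligible)) {
    message(sum(!eligible), " eye(s) with a single visit excluded from growth")
  }
  if (!any(eligible)) stop("no eye has >= 2 visits")
  g <- do.call(rbind, lapply(series[eligible], growth_rates))
  rownames(g) <- NULL
  g$tertile <- assign_tertiles(g)
  g
}

#' Baseline-area tertile labels
#'
#' Eyes are ranked by baseline GA area (ascending; ties broken stably by
#' participant id then eye so the split is deterministic) and cut into
#' three groups as equal as possible, with any remainder going to the lower
#' tertiles — 71 eyes split 24/24/23.
#'
#' @param growth data frame with `baseline_area_mm2`, `participant_id`,
#'   `eye` (>= 3 rows).
#' @return integer vector of labels 1..3, aligned with the input rows.
#' @export
assign_tertiles <- function(growth) {
  n <- nrow(growth)
  if (is.null(n) || n < 3) stop("tertile assignment needs >= 3 eyes")
  ord <- order(growth$baseline_area_mm2, growth$participant_id, growth$eye)
  q <- n %/% 3L
  r <- n %% 3L
  sizes <- q + as.integer(seq_len(3L) <= r)
  labels_sorted <- rep.int(1:3, sizes)
  labels <- integer(n)
  labels[ord] <- labels_sorted
  labels
}
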