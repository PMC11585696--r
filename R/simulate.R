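#' @title Synthetic FAF images and longitudinal cohorts
#' @name synthetic_data
#' @description Ground-truth test substrate for the whole pipeline: (a)
#'   FAF-like frames with a planted GA lesion and a known true RAFH, and
#'   (b) two-arm longitudinal cohorts with the hierarchical structure the
#'   mixed models assume (participant and eye intercepts, eye slopes,
#'   square-root-linear lesion growth, two noisy graders). All randomness
#'   flows from R's default Mersenne-Twister generator seeded from the
#'   mandatory `seed` field, so runs are bit-reproducible.
NULL

#' Configuration for a synthetic FAF image
#'
#' @param target_rafh planted true RAFH in \[0, 1\].
#' @param seed RNG seed (mandatory).
#' @param grid_px image side length in pixels.
#' @param scale_um_per_px pixel scale.
#' @param bg_mean,bg_sd background intensity mean/SD (8-bit grey levels).
#' @param n_lesions number of GA foci.
#' @param lesion_radius_um mean focus radius (recycled across foci).
#' @param ga_intensity mean intensity of the dark lesion interior.
#' @param speckle_offset intensity of hyperAF speckle above background;
#'   must exceed the detection offset for the speckle to be recoverable.
#' @param speckle_radius_um mean radius of individual speckle blobs.
#' @param rim_width_um rim band width used for planting.
#' @export
image_sim_config <- function(target_rafh, seed, grid_px = 256,
                             scale_um_per_px = 10, bg_mean = 100,
                             bg_sd = 8, n_lesions = 1,
                             lesion_radius_um = 600, ga_intensity = 25,
                             speckle_offset = 60, speckle_radius_um = 40,
                             rim_width_um = 450) {
  stopifnot(is.numeric(target_rafh), target_rafh >= 0, target_rafh <= 1)
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory")
  check_scale(scale_um_per_px)
  structure(as.list(environment()), class = "image_sim_config")
}

# one blobby perturbed-ellipse focus: radius modulated by low-order
# cosine harmonics so the border is irregular but smooth
blob_mask <- function(grid_px, center, radius_px, aspect = 1) {
  amp <- runif(4, -0.10, 0.10)
  phase <- runif(4, 0, 2 * pi)
  ij <- expand.grid(i = seq_len(grid_px), j = seq_len(grid_px))
  dx <- (ij$i - center[1])
  dy <- (ij$j - center[2]) / aspect
  theta <- atan2(dy, dx)
  r <- radius_px * (1 + amp[1] * cos(2 * theta + phase[1]) +
                      amp[2] * cos(3 * theta + phase[2]) +
                      amp[3] * cos(4 * theta + phase[3]) +
                      amp[4] * cos(5 * theta + phase[4]))
  matrix(sqrt(dx^2 + dy^2) <= r, grid_px, grid_px)
}

disk_indices <- function(nr, nc, center, radius_px) {
  i0 <- max(1, floor(center[1] - radius_px))
  i1 <- min(nr, ceiling(center[1] + radius_px))
  j0 <- max(1, floor(center[2] - radius_px))
  j1 <- min(nc, ceiling(center[2] + radius_px))
  ij <- expand.grid(i = i0:i1, j = j0:j1)
  keep <- (ij$i - center[1])^2 + (ij$j - center[2])^2 <= radius_px^2
  cbind(ij$i[keep], ij$j[keep])
}

#' Simulate a FAF image with planted ground truth
#'
#' Builds a noisy background, a dark irregular GA lesion, and
#' hyperautofluorescent speckle blobs planted inside the rim band until the
#' planted-pixel fraction of the rim hits the target RAFH exactly at pixel
#' resolution (blobs are trimmed randomly on overshoot).
#'
#' @param config an [image_sim_config()].
#' @return list: `image` ([faf_image()]), `ga_mask`, `true_hyper_mask`
#'   (both `binary_mask`), `rim_mask` (logical matrix used for planting),
#'   `true_rafh` (achieved planted ratio).
#' @export
simulate_faf_image <- function(config) {
  stopifnot(inherits(config, "image_sim_config"))
  set.seed(config$seed)
  n <- config$grid_px
  sc <- config$scale_um_per_px
  ga <- matrix(FALSE, n, n)
  r_px <- config$lesion_radius_um / sc
  for (k in seq_len(config$n_lesions)) {
    center <- if (config$n_lesions == 1) c(n / 2, n / 2) else {
      runif(2, n * 0.3, n * 0.7)
    }
    ga <- ga | blob_mask(n, center, r_px * runif(1, 0.85, 1.15),
                         aspect = runif(1, 0.85, 1.15))
  }
  if (!any(ga)) stop("lesion radius too small for this grid")
  if (all(ga)) stop("lesion fills the grid")
  d <- sqrt(.edt_sq(ga)) * sc
  rim <- d > 0 & d <= config$rim_width_um
  n_rim <- sum(rim)
  if (n_rim == 0) stop("rim band is empty; enlarge the grid")
  target_px <- round(config$target_rafh * n_rim)
  if (config$target_rafh > 0 && target_px == 0) {
    stop(sprintf("target RAFH %.3g unreachable: rim holds %d px (min ratio %.3g)",
                 config$target_rafh, n_rim, 1 / n_rim))
  }
  hyper <- matrix(FALSE, n, n)
  rim_idx <- which(rim)
  guard <- 0
  while (sum(hyper) < target_px) {
    guard <- guard + 1
    if (guard > 50000) stop("speckle planting failed to reach the target")
    center_idx <- rim_idx[sample.int(length(rim_idx), 1)]
    center <- c((center_idx - 1) %% n + 1, (center_idx - 1) %/% n + 1)
    rad <- (config$speckle_radius_um / sc) * runif(1, 0.6, 1.4)
    px <- disk_indices(n, n, center, rad)
    sel <- rim[px] & !hyper[px]
    hyper[px[sel, , drop = FALSE]] <- TRUE
  }
  excess <- sum(hyper) - target_px
  if (excess > 0) {
    on_idx <- which(hyper)
    hyper[sample(on_idx, excess)] <- FALSE
  }
  img <- matrix(rnorm(n * n, config$bg_mean, config$bg_sd), n, n)
  img[ga] <- rnorm(sum(ga), config$ga_intensity, config$bg_sd)
  img[hyper] <- rnorm(sum(hyper), config$bg_mean + config$speckle_offset,
                      config$bg_sd)
  img[] <- pmin(255, pmax(0, round(img)))
  list(image = faf_image(img, sc),
       ga_mask = binary_mask(ga, role = "ga"),
       true_hyper_mask = binary_mask(hyper, role = "hyper"),
       rim_mask = rim,
       true_rafh = sum(hyper) / n_rim)
}

#' Configuration for a synthetic longitudinal cohort
#'
#' Defaults emulate a two-arm GA trial re-analysis cohort: 44 participants
#' contributing ~71 eyes over visits at 0, 0.5, 1, 1.5 and 2 years, a
#' log-normal baseline GA area (median 5 mm^2), square-root-linear lesion
#' growth near 0.25 mm/year, baseline RAFH rising with the square root of
#' baseline GA area at 0.065 per mm, RAFH drift of 0.020 units/year, a
#' null treatment effect, and two graders with independent Gaussian noise
#' (SD 0.044, the per-grader level implied by a between-grader difference
#' SD near 0.062).
#'
#' @param seed RNG seed (mandatory).
#' @param n_participants number of participants.
#' @param second_eye_prob probability a participant contributes both eyes.
#' @param arm_ratio fraction of participants randomized to metformin.
#' @param visit_times scheduled visit times in years (baseline first).
#' @param dropout_prob probability each post-baseline visit is missed.
#' @param area_meanlog,area_sdlog log-normal baseline GA area (mm^2).
#' @param area_range_mm2 truncation range for baseline GA area, mm^2 —
#'   lesions below the trial's minimum or larger than the imaged macula
#'   are not enrolled, so the log-normal is sampled within this range.
#' @param sqrt_rate_mean,sqrt_rate_sd square-root growth rate (mm/year),
#'   truncated below at 0.02.
#' @param circularity_range per-eye perimeter shape factor range; perimeter
#'   is `c * 2 * sqrt(pi * A)` so `c = 1` is a circle.
#' @param multifocal_prob probability an eye is multifocal.
#' @param rafh_intercept baseline RAFH level at zero lesion size.
#' @param rafh_sqrt_area_slope cross-sectional RAFH slope on baseline
#'   sqrt-area, per mm.
#' @param rafh_time_slope marginal RAFH drift, units/year.
#' @param arm_time_effect added drift in the metformin arm, units/year.
#' @param growth_coupling length-3 vector: added sqrt growth rate per unit
#'   of an eye's RAFH deviation, by baseline-area tertile stratum — lets
#'   the size-dependent RAFH-growth association be switched on per stratum.
#' @param sd_participant,sd_eye,sd_eye_slope random-effect SDs.
#' @param sd_visit visit-level RAFH jitter SD.
#' @param grader_noise_sd per-grader measurement SD.
#' @param max_clip_frac run fails when more than this fraction of RAFH
#'   draws had to be clipped into \[0, 1\].
#' @export
cohort_sim_config <- function(seed, n_participants = 44,
                              second_eye_prob = 0.61, arm_ratio = 0.5,
                              visit_times = c(0, 0.5, 1, 1.5, 2),
                              dropout_prob = 0.12,
                              area_meanlog = log(5), area_sdlog = 0.9,
                              area_range_mm2 = c(0.25, 35),
                              sqrt_rate_mean = 0.25, sqrt_rate_sd = 0.12,
                              circularity_range = c(1, 2),
                              multifocal_prob = 0.66,
                              rafh_intercept = 0.15,
                              rafh_sqrt_area_slope = 0.065,
                              rafh_time_slope = 0.020,
                              arm_time_effect = 0,
                              growth_coupling = c(0.8, 0.8, 0),
                              sd_participant = 0.05, sd_eye = 0.04,
                              sd_eye_slope = 0.010, sd_visit = 0.015,
                              grader_noise_sd = 0.044,
                              max_clip_frac = 0.01) {
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory")
  stopifnot(n_participants >= 2, length(growth_coupling) == 3,
            all(c(sd_participant, sd_eye, sd_eye_slope, sd_visit,
                  grader_noise_sd) >= 0),
            dropout_prob >= 0, dropout_prob < 1,
            second_eye_prob >= 0, second_eye_prob <= 1,
            visit_times[1] == 0, !is.unsorted(visit_times))
  structure(as.list(environment()), class = "cohort_sim_config")
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Simulate a longitudinal two-arm cohort
#'
#' Hierarchical draws: participant intercepts, then eye intercepts and
#' slopes, then per-visit true RAFH
#' `intercept + slope_area * sqrt(A_baseline) + (drift + eye slope +
#' arm effect) * t + visit jitter`, with the square root of area growing
#' linearly at the eye's rate and perimeter derived from area through the
#' eye's circularity factor. The eye's growth rate is coupled to its RAFH
#' deviation with a stratum-specific coefficient (`growth_coupling`).
#' Grader readings are the truth plus independent Gaussian noise, clipped
#' to \[0, 1\].
#'
#' @param config a [cohort_sim_config()].
#' @return list: `records` (flat cohort table, see [cohort_schema()]),
#'   `truth` (per-eye data frame of the generating values), `n_clipped`,
#'   `clip_frac`. Errors when the clip fraction exceeds
#'   `config$max_clip_frac`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  np <- config$n_participants
  n_met <- round(np * config$arm_ratio)
  arm_p <- sample(rep(c("metformin", "observation"),
                      c(n_met, np - n_met)))
  strat_cut <- qlnorm(c(1, 2) / 3, config$area_meanlog, config$area_sdlog)
  rows <- list()
  truth <- list()
  n_clip <- 0L
  n_draw <- 0L
  for (p in seq_len(np)) {
    pid <- sprintf("P%03d", p)
    arm <- arm_p[p]
    u_p <- rnorm(1, 0, config$sd_participant)
    age <- round(pmin(95, pmax(55, rnorm(1, 76, 7))))
    sex <- if (runif(1) < 0.34) "male" else "female"
    bmi <- round(rnorm(1, 27, 4), 1)
    smoking <- if (runif(1) < 0.37) "yes" else "no"
    cvd <- if (runif(1) < 0.54) "yes" else "no"
    adherence <- if (arm == "metformin") {
      round(pmin(100, pmax(0, rnorm(1, 90, 12))), 1)
    } else 100
    eyes <- if (runif(1) < config$second_eye_prob) c("OD", "OS") else "OD"
    for (eye in eyes) {
      a0 <- rlnorm(1, config$area_meanlog, config$area_sdlog)
      while (a0 < config$area_range_mm2[1] ||
             a0 > config$area_range_mm2[2]) {
        a0 <- rlnorm(1, config$area_meanlog, config$area_sdlog)
      }
      stratum <- 1L + (a0 > strat_cut[1]) + (a0 > strat_cut[2])
      u_e <- rnorm(1, 0, config$sd_eye)
      u_s <- rnorm(1, 0, config$sd_eye_slope)
      dev <- u_p + u_e
      rate <- max(0.02, rnorm(1, config$sqrt_rate_mean,
                              config$sqrt_rate_sd) +
                    config$growth_coupling[stratum] * dev)
      circ <- runif(1, config$circularity_range[1],
                    config$circularity_range[2])
      multifocal <- runif(1) < config$multifocal_prob
      focus_count <- if (multifocal) 1L + sample.int(4, 1) else 1L
      faf_group <- if (runif(1) < 0.32) 2L else 1L
      foveal <- if (runif(1) < 0.89) "yes" else "no"
      keep <- c(TRUE, runif(length(config$visit_times) - 1) >=
                  config$dropout_prob)
      times <- config$visit_times[keep]
      arm_eff <- if (arm == "metformin") config$arm_time_effect else 0
      for (t in times) {
        sq_a <- sqrt(a0) + rate * t
        a_t <- sq_a^2
        per_t <- circ * 2 * sqrt(pi * a_t)
        mu <- config$rafh_intercept +
          config$rafh_sqrt_area_slope * sqrt(a0) +
          (config$rafh_time_slope + u_s + arm_eff) * t +
          u_p + u_e
        truth_t <- mu + rnorm(1, 0, config$sd_visit)
        g <- truth_t + rnorm(2, 0, config$grader_noise_sd)
        vals <- c(truth_t, g)
        n_clip <- n_clip + sum(vals < 0 | vals > 1)
        n_draw <- n_draw + 3L
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, eye = eye, arm = arm, time_years = t,
          rafh_g1 = clip01(g[1]), rafh_g2 = clip01(g[2]),
          ga_area_mm2 = a_t, ga_perimeter_mm = per_t,
          focus_count = focus_count, age = age, sex = sex, bmi = bmi,
          smoking = smoking, cvd = cvd, faf_pattern_group = faf_group,
          foveal_involvement = foveal, adherence_pct = adherence)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        participant_id = pid, eye = eye, arm = arm,
        baseline_area_mm2 = a0, sqrt_rate_true = rate,
        rafh_dev = dev, stratum = stratum, circularity = circ)
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  clip_frac <- n_clip / n_draw
  if (clip_frac > config$max_clip_frac) {
    stop(sprintf("%.2f%% of RAFH draws clipped to [0,1] (limit %.2f%%); adjust the configuration",
                 100 * clip_frac, 100 * config$max_clip_frac))
  }
  list(records = records, truth = do.call(rbind, truth),
       n_clipped = n_clip, clip_frac = clip_frac)
}

#' Simulate a pair of grader readings
#'
#' Independent Gaussian perturbations of the true RAFH, clipped to
#' \[0, 1\]; the number of clipped readings is reported as an attribute.
#'
#' @param true_rafh vector of true values.
#' @param noise_sd per-grader SD (>= 0).
#' @param seed RNG seed.
#' @return data frame with `rafh_g1`, `rafh_g2` and attribute `n_clipped`.
#' @export
simulate_grader_pair <- function(true_rafh, noise_sd = 0.044, seed) {
  stopifnot(noise_sd >= 0)
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory")
  set.seed(seed)
  g1 <- true_rafh + rnorm(length(true_rafh), 0, noise_sd)
  g2 <- true_rafh + rnorm(length(true_rafh), 0, noise_sd)
  n_clip <- sum(g1 < 0 | g1 > 1 | g2 < 0 | g2 > 1)
  structure(data.frame(rafh_g1 = clip01(g1), rafh_g2 = clip01(g2)),
            n_clipped = n_clip)
}
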