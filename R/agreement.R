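#' @title Two-grader reliability of RAFH measurements
#' @name agreement
#' @description Bland-Altman limits of agreement, two-way random-effects
#'   intraclass correlation (absolute agreement, single rater), discordance
#'   flagging for the one-round consensus review, and grader averaging.
NULL

check_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (!all(c("rafh_g1", "rafh_g2") %in% names(pairs))) {
    stop("pairs must have columns rafh_g1 and rafh_g2")
  }
  if (anyNA(pairs$rafh_g1) || anyNA(pairs$rafh_g2)) {
    stop("grader pair values may not be missing")
  }
  if (is.null(pairs$image_id)) pairs$image_id <- seq_len(nrow(pairs))
  pairs
}

#' Bland-Altman analysis of two graders
#'
#' Differences are `g1 - g2`; the 95% limits of agreement are the mean
#' difference plus/minus exactly 1.96 sample standard deviations (n-1
#' denominator), the conventional normal-theory multiplier rather than a
#' t quantile.
#'
#' @param pairs data frame with columns `rafh_g1`, `rafh_g2` and optionally
#'   `image_id`.
#' @return list with `n`, `mean_diff`, `sd_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(pairs) {
  pairs <- check_pairs(pairs)
  if (nrow(pairs) < 2) stop("Bland-Altman needs >= 2 pairs")
  d <- pairs$rafh_g1 - pairs$rafh_g2
  m <- mean(d)
  s <- sd(d)
  list(n = length(d), mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

#' Intraclass correlation, two-way random effects, absolute agreement,
#' single rater
#'
#' ICC(A,1) from the two-way ANOVA mean squares of the subjects-by-raters
#' table: with `n` subjects and `k` raters,
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with the F-based confidence interval of McGraw & Wong (Satterthwaite
#' denominator degrees of freedom).
#'
#' @param pairs as in [bland_altman()] (two raters).
#' @param conf confidence level (default 0.95).
#' @return list with `icc`, `icc_ci_low`, `icc_ci_high`, `n`, and a
#'   `degenerate` flag (TRUE, with `icc = NA`, when the ratings carry no
#'   between-subject variance).
#' @export
icc_absolute_agreement <- function(pairs, conf = 0.95) {
  pairs <- check_pairs(pairs)
  n <- nrow(pairs)
  if (n < 5) stop("ICC needs >= 5 pairs")
  x <- cbind(pairs$rafh_g1, pairs$rafh_g2)
  k <- ncol(x)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= .Machine$double.eps) {
    return(list(icc = NA_real_, icc_ci_low = NA_real_,
                icc_ci_high = NA_real_, n = n, degenerate = TRUE))
  }
  icc <- (msr - mse) / denom
  alpha <- 1 - conf
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, icc_ci_low = lo, icc_ci_high = hi, n = n,
       degenerate = FALSE)
}

#' Flag grader-discordant images for consensus review
#'
#' Images whose grader difference falls strictly outside the 95% limits of
#' agreement are flagged for a joint re-grading session (one round, not
#' iterated).
#'
#' @param pairs as in [bland_altman()].
#' @param summary Bland-Altman summary computed on the same pair set.
#' @return list with `flagged_ids`, `n_flagged`, `pct_flagged` (percent of
#'   all images).
#' @export
flag_discordant <- function(pairs, summary) {
  pairs <- check_pairs(pairs)
  d <- pairs$rafh_g1 - pairs$rafh_g2
  out <- d < summary$loa_low | d > summary$loa_high
  list(flagged_ids = pairs$image_id[out],
       n_flagged = sum(out),
       pct_flagged = 100 * sum(out) / nrow(pairs))
}

#' Grader-mean RAFH per image
#'
#' The per-image consensus value used by all downstream analyses:
#' `(g1 + g2) / 2`. Re-graded consensus values should already be
#' substituted into the pair columns.
#'
#' @param pairs as in [bland_altman()].
#' @return numeric vector of per-image means.
#' @export
mean_grader_rafh <- function(pairs) {
  pairs <- check_pairs(pairs)
  (pairs$rafh_g1 + pairs$rafh_g2) / 2
}

#' Full two-grader agreement summary
#'
#' Bland-Altman statistics, ICC(A,1) with confidence interval, and the
#' discordance flags, in one object.
#'
#' @inheritParams bland_altman
#' @param conf confidence level for the ICC interval.
#' @return an `agreement_summary` list combining the pieces.
#' @export
grader_agreement <- function(pairs, conf = 0.95) {
  ba <- bland_altman(pairs)
  icc <- icc_absolute_agreement(pairs, conf)
  fl <- flag_discordant(pairs, ba)
  structure(c(ba, icc[setdiff(names(icc), "n")], fl),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Two-grader agreement (n = %d images)\n",
    "  mean difference: %.4f, LoA [%.4f, %.4f]\n",
    "  ICC(A,1): %.3f (95%% CI %.3f-%.3f)\n",
    "  flagged for consensus: %d (%.1f%%)\n"),
    x$n, x$mean_diff, x$loa_low, x$loa_high,
    x$icc, x$icc_ci_low, x$icc_ci_high, x$n_flagged, x$pct_flagged))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Mean-vs-difference scatter with the mean-difference line (solid) and
#' 95% limits of agreement (dashed).
#'
#' @inheritParams bland_altman
#' @param path optional PNG path; when given the plot is written there.
#' @export
plot_bland_altman <- function(pairs, path = NULL) {
  pairs <- check_pairs(pairs)
  ba <- bland_altman(pairs)
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 700, res = 130)
    on.exit(grDevices::dev.off())
  }
  m <- mean_grader_rafh(pairs)
  d <- pairs$rafh_g1 - pairs$rafh_g2
  plot(m, d, pch = 19, col = "#00000088",
       xlab = "Mean RAFH of graders", ylab = "Grader difference (g1 - g2)",
       main = "Bland-Altman agreement")
  graphics::abline(h = ba$mean_diff, lwd = 2)
  graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 2)
  invisible(ba)
}
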