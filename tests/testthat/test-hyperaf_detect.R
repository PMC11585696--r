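make_rim_fixture <- function(n = 64, scale = 10) {
  ga <- matrix(FALSE, n, n)
  ga[(n %/% 2) + (-3:3), (n %/% 2) + (-3:3)] <- TRUE
  rim <- suppressWarnings(make_rim_band(ga, scale))
  list(ga = ga, rim = rim)
}

test_that("local background is the windowed median of non-GA pixels", {
  fx <- make_rim_fixture()
  img <- faf_image(matrix(100, 64, 64), 10)
  bg <- local_background(img, fx$rim, fx$ga)
  expect_true(all(bg[fx$rim$mask$pixels] == 100))
  expect_true(all(is.na(bg[!fx$rim$mask$pixels])))

  # median is robust to a single hot pixel
  hot <- matrix(0, 64, 64); hot[10, 10] <- 255
  bg2 <- local_background(faf_image(hot, 10), fx$rim, fx$ga)
  expect_true(all(bg2[fx$rim$mask$pixels] == 0))
})

test_that("windowed median equals the brute-force oracle at sampled pixels", {
  set.seed(7)
  fx <- make_rim_fixture()
  img <- faf_image(matrix(sample(0:255, 64 * 64, TRUE), 64, 64), 10)
  win_um <- 250
  bg <- local_background(img, fx$rim, fx$ga, window_um = win_um)
  h <- (round(win_um / 10)) %/% 2
  rim_idx <- which(fx$rim$mask$pixels, arr.ind = TRUE)
  pick <- rim_idx[sample(nrow(rim_idx), 20), , drop = FALSE]
  for (k in seq_len(nrow(pick))) {
    i <- pick[k, 1]; j <- pick[k, 2]
    ii <- max(1, i - h):min(64, i + h)
    jj <- max(1, j - h):min(64, j + h)
    w <- img$pixels[ii, jj]
    expect_equal(bg[i, j], median(w[!fx$ga[ii, jj]]))
  }
})

test_that("global background mode is the constant rim median", {
  set.seed(8)
  fx <- make_rim_fixture()
  img <- faf_image(matrix(sample(0:255, 64 * 64, TRUE), 64, 64), 10)
  bg <- local_background(img, fx$rim, fx$ga, mode = "global")
  rimpx <- fx$rim$mask$pixels
  expect_equal(unique(bg[rimpx]), median(img$pixels[rimpx]))
})

test_that("detection thresholds at background + offset, inclusively", {
  fx <- make_rim_fixture()
  # uniform 100 with a +30 blob: below the +40 offset, nothing detected
  img30 <- matrix(100, 64, 64)
  img30[40:44, 40:44] <- 130
  r30 <- detect_hyperaf(faf_image(img30, 10), fx$ga, fx$rim)
  expect_equal(r30$rafh, 0)

  # +40 exactly is detected (inclusive comparison)
  img40 <- matrix(100, 64, 64)
  img40[40:44, 40:44] <- 140
  r40 <- detect_hyperaf(faf_image(img40, 10), fx$ga, fx$rim)
  blob_in_rim <- sum(fx$rim$mask$pixels[40:44, 40:44])
  expect_equal(sum(r40$hyper_mask$pixels), blob_in_rim)

  expect_error(detect_hyperaf(faf_image(img40, 10), fx$ga, fx$rim,
                              offset = 0), "offset")
  expect_error(detect_hyperaf(faf_image(img40, 10), fx$ga, fx$rim,
                              offset = 255), "offset")
})

test_that("a planted compact blob is recovered at its area fraction", {
  sim <- simulate_faf_image(image_sim_config(target_rafh = 0.10, seed = 21))
  rim <- suppressWarnings(make_rim_band(sim$ga_mask, sim$image$scale))
  res <- detect_hyperaf(sim$image, sim$ga_mask, rim)
  expect_lt(abs(res$rafh - 0.10), 0.02)
})

test_that("RAFH is monotone non-decreasing as the offset decreases", {
  sim <- simulate_faf_image(image_sim_config(target_rafh = 0.15, seed = 3))
  rim <- suppressWarnings(make_rim_band(sim$ga_mask, sim$image$scale))
  rafhs <- vapply(c(80, 60, 40, 20, 10, 5), function(off) {
    detect_hyperaf(sim$image, sim$ga_mask, rim, offset = off)$rafh
  }, numeric(1))
  expect_true(all(diff(rafhs) >= 0))
  expect_true(all(rafhs >= 0 & rafhs <= 1))
})

test_that("RAFH is invariant to resolution within 0.02 on a smooth phantom", {
  ph10 <- sector_phantom(10)
  ph5 <- sector_phantom(5)
  r10 <- detect_hyperaf(ph10$image, ph10$ga, ph10$rim)$rafh
  r5 <- detect_hyperaf(ph5$image, ph5$ga, ph5$rim)$rafh
  expect_lt(abs(r10 - r5), 0.02)
  expect_lt(abs(r10 - 0.1), 0.02)    # sector covers 10% of the annulus
})

test_that("manual edits union, subtract, and clip to the rim", {
  fx <- make_rim_fixture()
  img <- matrix(100, 64, 64)
  img[40:42, 40:42] <- 160
  auto <- detect_hyperaf(faf_image(img, 10), fx$ga, fx$rim)
  expect_gt(auto$rafh, 0)

  # identity
  same <- apply_manual_edits(auto, rim = fx$rim)
  expect_equal(same$rafh, auto$rafh)
  expect_equal(same$hyper_mask$pixels, auto$hyper_mask$pixels)

  # removing everything zeroes RAFH
  gone <- apply_manual_edits(auto, remove = auto$hyper_mask, rim = fx$rim)
  expect_equal(gone$rafh, 0)

  # additions outside the rim are clipped away
  add <- matrix(FALSE, 64, 64)
  add[1:10, 1:10] <- TRUE           # far corner: outside the rim
  add[33, 40] <- TRUE
  added <- apply_manual_edits(auto, add = add, rim = fx$rim)
  in_rim_added <- sum(add & fx$rim$mask$pixels & !auto$hyper_mask$pixels)
  expect_equal(sum(added$hyper_mask$pixels),
               sum(auto$hyper_mask$pixels) + in_rim_added)

  expect_error(apply_manual_edits(auto, add = add, remove = add,
                                  rim = fx$rim), "disjoint")
})

test_that("compute_rafh is the exact pixel-count ratio with guards", {
  rim <- matrix(FALSE, 40, 40); rim[1:25, 1:40] <- TRUE   # 1000 px
  hyper <- matrix(FALSE, 40, 40); hyper[1:25, 1:10] <- TRUE # 250 px
  expect_equal(compute_rafh(hyper, rim), 0.25)
  expect_equal(compute_rafh(rim & FALSE, rim), 0)
  expect_equal(compute_rafh(rim, rim), 1)
  expect_error(compute_rafh(hyper, rim & FALSE), "empty")
  outside <- hyper; outside[30, 30] <- TRUE
  expect_error(compute_rafh(outside, rim), "outside")
})
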