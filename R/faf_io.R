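#' @title Image, mask and cohort-table input/output
#' @name faf_io
#' @description Readers and writers for the package's external formats:
#'   single-channel 8-bit PNG/TIFF images, 0/255 PNG masks, and the
#'   longitudinal cohort CSV. Pixel scale is always explicit; masks are
#'   strictly binary unless a binarization threshold is requested.
NULL

cohort_columns <- c("participant_id", "eye", "arm", "time_years",
                    "rafh_g1", "rafh_g2", "ga_area_mm2", "ga_perimeter_mm",
                    "focus_count", "age", "sex", "bmi", "smoking", "cvd",
                    "faf_pattern_group", "foveal_involvement",
                    "adherence_pct")

read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format '", ext, "' (PNG or TIFF expected)")
  }
}

#' Read a FAF image from PNG or TIFF
#'
#' Multi-channel input is collapsed to a single channel by the unweighted
#' channel mean (with a message). Images with more than 8-bit depth are
#' rejected unless `rescale = TRUE`, in which case the full intensity range
#' is mapped linearly onto \[0, 255\].
#'
#' @param path PNG or TIFF file.
#' @param scale_um_per_px pixel scale in micrometers per pixel; required.
#' @param rescale allow >8-bit input, rescaling to 0-255.
#' @return A [faf_image()].
#' @export
read_faf_image <- function(path, scale_um_per_px, rescale = FALSE) {
  check_scale(scale_um_per_px)
  arr <- read_raster(path)
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] == 4L) arr <- arr[, , 1:3]  # drop alpha
    message("multi-channel image collapsed to grayscale by channel mean: ",
            path)
    arr <- apply(arr, c(1, 2), mean)
  }
  v <- arr * 255
  if (max(abs(v - round(v))) > 1e-6) {
    if (!rescale) {
      stop("image depth exceeds 8 bits; pass rescale = TRUE to map onto 0-255")
    }
    rng <- range(arr)
    v <- if (diff(rng) > 0) (arr - rng[1]) / diff(rng) * 255 else arr * 0
  }
  faf_image(round(v), scale_um_per_px)
}

#' Read a binary mask co-registered to an image
#'
#' Mask PNGs must contain only the values 0 and 255. Anti-aliased or
#' otherwise non-binary masks are rejected unless `binarize_at` (0-255) is
#' given, in which case pixels strictly above the threshold become TRUE.
#'
#' @param path PNG file with values 0/255.
#' @param image the paired [faf_image()]; shapes must agree.
#' @param role mask role tag, see [binary_mask()].
#' @param binarize_at optional threshold for non-binary input.
#' @export
read_mask <- function(path, image, role = "ga", binarize_at = NULL) {
  arr <- read_raster(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  v <- round(arr * 255)
  if (is.null(binarize_at)) {
    bad <- setdiff(unique(as.vector(v)), c(0, 255))
    if (length(bad) > 0) {
      stop("mask contains values other than 0/255 (e.g. ",
           paste(utils::head(bad, 3), collapse = ", "),
           "); pass binarize_at to threshold explicitly")
    }
    px <- v == 255
  } else {
    stopifnot(is.numeric(binarize_at), binarize_at >= 0, binarize_at < 255)
    px <- v > binarize_at
  }
  binary_mask(px, role = role, image = image)
}

#' Write an image or mask as PNG
#'
#' @param x a `faf_image` or `binary_mask`.
#' @param path output PNG path.
#' @export
write_faf_png <- function(x, path) {
  if (inherits(x, "faf_image")) {
    png::writePNG(x$pixels / 255, path)
  } else {
    png::writePNG(mask_pixels(x) * 1, path)
  }
  invisible(path)
}

validate_records <- function(df) {
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  num_cols <- c("time_years", "rafh_g1", "rafh_g2", "ga_area_mm2",
                "ga_perimeter_mm", "focus_count", "age", "bmi",
                "faf_pattern_group", "adherence_pct")
  for (cn in num_cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      vv <- suppressWarnings(as.numeric(v))
      if (any(is.na(vv) & !is.na(v) & v != "")) {
        stop("non-numeric values in column ", cn)
      }
      df[[cn]] <- vv
    }
  }
  if (any(df$time_years < 0, na.rm = TRUE)) stop("time_years must be >= 0")
  for (cn in c("rafh_g1", "rafh_g2")) {
    v <- df[[cn]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) stop(cn, " must lie in [0, 1]")
  }
  if (any(df$ga_area_mm2 <= 0, na.rm = TRUE)) stop("ga_area_mm2 must be > 0")
  if (any(df$ga_perimeter_mm <= 0, na.rm = TRUE)) {
    stop("ga_perimeter_mm must be > 0")
  }
  if (any(df$focus_count < 1, na.rm = TRUE)) stop("focus_count must be >= 1")
  if (!all(df$eye %in% c("OD", "OS"))) stop("eye must be OD or OS")
  if (!all(df$arm %in% c("metformin", "observation"))) {
    stop("arm must be metformin or observation")
  }
  key <- paste(df$participant_id, df$eye, df$time_years)
  if (anyDuplicated(key)) {
    stop("duplicate (participant, eye, time) rows: ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  }
  df
}

#' Read a longitudinal cohort table
#'
#' The CSV must carry the exact column set of the package's cohort schema
#' (see [cohort_schema()]). Rows are grouped by `(participant_id, eye)` and
#' sorted by `time_years`; eyes with a single visit are retained but marked
#' ineligible for growth-rate computation.
#'
#' @param path CSV path.
#' @return A list of `eye_series` objects (per-eye data frames, time-sorted,
#'   with an `eligible` attribute: TRUE when the eye has >= 2 visits).
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  split_eyes(validate_records(df))
}

#' Split a flat cohort table into per-eye series
#'
#' @param records validated cohort data frame.
#' @return list of `eye_series`, named `participant:eye`.
#' @export
split_eyes <- function(records) {
  records <- validate_records(records)
  key <- paste(records$participant_id, records$eye, sep = ":")
  out <- lapply(split(records, key), function(s) {
    s <- s[order(s$time_years), , drop = FALSE]
    rownames(s) <- NULL
    structure(s, class = c("eye_series", "data.frame"),
              eligible = nrow(s) >= 2L)
  })
  out[order(names(out))]
}

#' Flatten a list of eye series back into one table
#' @param series list of `eye_series` from [split_eyes()].
#' @export
bind_series <- function(series) {
  df <- do.call(rbind, lapply(series, as.data.frame))
  rownames(df) <- NULL
  df
}

#' Cohort CSV column names
#' @export
cohort_schema <- function() cohort_columns

#' Write per-visit records to CSV
#'
#' Values round-trip losslessly through [read_cohort_table()] (numerics are
#' written at full precision).
#'
#' @param path output CSV path.
#' @param records flat data frame or list of eye series.
#' @export
write_metrics <- function(path, records) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- bind_series(records)
  }
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data frame")
  }
  if (!dir.exists(dirname(path))) {
    stop("directory does not exist: ", dirname(path))
  }
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
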