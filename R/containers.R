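#' FAF image container
#'
#' An en-face fundus autofluorescence frame: an 8-bit intensity matrix plus
#' the physical pixel scale. All geometry downstream (rim width, areas,
#' perimeters) is derived from `scale`, which must be supplied by the user —
#' it is never read from image headers.
#'
#' @param pixels integer-valued matrix with intensities in \[0, 255\].
#' @param scale_um_per_px physical size of one pixel in micrometers (> 0).
#' @return An object of class `faf_image`: a list with elements `pixels`
#'   (matrix) and `scale` (um/pixel).
#' @examples
#' img <- faf_image(matrix(100L, 32, 32), scale_um_per_px = 10)
#' dim(img$pixels)
#' @export
faf_image <- function(pixels, scale_um_per_px) {
  stopifnot(is.matrix(pixels))
  px <- pixels
  storage.mode(px) <- "double"
  if (anyNA(px) || any(px < 0) || any(px > 255)) {
    stop("image intensities must lie in [0, 255] with no missing values")
  }
  check_scale(scale_um_per_px)
  structure(list(pixels = px, scale = as.numeric(scale_um_per_px)),
            class = "faf_image")
}

check_scale <- function(scale) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("pixel scale (um/pixel) must be a single finite positive number")
  }
  invisible(scale)
}

#' Binary mask co-registered to a FAF image
#'
#' @param pixels logical matrix (TRUE = inside the region).
#' @param role what the mask delineates: the GA lesion, the rim band, a
#'   hyperautofluorescent region, or a manual edit layer.
#' @param image optional `faf_image`; when given, the mask shape is checked
#'   against it.
#' @return Object of class `binary_mask`: list with `pixels` and `role`.
#' @export
binary_mask <- function(pixels, role = c("ga", "rim", "hyper", "edit"),
                        image = NULL) {
  role <- match.arg(role)
  stopifnot(is.matrix(pixels), is.logical(pixels))
  if (anyNA(pixels)) stop("mask may not contain missing values")
  if (!is.null(image)) check_same_grid(pixels, image$pixels)
  structure(list(pixels = pixels, role = role), class = "binary_mask")
}

# Accept a binary_mask or a plain logical matrix; return the logical matrix.
mask_pixels <- function(x) {
  if (inherits(x, "binary_mask")) return(x$pixels)
  if (is.matrix(x) && is.logical(x)) return(x)
  if (is.matrix(x) && is.numeric(x) && all(x %in% c(0, 1))) {
    return(x == 1)
  }
  stop("expected a binary_mask or a logical matrix")
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("grid shapes differ: %s vs %s",
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")))
  }
  invisible(TRUE)
}

#' @export
print.faf_image <- function(x, ...) {
  cat(sprintf("<faf_image> %d x %d px, %.3g um/px, intensity [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), x$scale,
              as.integer(min(x$pixels)), as.integer(max(x$pixels))))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask role=%s> %d x %d px, %d TRUE\n",
              x$role, nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}
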