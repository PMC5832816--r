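#' Binary specimen mask
#'
#' A `binary_mask` is a logical matrix in image orientation (row 1 = top,
#' column 1 = left) where `TRUE` marks object (specimen) pixels and `FALSE`
#' marks background. It is the substrate of every image-based volume
#' estimator in the package; on disk it corresponds to the ImageJ text-image
#' convention of 255 for object and 0 for background.
#'
#' @param x logical matrix, or a numeric matrix containing only 0 and 255
#'   (the text-image encoding), or only 0 and 1.
#' @return An object of class `binary_mask` (a logical matrix).
#' @examples
#' m <- binary_mask(matrix(c(0, 255, 0, 0), 2, 2))
#' n_object(m)
#' @export
binary_mask <- function(x) {
  if (is.logical(x) && is.matrix(x)) {
    m <- x
  } else if (is.numeric(x) && is.matrix(x)) {
    vals <- unique(as.vector(x))
    if (!all(vals %in% c(0, 255)) && !all(vals %in% c(0, 1))) {
      abort("numeric mask values must be {0, 255} or {0, 1}", "invermass_format_error")
    }
    m <- x > 0
  } else {
    abort("a binary mask must be a logical or numeric matrix", "invermass_format_error")
  }
  if (nrow(m) < 1L || ncol(m) < 1L) {
    abort("mask must have at least one row and one column", "invermass_format_error")
  }
  m[is.na(m)] <- FALSE
  structure(m, class = c("binary_mask", class(matrix(logical()))))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d object pixel(s)\n",
              nrow(x), ncol(x), n_object(x)))
  invisible(x)
}

#' Number of object pixels in a mask
#'
#' @param mask a [binary_mask()].
#' @return Integer count of object pixels.
#' @export
n_object <- function(mask) {
  sum(unclass(mask))
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "aligned_mask")) mask <- mask$mask
  if (!inherits(mask, "binary_mask")) mask <- binary_mask(mask)
  unclass(mask)
}

#' Scale calibration
#'
#' Stores the pixel-to-physical scale of an imaging setup as micrometres per
#' pixel. Areas scale with `ratio^2` and volumes with `ratio^3`.
#'
#' @param ratio micrometres per pixel; strictly positive scalar.
#' @return An object of class `scale_calibration`.
#' @examples
#' cal <- scale_calibration(12.5)
#' cal$area_factor   # um^2 per px^2
#' @export
scale_calibration <- function(ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) || ratio <= 0) {
    abort("scale ratio (um per pixel) must be a single positive number",
          "invermass_domain_error")
  }
  structure(
    list(ratio = as.numeric(ratio),
         area_factor = ratio^2,
         volume_factor = ratio^3),
    class = "scale_calibration"
  )
}

as_calibration <- function(calib) {
  if (inherits(calib, "scale_calibration")) return(calib)
  scale_calibration(calib)
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("<scale_calibration> %.6g um/px (area x%.6g, volume x%.6g)\n",
              x$ratio, x$area_factor, x$volume_factor))
  invisible(x)
}

# Object pixel centers as (col, row) coordinates, one row per pixel.
object_coords <- function(mask) {
  m <- as_mask_matrix(mask)
  idx <- which(m, arr.ind = TRUE)
  cbind(col = idx[, 2L], row = idx[, 1L])
}
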