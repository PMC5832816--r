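#' Feret (maximum caliper) orientation of a silhouette
#'
#' Returns the orientation, in degrees within (-90, 90], of the longest
#' distance between any two object-pixel centers. The maximum is exact: it
#' is taken over all pairs of convex-hull vertices. Angles are measured from
#' the horizontal image axis, positive counter-clockwise (so a vertical bar
#' is 90 degrees). Ties are broken towards the smallest absolute angle.
#'
#' @param mask a [binary_mask()] with at least two object pixels.
#' @return Angle in degrees, a single number in (-90, 90].
#' @export
feret_angle <- function(mask) {
  pts <- object_coords(mask)
  if (nrow(pts) < 2L) {
    abort("Feret orientation needs at least 2 object pixels",
          "invermass_degenerate_object_error")
  }
  hull <- pts[unique(chull(pts[, 1L], pts[, 2L])), , drop = FALSE]
  if (nrow(hull) < 2L) hull <- unique(pts)  # degenerate hull (collinear guard)
  dx <- outer(hull[, 1L], hull[, 1L], "-")
  dy <- outer(hull[, 2L], hull[, 2L], "-")
  d2 <- dx^2 + dy^2
  dmax <- max(d2)
  cand <- which(d2 >= dmax - 1e-9, arr.ind = TRUE)
  cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
  # image rows grow downward: flip the sign of the row delta for a
  # mathematical (y up, counter-clockwise positive) angle
  ang <- atan2(-(hull[cand[, 2L], 2L] - hull[cand[, 1L], 2L]),
               hull[cand[, 2L], 1L] - hull[cand[, 1L], 1L]) * 180 / pi
  ang <- ((ang + 90) %% 180) - 90          # fold to (-90, 90]
  ang[ang <= -90] <- ang[ang <= -90] + 180
  unname(ang[which.min(abs(ang))])
}

#' Rotate a binary mask about its object centroid
#'
#' Nearest-neighbour resampling on pixel centers, re-binarized, on a canvas
#' large enough to hold the rotated object. Positive angles rotate the
#' object counter-clockwise (in the usual y-up sense).
#'
#' @param mask a [binary_mask()].
#' @param degrees rotation angle.
#' @return A [binary_mask()] of the rotated object, cropped to its bounding
#'   box plus a 1-pixel margin.
#' @export
rotate_mask <- function(mask, degrees) {
  m <- as_mask_matrix(mask)
  if (!any(m)) abort("cannot rotate an empty mask", "invermass_empty_object_error")
  if (abs(degrees) < 1e-12) return(binary_mask(m))
  th <- degrees * pi / 180
  pts <- object_coords(m)
  cc <- mean(pts[, 1L]); rc <- mean(pts[, 2L])
  # forward map of (col, row) offsets under a CCW rotation with row axis down
  fwd <- function(dc, dr) cbind(dc * cos(th) + dr * sin(th),
                                -dc * sin(th) + dr * cos(th))
  corners <- fwd(c(min(pts[, 1L]), max(pts[, 1L]))[c(1, 1, 2, 2)] - cc,
                 c(min(pts[, 2L]), max(pts[, 2L]))[c(1, 2, 1, 2)] - rc)
  c_lo <- floor(min(corners[, 1L])) - 1L; c_hi <- ceiling(max(corners[, 1L])) + 1L
  r_lo <- floor(min(corners[, 2L])) - 1L; r_hi <- ceiling(max(corners[, 2L])) + 1L
  out_cols <- c_lo:c_hi; out_rows <- r_lo:r_hi
  # inverse map: for every output pixel center, find the source pixel
  dc <- rep(out_cols, each = length(out_rows))
  dr <- rep(out_rows, times = length(out_cols))
  src_c <- round(dc * cos(th) - dr * sin(th) + cc)
  src_r <- round(dc * sin(th) + dr * cos(th) + rc)
  ok <- src_c >= 1L & src_c <= ncol(m) & src_r >= 1L & src_r <= nrow(m)
  val <- logical(length(dc))
  val[ok] <- m[cbind(src_r[ok], src_c[ok])]
  binary_mask(matrix(val, nrow = length(out_rows), ncol = length(out_cols)))
}

# Shoelace area of the convex hull of object-pixel centers, used as a cheap
# convexity (solidity) screen before the revolution integral.
hull_solidity <- function(mask) {
  pts <- object_coords(mask)
  if (nrow(pts) < 3L) return(1)
  h <- pts[chull(pts[, 1L], pts[, 2L]), , drop = FALSE]
  n <- nrow(h)
  if (n < 3L) return(1)
  x <- h[, 1L]; y <- h[, 2L]
  area <- abs(sum(x * y[c(2:n, 1L)] - x[c(2:n, 1L)] * y)) / 2
  if (area <= 0) return(1)
  nrow(pts) / area
}

#' Principal-axis orientation of a silhouette
#'
#' Orientation, in degrees within (-90, 90], of the major principal axis of
#' the object-pixel centers (the eigenvector of their 2D covariance with
#' the larger eigenvalue). For elongated convex bodies this coincides with
#' the Feret direction, but unlike the maximum caliper it is not pulled
#' towards the diagonal of low-aspect shapes, which makes it the less
#' biased choice of revolution axis.
#'
#' @param mask a [binary_mask()] with at least two object pixels.
#' @return Angle in degrees in (-90, 90]; 0 for an isotropic object.
#' @export
principal_angle <- function(mask) {
  pts <- object_coords(mask)
  if (nrow(pts) < 2L) {
    abort("principal orientation needs at least 2 object pixels",
          "invermass_degenerate_object_error")
  }
  x <- pts[, 1L]; y <- -pts[, 2L]           # y up
  cxx <- mean(x^2) - mean(x)^2
  cyy <- mean(y^2) - mean(y)^2
  cxy <- mean(x * y) - mean(x) * mean(y)
  if (abs(cxy) < 1e-12 && abs(cxx - cyy) < 1e-12) return(0)
  ang <- 0.5 * atan2(2 * cxy, cxx - cyy) * 180 / pi
  ang <- ((ang + 90) %% 180) - 90
  if (ang <= -90) ang + 180 else ang
}

#' Align a silhouette so its long axis is horizontal
#'
#' Rotates the object by minus its orientation angle about the object
#' centroid, with nearest-neighbour resampling and re-binarization, so that
#' the long body axis lies along the image columns — the revolution axis of
#' [revolve_volume()]. The orientation is either the principal axis
#' (default; see [principal_angle()]) or the Feret direction
#' ([feret_angle()]), which the two coincide on for elongated bodies.
#'
#' @param mask a [binary_mask()] with at least two object pixels.
#' @param method `"principal"` or `"feret"`.
#' @return An `aligned_mask`: a list with elements `mask` (the rotated
#'   [binary_mask()]) and `rotation_applied` (degrees).
#' @export
align_silhouette <- function(mask, method = c("principal", "feret")) {
  method <- match.arg(method)
  ang <- switch(method, principal = principal_angle(mask), feret = feret_angle(mask))
  rotated <- if (abs(ang) < 1e-9) binary_mask(as_mask_matrix(mask)) else rotate_mask(mask, -ang)
  structure(list(mask = rotated, rotation_applied = -ang),
            class = "aligned_mask")
}

#' Align a silhouette so its Feret diameter is horizontal
#'
#' [align_silhouette()] with `method = "feret"`: rotates by minus the exact
#' maximum-caliper angle. Matches the manual rotate-Feret-horizontal step
#' of an ImageJ workflow.
#'
#' @inheritParams align_silhouette
#' @return An `aligned_mask`; see [align_silhouette()].
#' @export
align_to_feret <- function(mask) {
  align_silhouette(mask, method = "feret")
}

#' @export
print.aligned_mask <- function(x, ...) {
  cat(sprintf("<aligned_mask> rotation applied %.3f deg\n", x$rotation_applied))
  print(x$mask)
  invisible(x)
}

#' Per-column slice diameters of an aligned silhouette
#'
#' Each image column is treated as a one-pixel-wide transversal section.
#' In `"count"` mode (default) the slice diameter is the number of object
#' pixels in the column; in `"extent"` mode it is the top-to-bottom object
#' extent, which ignores interior holes.
#'
#' @param aligned an `aligned_mask` from [align_to_feret()] or a raw
#'   [binary_mask()] already in the desired orientation.
#' @param diameter_mode `"count"` or `"extent"`.
#' @return A `column_profile`: numeric vector of per-column diameters (px),
#'   one entry per mask column.
#' @export
column_profile <- function(aligned, diameter_mode = c("count", "extent")) {
  diameter_mode <- match.arg(diameter_mode)
  m <- as_mask_matrix(aligned)
  d <- if (diameter_mode == "count") {
    colSums(m)
  } else {
    apply(m, 2L, function(col) {
      w <- which(col)
      if (length(w) == 0L) 0 else max(w) - min(w) + 1
    })
  }
  structure(as.numeric(d), class = "column_profile")
}

#' Solid-of-revolution volume of a column profile, in cubic pixels
#'
#' Every column diameter `d` contributes a one-pixel-thick circular slice of
#' volume `pi * (d/2)^2`; the total is their sum.
#'
#' @param profile a `column_profile` (or numeric vector of diameters, px).
#' @return Volume in px^3.
#' @examples
#' revolve_volume_px(c(4))   # pi * 4
#' @export
revolve_volume_px <- function(profile) {
  d <- as.numeric(profile)
  if (any(d < 0)) abort("slice diameters must be non-negative", "invermass_domain_error")
  sum(pi * (d / 2)^2)
}

#' Body volume by the solid-of-revolution method
#'
#' The full image-analysis pipeline for subcircular organisms: the
#' silhouette is rotated so its long axis is horizontal, every column of
#' object pixels is treated as a one-pixel-wide circular slice, slice
#' volumes are summed, and the result is converted to cubic micrometres
#' with the scale calibration. The slices are assumed rotationally
#' symmetric about the horizontal axis, so the method suits straight,
#' symmetrical bodies with convex contours; a markedly non-convex
#' silhouette triggers a warning.
#'
#' @param mask a [binary_mask()] (or `aligned_mask`, in which case no
#'   further rotation is applied).
#' @param calib a [scale_calibration()] or a plain ratio in um/px.
#' @param diameter_mode `"count"` (default) or `"extent"`; see
#'   [column_profile()].
#' @param orientation alignment rule, `"principal"` (default) or
#'   `"feret"`; see [align_silhouette()].
#' @param check_convexity warn when hull solidity falls below 0.9.
#' @return Volume in um^3.
#' @examples
#' shp <- render_disk(60)
#' revolve_volume(shp$mask, scale_calibration(1))   # ~ (4/3) * pi * 60^3
#' @export
revolve_volume <- function(mask, calib, diameter_mode = c("count", "extent"),
                           orientation = c("principal", "feret"),
                           check_convexity = TRUE) {
  diameter_mode <- match.arg(diameter_mode)
  calib <- as_calibration(calib)
  aligned <- if (inherits(mask, "aligned_mask")) mask else
    align_silhouette(mask, match.arg(orientation))
  if (check_convexity) {
    sol <- hull_solidity(aligned$mask)
    if (sol < 0.9) {
      warning(sprintf(paste("silhouette solidity %.2f < 0.9: the revolution method assumes",
                            "convex, symmetrical contours and may overestimate volume"), sol),
              call. = FALSE)
    }
  }
  prof <- column_profile(aligned, diameter_mode)
  revolve_volume_px(prof) * calib$volume_factor
}
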