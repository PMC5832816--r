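#' Ellipsoid approximation of body volume
#'
#' Classical geometric proxy: the body is an ellipsoid with axes equal to
#' maximum body length (BL), maximum body width (BW) and body depth (BD),
#' giving volume `(pi/6) * BL * BW * BD`. In the common field protocol the
#' depth is not measured and is taken equal to BW (the default here) — for a
#' dorso-ventrally flattened animal of true depth D this inflates the
#' estimate by exactly BW/D.
#'
#' @param BL maximum body length, um.
#' @param BW maximum body width, um.
#' @param BD body depth, um; defaults to `BW`.
#' @return Volume in um^3.
#' @examples
#' ellipsoid_volume(2, 1)        # pi/3
#' @export
ellipsoid_volume <- function(BL, BW, BD = BW) {
  check_positive(c(BL = BL, BW = BW, BD = BD))
  (pi / 6) * BL * BW * BD
}

#' Cylinder approximation of body volume
#'
#' The body is a cylinder of length BL with a circular cross-section of
#' diameter BW: `(pi/4) * BW^2 * BL`. With BD = BW this exceeds the
#' ellipsoid approximation by a factor of exactly 1.5.
#'
#' @param BL body (or structure) length, um.
#' @param BW body (or structure) width = section diameter, um.
#' @return Volume in um^3.
#' @examples
#' cylinder_volume(200, 100)     # pi * 50^2 * 200
#' @export
cylinder_volume <- function(BL, BW) {
  check_positive(c(BL = BL, BW = BW))
  (pi / 4) * BW^2 * BL
}

#' Specimen volume from an enlarged clay model (cube-law scaling)
#'
#' A clay replica of the specimen, built at an enlarged scale, displaces a
#' measurable water volume `Vm`; the specimen volume follows from isometric
#' scaling: `Vs = Vm * (Ls / Lm)^3`, where `Lm` and `Ls` are model and
#' specimen lengths in the same unit.
#'
#' @param Vm model displaced volume, ml.
#' @param Lm model length.
#' @param Ls specimen length (same unit as `Lm`).
#' @return Specimen volume in ml.
#' @examples
#' clay_scaled_volume(8, 20, 1)  # 0.001 ml
#' @export
clay_scaled_volume <- function(Vm, Lm, Ls) {
  check_positive(c(Vm = Vm, Lm = Lm, Ls = Ls))
  if (Ls > Lm) {
    warning("specimen length exceeds model length: clay models are expected to be enlarged",
            call. = FALSE)
  }
  Vm * (Ls / Lm)^3
}

#' Convert millilitres to cubic micrometres
#'
#' @param ml volume in ml. 1 ml = 1e12 um^3.
#' @return Volume in um^3.
#' @export
ml_to_um3 <- function(ml) {
  if (any(!is.finite(ml)) || any(ml < 0)) {
    abort("volume in ml must be non-negative and finite", "invermass_domain_error")
  }
  ml * 1e12
}

check_positive <- function(x) {
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    abort(sprintf("%s must be positive and finite",
                  paste(names(x)[bad], collapse = ", ")),
          "invermass_domain_error")
  }
  invisible(TRUE)
}
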