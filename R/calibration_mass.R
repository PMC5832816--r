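#' Calibrate the fine-focus drive against a slide of known thickness
#'
#' Both faces of a reference slide (100 um thick by default) are marked and
#' focused in turn; the number of micrometre-knob divisions between the two
#' focal planes is recorded, typically ten times. The vertical displacement
#' per knob division is the slide thickness divided by the mean count.
#'
#' @param division_counts numeric vector (length >= 1) of repeat counts.
#' @param slide_thickness reference slide thickness, um.
#' @return A `focus_calibration`: list with `slide_thickness`,
#'   `division_counts`, `um_per_division`.
#' @examples
#' calibrate_focus(c(19, 21))$um_per_division  # 5 um per division
#' @export
calibrate_focus <- function(division_counts, slide_thickness = 100) {
  if (length(division_counts) < 1L || any(!is.finite(division_counts)) ||
      any(division_counts <= 0)) {
    abort("division counts must be positive and finite", "invermass_domain_error")
  }
  if (!is.finite(slide_thickness) || slide_thickness <= 0) {
    abort("slide thickness must be positive", "invermass_domain_error")
  }
  structure(list(slide_thickness = slide_thickness,
                 division_counts = as.numeric(division_counts),
                 um_per_division = slide_thickness / mean(division_counts)),
            class = "focus_calibration")
}

#' Specimen thickness from focus-drive divisions
#'
#' @param divisions knob divisions between the focal planes of the lower and
#'   upper specimen surface (> 0).
#' @param cal a [calibrate_focus()] result.
#' @return Thickness in um.
#' @export
thickness_from_divisions <- function(divisions, cal) {
  if (!inherits(cal, "focus_calibration")) {
    abort("cal must come from calibrate_focus()", "invermass_domain_error")
  }
  if (any(!is.finite(divisions)) || any(divisions <= 0)) {
    abort("divisions must be positive", "invermass_domain_error")
  }
  divisions * cal$um_per_division
}

#' Tissue density from mass / displaced-volume trials
#'
#' Each trial weighs a pooled set of rehydrated specimens and measures the
#' water volume it displaces in a graduated cylinder. Density is the mean of
#' the per-trial mass/volume quotients; the quoted absolute error is half
#' the range of the quotients (0 for a single trial), a spread measure, not
#' a standard error.
#'
#' @param mass_g per-trial pooled mass, g.
#' @param volume_ml per-trial displaced volume, ml.
#' @return A `tissue_density`: list with `rho` (g/ml), `abs_error` (g/ml)
#'   and the `trials` data frame.
#' @examples
#' density_from_trials(c(1.03, 1.09), c(1, 1))  # 1.06 +/- 0.03 g/ml
#' @export
density_from_trials <- function(mass_g, volume_ml) {
  if (length(mass_g) != length(volume_ml) || length(mass_g) < 1L) {
    abort("need >= 1 trial with matching mass and volume", "invermass_domain_error")
  }
  if (any(!is.finite(c(mass_g, volume_ml))) || any(mass_g <= 0) || any(volume_ml <= 0)) {
    abort("trial masses and volumes must be positive", "invermass_domain_error")
  }
  q <- mass_g / volume_ml
  structure(list(rho = mean(q),
                 abs_error = (max(q) - min(q)) / 2,
                 trials = data.frame(mass_g = mass_g, volume_ml = volume_ml,
                                     quotient = q)),
            class = "tissue_density")
}

#' @export
print.tissue_density <- function(x, ...) {
  cat(sprintf("<tissue_density> %.3g +/- %.2g g/ml (%d trial(s), half-range error)\n",
              x$rho, x$abs_error, nrow(x$trials)))
  invisible(x)
}

#' Convert body volume to body mass
#'
#' `mass [mg] = volume [um^3] * rho [g/ml] * 1e-9`, since 1 ml = 1e12 um^3
#' and 1 g = 1e3 mg.
#'
#' @param volume_um3 volume in um^3.
#' @param rho tissue density in g/ml, or a [density_from_trials()] result.
#' @return Mass in mg.
#' @examples
#' mass_from_volume(1e9, 1.06)   # 1.06 mg
#' @export
mass_from_volume <- function(volume_um3, rho) {
  if (inherits(rho, "tissue_density")) rho <- rho$rho
  if (any(!is.finite(volume_um3)) || any(volume_um3 <= 0)) {
    abort("volume must be positive (um^3)", "invermass_domain_error")
  }
  if (!is.finite(rho) || rho <= 0) {
    abort("density must be positive (g/ml)", "invermass_domain_error")
  }
  volume_um3 * rho * 1e-9
}

#' Pooled mean individual mass from weighed sets
#'
#' When specimens are too light to weigh singly, sets of individuals are
#' weighed together; the mean individual mass is the unweighted mean over
#' sets of (set mass / set size). With two sets of 20 and 21 individuals
#' this is `((w1/20) + (w2/21)) / 2`.
#'
#' @param set_mass_mg per-set total mass, mg.
#' @param n_individuals per-set number of individuals.
#' @return Mean individual mass, mg.
#' @examples
#' pooled_mean_mass(c(40, 42), c(20, 21))  # 2 mg
#' @export
pooled_mean_mass <- function(set_mass_mg, n_individuals) {
  if (length(set_mass_mg) < 1L || length(set_mass_mg) != length(n_individuals)) {
    abort("need >= 1 set with matching masses and counts", "invermass_domain_error")
  }
  if (any(!is.finite(set_mass_mg)) || any(set_mass_mg <= 0)) {
    abort("set masses must be positive", "invermass_domain_error")
  }
  if (any(n_individuals < 1) || any(n_individuals != round(n_individuals))) {
    abort("set sizes must be positive integers", "invermass_domain_error")
  }
  mean(set_mass_mg / n_individuals)
}
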