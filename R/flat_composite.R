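#' Object area of a silhouette in square micrometres
#'
#' @param mask a [binary_mask()] of the specimen in ventral view.
#' @param calib a [scale_calibration()] or ratio in um/px.
#' @return Area in um^2 (object-pixel count times ratio^2).
#' @export
area_um2 <- function(mask, calib) {
  calib <- as_calibration(calib)
  n <- n_object(mask)
  if (n == 0L) abort("mask contains no object pixels", "invermass_empty_object_error")
  n * calib$area_factor
}

#' Thickness profile from landmark measurements
#'
#' Dorso-ventrally flattened specimens are assigned a mean thickness from
#' measurements at anatomical landmarks (e.g. pharynx, ventral sucker,
#' posterior end of vitellarium for a trematode). The default mean is
#' unweighted; weights can be supplied for landmarks representing unequal
#' body fractions.
#'
#' @param landmarks named (or unnamed) numeric vector of thicknesses, um.
#' @param weights optional non-negative weights, same length as `landmarks`.
#' @return A `thickness_profile`: list with `landmarks` and `mean_thickness`.
#' @export
thickness_profile <- function(landmarks, weights = NULL) {
  if (length(landmarks) < 1L || any(!is.finite(landmarks)) || any(landmarks <= 0)) {
    abort("landmark thicknesses must be positive and finite", "invermass_domain_error")
  }
  mt <- if (is.null(weights)) {
    mean(landmarks)
  } else {
    if (length(weights) != length(landmarks) || any(weights < 0) || sum(weights) <= 0) {
      abort("weights must be non-negative and sum to > 0", "invermass_domain_error")
    }
    sum(landmarks * weights) / sum(weights)
  }
  structure(list(landmarks = landmarks, mean_thickness = mt),
            class = "thickness_profile")
}

#' Flat-section volume: area times mean thickness
#'
#' The volume model for dorso-ventrally flattened organisms: ventral-view
#' area multiplied by the specimen's mean dorso-ventral thickness.
#'
#' @param area area in um^2 (> 0).
#' @param mean_thickness mean thickness in um (> 0), or a
#'   [thickness_profile()].
#' @return Volume in um^3.
#' @examples
#' flat_volume(400, 10)   # 4000 um^3
#' @export
flat_volume <- function(area, mean_thickness) {
  if (inherits(mean_thickness, "thickness_profile")) {
    mean_thickness <- mean_thickness$mean_thickness
  }
  if (!is.numeric(area) || length(area) != 1L || !is.finite(area) || area <= 0) {
    abort("area must be a single positive number (um^2)", "invermass_domain_error")
  }
  if (!is.numeric(mean_thickness) || length(mean_thickness) != 1L ||
      !is.finite(mean_thickness) || mean_thickness <= 0) {
    abort("mean thickness must be a single positive number (um)", "invermass_domain_error")
  }
  area * mean_thickness
}

#' Add the volume of a salient structure to a body volume
#'
#' Accounts for organs that stand proud of the flattened body, such as the
#' ventral sucker of a trematode, as their own area-times-thickness term.
#'
#' @param base body volume in um^3 (> 0).
#' @param structure_area structure area in um^2 (> 0).
#' @param structure_thickness structure thickness in um (> 0).
#' @return `base + structure_area * structure_thickness`, um^3.
#' @export
add_structure_volume <- function(base, structure_area, structure_thickness) {
  vals <- c(base = base, area = structure_area, thickness = structure_thickness)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("base volume and structure measurements must all be positive",
          "invermass_domain_error")
  }
  base + structure_area * structure_thickness
}

#' Declare one body part of a partitioned specimen
#'
#' Complex morphologies are split into parts by transversal section: flat
#' parts (main body regions, appendages) are measured as area times
#' thickness; subcircular parts (e.g. egg strings) as solids of revolution
#' from their own silhouette. `multiplicity` repeats a part, e.g. 2 for a
#' measured member of a bilateral appendage pair.
#'
#' @param name unique part name.
#' @param model `"flat"` or `"revolution"`.
#' @param mask silhouette [binary_mask()]; required for revolution parts,
#'   optional for flat parts when `area` is given directly.
#' @param area area in um^2, for flat parts digitized elsewhere (e.g. via a
#'   drawing tube); ignored when a mask is given.
#' @param thickness thickness in um; required for flat parts.
#' @param multiplicity positive integer number of copies.
#' @return A `body_part`.
#' @export
body_part <- function(name, model = c("flat", "revolution"), mask = NULL,
                      area = NULL, thickness = NULL, multiplicity = 1L) {
  model <- match.arg(model)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("part name must be a non-empty string", "invermass_config_error")
  }
  if (!is.numeric(multiplicity) || length(multiplicity) != 1L ||
      multiplicity < 1 || multiplicity != round(multiplicity)) {
    abort(sprintf("part '%s': multiplicity must be a positive integer", name),
          "invermass_config_error")
  }
  if (model == "flat") {
    if (is.null(thickness) || !is.finite(thickness) || thickness <= 0) {
      abort(sprintf("flat part '%s' requires a positive thickness (um)", name),
            "invermass_config_error")
    }
    if (is.null(mask) && (is.null(area) || !is.finite(area) || area <= 0)) {
      abort(sprintf("flat part '%s' requires a mask or a positive area (um^2)", name),
            "invermass_config_error")
    }
  } else {
    if (is.null(mask)) {
      abort(sprintf("revolution part '%s' requires a silhouette mask", name),
            "invermass_config_error")
    }
  }
  structure(list(name = name, model = model,
                 mask = if (!is.null(mask)) binary_mask(as_mask_matrix(mask)),
                 area = area, thickness = thickness,
                 multiplicity = as.integer(multiplicity)),
            class = "body_part")
}

#' Volume of one body part
#'
#' Flat parts: area (from mask or supplied directly) times thickness.
#' Revolution parts: [revolve_volume()] of the part silhouette. The result
#' is multiplied by the part's multiplicity.
#'
#' @param part a [body_part()].
#' @param calib a [scale_calibration()] or ratio in um/px.
#' @param ... passed to [revolve_volume()] for revolution parts.
#' @return Volume in um^3.
#' @export
part_volume <- function(part, calib, ...) {
  if (!inherits(part, "body_part")) abort("not a body_part", "invermass_config_error")
  calib <- as_calibration(calib)
  v <- tryCatch({
    if (part$model == "flat") {
      a <- if (!is.null(part$mask)) area_um2(part$mask, calib) else part$area
      flat_volume(a, part$thickness)
    } else {
      revolve_volume(part$mask, calib, ...)
    }
  }, invermass_error = function(e) {
    abort(sprintf("part '%s': %s", part$name, conditionMessage(e)), class(e)[1L])
  })
  v * part$multiplicity
}

#' Assemble a partitioned specimen
#'
#' @param specimen_id identifier string.
#' @param parts list of [body_part()] objects with unique names.
#' @param calib a [scale_calibration()] or ratio in um/px.
#' @return A `partitioned_specimen`.
#' @export
partitioned_specimen <- function(specimen_id, parts, calib) {
  if (length(parts) < 1L || !all(vapply(parts, inherits, logical(1), "body_part"))) {
    abort("parts must be a non-empty list of body_part objects", "invermass_config_error")
  }
  nms <- vapply(parts, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    abort("part names must be unique", "invermass_config_error")
  }
  structure(list(specimen_id = as.character(specimen_id), parts = parts,
                 calib = as_calibration(calib)),
            class = "partitioned_specimen")
}

#' Composite volume of a partitioned specimen
#'
#' Sums [part_volume()] over all declared parts — the estimator for complex
#' morphologies combining flat body regions and appendages with subcircular
#' structures such as egg strings.
#'
#' @param specimen a [partitioned_specimen()].
#' @param ... passed to [part_volume()].
#' @return Total volume in um^3.
#' @export
composite_volume <- function(specimen, ...) {
  if (!inherits(specimen, "partitioned_specimen")) {
    abort("not a partitioned_specimen", "invermass_config_error")
  }
  sum(vapply(specimen$parts, part_volume, numeric(1), calib = specimen$calib, ...))
}
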