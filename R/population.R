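# Synthetic specimen populations with known ground truth. Three templates
# cover the three morphologies the estimators target:
#   flatworm — dorso-ventrally flattened body (triaxial ellipsoid, depth a
#              quarter of the width by default), measured by the
#              flat-section method; the classical BD = BW shapes
#              overestimate it by ~width/depth.
#   worm     — elongate subcircular body (prolate spheroid), measured by
#              the solid-of-revolution method.
#   copepod  — partitioned morphology: three flat body regions, eight
#              appendage pairs and two egg strings, measured by the
#              composite method.
# Every specimen also carries a simulated clay-model record (displacement
# read to the resolution of a graduated cylinder) so the cube-law method is
# exercised end to end.

clay_record <- function(true_volume_um3, length_um, scale, read_step_ml) {
  vm_exact <- true_volume_um3 * 1e-12 * scale^3          # ml
  vm <- max(read_step_ml, round(vm_exact / read_step_ml) * read_step_ml)
  list(Vm_ml = vm, Lm = length_um * scale, Ls = length_um)
}

#' Generate a synthetic specimen population with known masses
#'
#' Creates `n` specimens of one morphological template (see the package
#' vignette for what each emulates), each with the raw inputs every
#' applicable estimator needs — silhouette masks, landmark thicknesses,
#' maximum body length/width, partition declarations, clay-model records —
#' plus the analytic ground-truth volume and mass. Reproducible for a given
#' seed.
#'
#' Template defaults mirror the organisms the estimators were designed for:
#' flatworm 4-8 mm long at 10 um/px and density 1.06 g/ml; worm 35-70 mm at
#' 25 um/px and 1.05 g/ml; copepod ~5.5 mm at 5 um/px and 1.15 g/ml.
#'
#' @param n number of specimens (default 20, a typical sample).
#' @param template `"flatworm"`, `"worm"` or `"copepod"`.
#' @param seed integer seed.
#' @param depth_ratio flatworm true depth as a fraction of body width
#'   (default 0.25).
#' @param ratio um/px; template default if `NULL`.
#' @param rho tissue density g/ml; template default if `NULL`.
#' @return A `synthetic_population`: list with `specimens` (each holding its
#'   inputs and `true_volume_um3`, `true_mass_mg`), `template`, `ratio`,
#'   `rho`, `seed`.
#' @export
make_population <- function(n = 20L, template = c("flatworm", "worm", "copepod"),
                            seed = 1L, depth_ratio = 0.25,
                            ratio = NULL, rho = NULL) {
  template <- match.arg(template)
  if (!is.finite(n) || n < 1 || n != round(n)) {
    abort("n must be a positive integer", "invermass_domain_error")
  }
  defaults <- switch(template,
                     flatworm = list(ratio = 10, rho = 1.06),
                     worm     = list(ratio = 25, rho = 1.05),
                     copepod  = list(ratio = 5,  rho = 1.15))
  ratio <- ratio %||% defaults$ratio
  rho <- rho %||% defaults$rho
  if (rho <= 0) abort("rho must be positive", "invermass_domain_error")
  specimens <- with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      id <- sprintf("%s_%02d", template, i)
      switch(template,
             flatworm = synth_flatworm(id, ratio, rho, depth_ratio),
             worm = synth_worm(id, ratio, rho),
             copepod = synth_copepod(id, ratio, rho))
    })
  })
  structure(list(specimens = specimens, template = template, ratio = ratio,
                 rho = rho, seed = seed, n = as.integer(n)),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("<synthetic_population> %d %s specimen(s), %.3g um/px, rho %.3g g/ml, seed %d\n",
              x$n, x$template, x$ratio, x$rho, x$seed))
  invisible(x)
}

synth_flatworm <- function(id, ratio, rho, depth_ratio) {
  BL <- rlnorm(1, log(6000), 0.15)                # um; ~4-8 mm
  a_px <- max(50L, round(BL / (2 * ratio)))
  b_px <- max(15L, round(a_px / 4))               # BW ~ BL/4
  BL_um <- 2 * a_px * ratio
  BW_um <- 2 * b_px * ratio
  D_um <- depth_ratio * BW_um
  # true body: triaxial ellipsoid (BL, BW, D axes)
  true_v <- (pi / 6) * BL_um * BW_um * D_um
  shape <- render_ellipse(a_px, b_px)
  # landmark thicknesses representative of the mean dorso-ventral depth,
  # which for an ellipsoid body is 2/3 of the maximum depth
  landmarks <- setNames((2 / 3) * D_um * (1 + rnorm(3, 0, 0.02)),
                        c("pharynx", "ventral_sucker", "vitellarium_end"))
  clay <- clay_record(true_v, BL_um, scale = runif(1, 16, 19), read_step_ml = 0.05)
  list(id = id, template = "flatworm", mask = shape$mask,
       thickness_landmarks = landmarks,
       BL_um = BL_um, BW_um = BW_um, depth_um = D_um, clay = clay,
       true_volume_um3 = true_v, true_mass_mg = true_v * rho * 1e-9)
}

synth_worm <- function(id, ratio, rho) {
  BL <- rlnorm(1, log(50000), 0.2)                # um; ~35-70 mm
  a_px <- max(200L, round(BL / (2 * ratio)))
  b_px <- max(50L, round(a_px / 20))              # subcircular, BW ~ BL/10
  BL_um <- 2 * a_px * ratio
  BW_um <- 2 * b_px * ratio
  true_v <- (4 / 3) * pi * (BL_um / 2) * (BW_um / 2)^2   # prolate spheroid
  shape <- render_ellipse(a_px, b_px)
  clay <- clay_record(true_v, BL_um, scale = runif(1, 2, 9), read_step_ml = 0.5)
  list(id = id, template = "worm", mask = shape$mask,
       BL_um = BL_um, BW_um = BW_um, clay = clay,
       true_volume_um3 = true_v, true_mass_mg = true_v * rho * 1e-9)
}

synth_copepod <- function(id, ratio, rho) {
  s <- rlnorm(1, 0, 0.1)                          # overall size factor
  body <- data.frame(
    name = c("cephalothorax", "fourth_pedigerous_somite", "genital_abdominal_complex"),
    area = c(3.2e6, 0.5e6, 1.1e6) * s^2,          # um^2
    thickness = c(380, 300, 260) * s              # um
  )
  app <- data.frame(
    name = c("antenna1", "antenna2", "maxilla", "maxilliped",
             "leg1", "leg2", "leg3", "leg4"),
    area = c(2.0e4, 3.0e4, 2.5e4, 6.0e4, 1.2e5, 1.1e5, 9.0e4, 4.0e4) * s^2,
    thickness = c(40, 45, 40, 60, 80, 80, 70, 50) * s
  )
  egg_L_px <- max(100L, round(2500 * s / ratio))
  egg_H_px <- max(20L, round(150 * s / ratio))
  egg <- render_rectangle(egg_L_px, egg_H_px)
  parts <- c(
    lapply(seq_len(nrow(body)), function(k)
      body_part(body$name[k], "flat", area = body$area[k],
                thickness = body$thickness[k])),
    lapply(seq_len(nrow(app)), function(k)
      body_part(app$name[k], "flat", area = app$area[k],
                thickness = app$thickness[k], multiplicity = 2L)),
    list(body_part("egg_strings", "revolution", mask = egg$mask,
                   multiplicity = 2L))
  )
  spec <- partitioned_specimen(id, parts, ratio)
  true_v <- sum(body$area * body$thickness) + 2 * sum(app$area * app$thickness) +
    2 * pi * (egg_H_px / 2)^2 * egg_L_px * ratio^3
  BL_um <- 5500 * s
  BW_um <- 2200 * s
  clay <- clay_record(true_v, BL_um, scale = runif(1, 26, 39), read_step_ml = 0.5)
  list(id = id, template = "copepod", partition = spec,
       egg_L_um = egg_L_px * ratio, egg_D_um = egg_H_px * ratio,
       BL_um = BL_um, BW_um = BW_um, depth_um = 380 * s, clay = clay,
       true_volume_um3 = true_v, true_mass_mg = true_v * rho * 1e-9)
}

#' Run every applicable estimator over a synthetic population
#'
#' Produces the long-format mass table the comparison statistics consume.
#' Method labels follow the field convention: `direct` (ground-truth /
#' weighed mass), `m1` (clay-model cube-law scaling), `m2` (image analysis:
#' flat-section, revolution or composite, whichever suits the template),
#' `m3a`/`m3b` (ellipsoid / cylinder with BD = BW) for flatworms, `m3` for
#' the other templates.
#'
#' @param pop a [make_population()] result.
#' @return A [mass_table()] data frame (`individual_id`, `method`,
#'   `mass_mg`).
#' @export
estimate_population <- function(pop) {
  if (!inherits(pop, "synthetic_population")) {
    abort("pop must come from make_population()", "invermass_domain_error")
  }
  cal <- scale_calibration(pop$ratio)
  rows <- lapply(pop$specimens, function(sp) {
    mass <- function(v_um3) mass_from_volume(v_um3, pop$rho)
    clay_v <- ml_to_um3(clay_scaled_volume(sp$clay$Vm_ml, sp$clay$Lm, sp$clay$Ls))
    est <- switch(sp$template,
      flatworm = c(
        m1 = mass(clay_v),
        m2 = mass(flat_volume(area_um2(sp$mask, cal),
                              mean(sp$thickness_landmarks))),
        m3a = mass(ellipsoid_volume(sp$BL_um, sp$BW_um)),
        m3b = mass(cylinder_volume(sp$BL_um, sp$BW_um))
      ),
      worm = c(
        m1 = mass(clay_v),
        m2 = mass(revolve_volume(sp$mask, cal)),
        m3 = mass(cylinder_volume(sp$BL_um, sp$BW_um))
      ),
      copepod = c(
        m1 = mass(clay_v),
        m2 = mass(composite_volume(sp$partition)),
        m3 = mass(ellipsoid_volume(sp$BL_um, sp$BW_um) +
                    2 * cylinder_volume(sp$egg_L_um, sp$egg_D_um))
      )
    )
    data.frame(individual_id = sp$id,
               method = c("direct", names(est)),
               mass_mg = c(sp$true_mass_mg, unname(est)),
               stringsAsFactors = FALSE)
  })
  mass_table(do.call(rbind, rows))
}
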