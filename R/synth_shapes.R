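# Synthetic silhouettes with analytically known areas and revolution
# volumes. Rasterization rule throughout: a pixel is object iff its center
# lies inside (or on) the ideal shape, which keeps pixel-count area unbiased
# as resolution grows.

new_shape <- function(mask, true_area, true_volume, kind, params) {
  structure(list(mask = mask, true_area = true_area, true_volume = true_volume,
                 kind = kind, params = params),
            class = "synthetic_shape")
}

#' @export
print.synthetic_shape <- function(x, ...) {
  cat(sprintf("<synthetic_shape> %s (%s): area %.6g px^2, revolution volume %.6g px^3\n",
              x$kind, paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
              x$true_area, x$true_volume))
  invisible(x)
}

#' Rasterized disk with analytic sphere volume
#'
#' @param r_px radius in pixels (>= 1).
#' @param pad background margin in pixels.
#' @return A `synthetic_shape` with `mask`, `true_area` (`pi r^2`, px^2) and
#'   `true_volume` (`(4/3) pi r^3`, px^3 — the sphere obtained under
#'   revolution).
#' @export
render_disk <- function(r_px, pad = 2L) {
  if (!is.finite(r_px) || r_px < 1) abort("radius must be >= 1 px", "invermass_domain_error")
  n <- 2L * ceiling(r_px) + 1L + 2L * pad
  ctr <- (n + 1L) / 2
  dc <- matrix(rep(seq_len(n) - ctr, each = n), n, n)
  dr <- matrix(rep(seq_len(n) - ctr, times = n), n, n)
  mask <- binary_mask(dc^2 + dr^2 <= r_px^2)
  new_shape(mask, pi * r_px^2, (4 / 3) * pi * r_px^3, "disk", list(r_px = r_px))
}

#' Rasterized solid rectangle with analytic cylinder volume
#'
#' @param L_px horizontal length in pixels.
#' @param H_px vertical height in pixels.
#' @param pad background margin in pixels.
#' @return A `synthetic_shape`; `true_volume = pi (H/2)^2 L` (the cylinder
#'   obtained under revolution about the horizontal axis), `true_area = L*H`.
#' @export
render_rectangle <- function(L_px, H_px, pad = 2L) {
  if (any(!is.finite(c(L_px, H_px))) || L_px < 1 || H_px < 1) {
    abort("rectangle sides must be >= 1 px", "invermass_domain_error")
  }
  L <- as.integer(round(L_px)); H <- as.integer(round(H_px))
  m <- matrix(FALSE, H + 2L * pad, L + 2L * pad)
  m[pad + seq_len(H), pad + seq_len(L)] <- TRUE
  new_shape(binary_mask(m), L * H, pi * (H / 2)^2 * L, "rectangle",
            list(L_px = L, H_px = H))
}

#' Rasterized filled ellipse with analytic prolate-spheroid volume
#'
#' The semi-major axis `a_px` is horizontal, so revolution about the
#' horizontal axis yields a prolate spheroid of volume `(4/3) pi a b^2`.
#'
#' @param a_px horizontal semi-axis, px.
#' @param b_px vertical semi-axis, px.
#' @param pad background margin in pixels.
#' @return A `synthetic_shape` with `true_area = pi a b`.
#' @export
render_ellipse <- function(a_px, b_px, pad = 2L) {
  if (any(!is.finite(c(a_px, b_px))) || a_px < 1 || b_px < 1) {
    abort("ellipse semi-axes must be >= 1 px", "invermass_domain_error")
  }
  nc <- 2L * ceiling(a_px) + 1L + 2L * pad
  nr <- 2L * ceiling(b_px) + 1L + 2L * pad
  cc <- (nc + 1L) / 2; rc <- (nr + 1L) / 2
  dc <- matrix(rep(seq_len(nc) - cc, each = nr), nr, nc)
  dr <- matrix(rep(seq_len(nr) - rc, times = nc), nr, nc)
  mask <- binary_mask((dc / a_px)^2 + (dr / b_px)^2 <= 1)
  new_shape(mask, pi * a_px * b_px, (4 / 3) * pi * a_px * b_px^2, "ellipse",
            list(a_px = a_px, b_px = b_px))
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

shift_mask <- function(m, dr, dc) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)); cs <- seq_len(ncol(m))
  r_src <- rs - dr; c_src <- cs - dc
  rok <- r_src >= 1L & r_src <= nrow(m); cok <- c_src >= 1L & c_src <= ncol(m)
  out[rs[rok], cs[cok]] <- m[r_src[rok], c_src[cok]]
  out
}

boundary_band <- function(m) {
  nb_bg <- !shift_mask(m, 1L, 0L) | !shift_mask(m, -1L, 0L) |
    !shift_mask(m, 0L, 1L) | !shift_mask(m, 0L, -1L)
  nb_obj <- shift_mask(m, 1L, 0L) | shift_mask(m, -1L, 0L) |
    shift_mask(m, 0L, 1L) | shift_mask(m, 0L, -1L)
  (m & nb_bg) | (!m & nb_obj)
}

#' Degrade a mask with boundary jitter and interior holes
#'
#' Emulates segmentation noise: pixels within `edge_jitter_px` of the
#' object boundary are toggled with probability 0.5, and interior object
#' pixels (all four neighbours object) are punched out with probability
#' `hole_rate`. Deterministic for a given seed; with both rates zero the
#' mask is returned unchanged.
#'
#' @param mask a [binary_mask()].
#' @param edge_jitter_px width of the boundary band to jitter (integer >= 0).
#' @param hole_rate per-pixel interior hole probability in `[0, 1]`.
#' @param seed integer seed.
#' @return A [binary_mask()].
#' @export
perturb <- function(mask, edge_jitter_px = 0, hole_rate = 0, seed = 1L) {
  if (edge_jitter_px < 0 || hole_rate < 0 || hole_rate > 1) {
    abort("edge_jitter_px must be >= 0 and hole_rate in [0, 1]", "invermass_domain_error")
  }
  m <- as_mask_matrix(mask)
  if (edge_jitter_px == 0 && hole_rate == 0) return(binary_mask(m))
  with_local_seed(seed, {
    for (k in seq_len(round(edge_jitter_px))) {
      band <- which(boundary_band(m))
      flip <- band[runif(length(band)) < 0.5]
      m[flip] <- !m[flip]
    }
    if (hole_rate > 0) {
      interior <- m & shift_mask(m, 1L, 0L) & shift_mask(m, -1L, 0L) &
        shift_mask(m, 0L, 1L) & shift_mask(m, 0L, -1L)
      idx <- which(interior)
      m[idx[runif(length(idx)) < hole_rate]] <- FALSE
    }
  })
  binary_mask(m)
}
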