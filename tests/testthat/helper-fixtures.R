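# Build a binary mask from a compact string sketch: 'X' = object, '.' =
# background, one image row per line.
mask_sketch <- function(txt) {
  lines <- strsplit(txt, "\n")[[1]]
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(trimws(lines), function(l) strsplit(l, "")[[1]] == "X")
  binary_mask(do.call(rbind, rows))
}

# Independent brute-force Feret oracle: maximum pairwise distance over ALL
# object pixel centers (no convex hull), angle of the first maximal pair
# folded to (-90, 90].
feret_brute <- function(mask) {
  pts <- which(unclass(mask), arr.ind = TRUE)   # (row, col)
  best <- -1; best_ang <- NA_real_
  n <- nrow(pts)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dc <- pts[j, 2] - pts[i, 2]
      dr <- pts[j, 1] - pts[i, 1]
      d2 <- dc^2 + dr^2
      ang <- atan2(-dr, dc) * 180 / pi
      ang <- ((ang + 90) %% 180) - 90
      if (ang <= -90) ang <- ang + 180
      if (d2 > best + 1e-9 ||
          (abs(d2 - best) <= 1e-9 && abs(ang) < abs(best_ang))) {
        best <- d2; best_ang <- ang
      }
    }
  }
  unname(best_ang)
}

# Random small mask for round-trip / property tests.
random_mask <- function(nr, nc, p = 0.4) {
  binary_mask(matrix(runif(nr * nc) < p, nr, nc))
}
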