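test_that("feret_angle matches axis-aligned and diagonal bars", {
  horiz <- binary_mask(matrix(TRUE, 1, 10))
  expect_equal(feret_angle(horiz), 0)
  vert <- binary_mask(matrix(TRUE, 10, 1))
  expect_equal(feret_angle(vert), 90)

  diag <- binary_mask(diag(10) > 0)      # runs down-right
  expect_equal(feret_angle(diag), feret_brute(diag))
  expect_equal(abs(feret_angle(diag)), 45, tolerance = 1)

  two_px <- binary_mask(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_equal(feret_angle(two_px), 90)   # vertical neighbour pair
  expect_error(feret_angle(binary_mask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))),
               class = "invermass_degenerate_object_error")
})

test_that("feret_angle agrees with the all-pairs brute force on random blobs", {
  set.seed(5)
  for (k in 1:4) {
    m <- largest_component(random_mask(15, 15, 0.4))
    if (n_object(m) < 2) next
    expect_equal(feret_angle(m), feret_brute(m), tolerance = 1e-8)
  }
})

test_that("principal_angle orients bars and ellipses like the Feret axis", {
  expect_equal(principal_angle(binary_mask(matrix(TRUE, 1, 10))), 0)
  expect_equal(principal_angle(binary_mask(matrix(TRUE, 10, 1))), 90)
  expect_equal(principal_angle(binary_mask(diag(10) > 0)), -45, tolerance = 1e-6)
  e <- render_ellipse(80, 30)$mask
  expect_equal(principal_angle(e), 0, tolerance = 0.5)
  expect_equal(principal_angle(rotate_mask(e, 25)), 25, tolerance = 0.5)
})

test_that("alignment renders the long axis horizontal and conserves pixels", {
  horiz <- binary_mask(matrix(TRUE, 1, 10))
  al <- align_to_feret(horiz)
  expect_equal(al$rotation_applied, 0)
  expect_identical(unclass(al$mask), unclass(horiz))

  diag <- binary_mask(diag(10) > 0)
  al <- align_to_feret(diag)
  prof <- column_profile(al)
  occupied <- sum(prof > 0)
  # a 45-degree bar of 10 px spans ~ 10 * sqrt(2) when laid horizontal
  expect_equal(occupied, round(9 * sqrt(2)) + 1, tolerance = 1.01)
  expect_lte(max(prof), 2)

  disk <- render_disk(50)$mask
  for (ang in c(15, 45, 77)) {
    rot <- rotate_mask(disk, ang)
    expect_lt(abs(n_object(rot) - n_object(disk)) / n_object(disk), 0.05)
  }
})

test_that("column_profile counts object pixels per column", {
  full <- binary_mask(matrix(TRUE, 3, 3))
  expect_equal(as.numeric(column_profile(full)), c(3, 3, 3))
  empty <- binary_mask(matrix(FALSE, 2, 4))
  expect_equal(as.numeric(column_profile(empty)), rep(0, 4))
  expect_equal(sum(column_profile(full)), n_object(full))

  disk <- render_disk(50)$mask
  center <- max(column_profile(disk))
  expect_lt(abs(center - 101), 2.5)      # analytic chord 2r + 1
})

test_that("count and extent diameter modes differ only on interior holes", {
  m <- render_disk(40)$mask
  holey <- perturb(m, hole_rate = 0.02, seed = 3)
  expect_equal(as.numeric(column_profile(holey, "extent")),
               as.numeric(column_profile(m, "extent")))
  expect_lt(sum(column_profile(holey, "count")), sum(column_profile(m, "count")))
})

test_that("revolve_volume_px implements the slice-sum formula", {
  expect_equal(revolve_volume_px(c(4)), pi * 4)
  expect_equal(revolve_volume_px(numeric(0)), 0)
  expect_error(revolve_volume_px(c(3, -1)), class = "invermass_domain_error")
  # monotone: growing any column never decreases volume
  set.seed(2)
  d <- sample(0:30, 20, replace = TRUE)
  for (k in 1:5) {
    i <- sample(20, 1)
    d2 <- d; d2[i] <- d2[i] + sample(1:5, 1)
    expect_gte(revolve_volume_px(d2), revolve_volume_px(d))
  }
})

test_that("revolution volume matches sphere, cylinder and spheroid oracles", {
  disk <- render_disk(100)
  v <- revolve_volume(disk$mask, scale_calibration(1))
  expect_lt(abs(v - disk$true_volume) / disk$true_volume, 0.015)

  rect <- render_rectangle(200, 100)
  vr <- revolve_volume(rect$mask, 1)
  expect_lt(abs(vr - rect$true_volume) / rect$true_volume, 0.01)

  ell <- render_ellipse(150, 60)
  ve <- revolve_volume(ell$mask, 1)
  expect_lt(abs(ve - ell$true_volume) / ell$true_volume, 0.02)
})

test_that("volume scales cubically with the calibration ratio", {
  disk <- render_disk(60)
  v1 <- revolve_volume(disk$mask, 1)
  v2 <- revolve_volume(disk$mask, 2)
  expect_equal(v2, 8 * v1)
})

test_that("volume is exactly invariant under mask flips", {
  ell <- render_ellipse(70, 30)$mask
  m <- unclass(ell)
  v <- revolve_volume(ell, 1)
  expect_equal(revolve_volume(binary_mask(m[nrow(m):1, ]), 1), v)
  expect_equal(revolve_volume(binary_mask(m[, ncol(m):1]), 1), v)
})

test_that("pre-rotation followed by alignment changes volume by < 3%", {
  shapes <- list(render_rectangle(150, 70)$mask, render_ellipse(100, 40)$mask)
  for (m in shapes) {
    v0 <- revolve_volume(m, 1)
    for (ang in c(10, 35, 80)) {
      v <- revolve_volume(rotate_mask(m, ang), 1)
      expect_lt(abs(v - v0) / v0, 0.03)
    }
  }
})

test_that("half-ellipse profile revolves to the prolate spheroid", {
  ell <- render_ellipse(60, 50)
  v <- revolve_volume(ell$mask, 1)
  expect_lt(abs(v - (4 / 3) * pi * 60 * 50^2) / ((4 / 3) * pi * 60 * 50^2), 0.02)
})

test_that("markedly non-convex silhouettes trigger a solidity warning", {
  cross <- mask_sketch(paste(
    c(rep("........XXXX........", 8),
      rep("XXXXXXXXXXXXXXXXXXXX", 4),
      rep("........XXXX........", 8)), collapse = "\n"))
  expect_warning(revolve_volume(cross, 1), "solidity")
  expect_silent(v <- revolve_volume(render_disk(30)$mask, 1))
})

test_that("degenerate objects propagate an error through the pipeline", {
  one_px <- binary_mask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_error(revolve_volume(one_px, 1), class = "invermass_degenerate_object_error")
})
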