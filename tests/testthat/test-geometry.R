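# Equatorial frame: circle fit, pole, spheroid refinement, alignment, angles.

test_that("three-point circle fit recovers constructed circles exactly", {
  # canonical unit circle
  fit <- fit_circle_3pt(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0))
  expect_equal(fit$C, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit$radius, 1, tolerance = 1e-12)
  expect_equal(abs(fit$n), c(0, 0, 1), tolerance = 1e-12)

  # analytic circumcircle oracle on arbitrary circles
  for (s in 1:6) {
    set.seed(s)
    C0 <- runif(3, -50, 50); r0 <- runif(1, 2, 40); n0 <- rnorm(3)
    n0 <- n0 / sqrt(sum(n0^2))
    p <- circle_points(C0, r0, n0, sort(runif(3, 0, 360)))
    fit <- fit_circle_3pt(p[1, ], p[2, ], p[3, ])
    expect_equal(fit$C, C0, tolerance = 1e-9)
    expect_equal(fit$radius, r0, tolerance = 1e-9)
    expect_equal(abs(sum(fit$n * n0)), 1, tolerance = 1e-9)
  }
})

test_that("collinear landmarks raise the degenerate-landmarks error", {
  expect_error(
    fit_circle_3pt(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
    "degenerate landmarks"
  )
  expect_error(
    fit_circle_3pt(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
    "degenerate landmarks"
  )
})

test_that("normal orientation points toward the data hemisphere", {
  set.seed(1)
  pts <- cbind(rnorm(100), rnorm(100), runif(100, 1, 3))  # all z > 0
  expect_equal(orient_normal(pts, c(0, 0, 0), c(0, 0, -1)), c(0, 0, 1))
  expect_equal(orient_normal(pts, c(0, 0, 0), c(0, 0, 1)), c(0, 0, 1))
  balanced <- rbind(c(0, 0, 1), c(0, 0, -1))
  expect_error(orient_normal(balanced, c(0, 0, 0), c(0, 0, 1)), "ambiguous")
})

test_that("anterior pole selection follows the ray rule", {
  pts <- rbind(
    c(0, 0, 700),      # exactly on the +z ray
    c(300, 0, 650), c(-200, 100, 600), c(0, 0, -100)
  )
  ap <- find_anterior_pole(pts, C = c(0, 0, 0), n = c(0, 0, 1), R_max = 1000)
  expect_equal(ap$index, 1L)
  expect_equal(ap$t, 700)
  expect_equal(sqrt(sum((ap$AP - c(0, 0, 0))^2)), 700)

  expect_error(
    find_anterior_pole(matrix(numeric(), 0, 3), c(0, 0, 0), c(0, 0, 1), 1000),
    "empty"
  )
  expect_error(
    find_anterior_pole(rbind(c(500, 0, 100)), c(0, 0, 0), c(0, 0, 1), 1000),
    "no pole found"
  )
})

test_that("radial distances are the landmark/pole distances and scale", {
  lm <- circle_points(c(0, 0, 0), 1, c(0, 0, 1), c(0, 120, 240))
  pts <- rbind(lm, c(0, 0, 1), c(0.1, 0, 0.98), c(-0.1, 0.05, 0.97))
  frame <- build_frame(pts, lm)
  expect_equal(unname(radial_distances(frame)), rep(1, 4), tolerance = 1e-9)

  frame2 <- build_frame(pts * 2, lm * 2)
  expect_equal(
    unname(radial_distances(frame2)),
    2 * unname(radial_distances(frame)),
    tolerance = 1e-9
  )
})

test_that("the geometric pipeline recovers preset radii and aspect ratio", {
  for (preset in c("mature", "young")) {
    cfg <- lens_preset(preset, seed = 1)
    truth <- sample_epithelium(cfg)
    pts <- mounted_points(truth)
    frame <- build_frame(pts, gz_mr_landmarks(cfg))
    expect_equal(frame$R_max, cfg$r_max, tolerance = 1e-6)
    expect_equal(frame$R_min, cfg$r_min, tolerance = 1e-6)
    met <- lens_metrics(frame)
    expect_equal(met$aspect_ratio, cfg$r_min / cfg$r_max, tolerance = 0.02)
    # landmark circle sits at the planted GZ/MR boundary latitude
    th <- cfg$theta_mr_start * pi / 180
    expect_equal(frame$circle_radius, cfg$r_max * sin(th), tolerance = 1e-6)
    expect_equal(unname(frame$D[1:3]), rep(frame$circle_radius, 3),
                 tolerance = 1e-9)
  }
})

test_that("anterior pole lands near the true pole on the mature phantom", {
  cfg <- lens_preset("mature", seed = 1)
  truth <- sample_epithelium(cfg)
  pts <- mounted_points(truth)
  frame <- build_frame(pts, gz_mr_landmarks(cfg))
  mapped <- map_points(pts, frame)
  expect_lt(mapped$theta_deg[frame$ap_index], 2)
})

test_that("canonical alignment is rigid and sends the axis to +z", {
  cfg <- lens_preset("mature", seed = 2)
  truth <- sample_epithelium(cfg)
  pts <- mounted_points(truth)
  frame <- build_frame(pts, gz_mr_landmarks(cfg))
  aligned <- align_to_canonical(pts, frame)
  xyz0 <- as.matrix(pts[, c("x_um", "y_um", "z_um")])
  xyz1 <- as.matrix(aligned[, c("x_um", "y_um", "z_um")])
  idx <- seq(1, nrow(xyz0), by = 23)
  expect_equal(as.vector(dist(xyz1[idx, ])), as.vector(dist(xyz0[idx, ])),
               tolerance = 1e-9)
  n_aligned <- attr(aligned, "rotation") %*% frame$n
  expect_equal(as.vector(n_aligned), c(0, 0, 1), tolerance = 1e-12)

  # already-canonical data: identity transform
  lm_aligned <- sweep(frame$landmarks, 2, frame$center) %*%
    t(attr(aligned, "rotation"))
  frame2 <- build_frame(aligned, lm_aligned)
  aligned2 <- align_to_canonical(aligned, frame2)
  expect_equal(
    as.matrix(aligned2[, c("x_um", "y_um", "z_um")]), xyz1,
    tolerance = 1e-6, ignore_attr = TRUE
  )
})

test_that("spherical coordinates satisfy the defining landmarks", {
  # anterior pole maps to theta 0; a true-equator point maps to theta 90
  sph <- spherical_coordinates(
    rbind(c(0, 0, 700), c(1000, 0, 0), c(0, -1000, 0)),
    R_max = 1000, R_min = 700
  )
  expect_equal(sph$theta_deg, c(0, 90, 90), tolerance = 1e-12)
  expect_equal(sph$phi_deg[2:3], c(0, 270), tolerance = 1e-12)
  expect_error(
    spherical_coordinates(rbind(c(0, 0, 0)), 1000, 700),
    "undefined angle"
  )
})

test_that("assigned angles reproduce the generator's truth", {
  cfg <- lens_preset("mature", seed = 3)
  truth <- sample_epithelium(cfg)
  pts <- mounted_points(truth)
  mapped <- map_points(pts, build_frame(pts, gz_mr_landmarks(cfg)))
  expect_lt(sqrt(mean((mapped$theta_deg - truth$true_theta_deg)^2)), 1)
  dphi <- (mapped$phi_deg - truth$true_phi_deg + 180) %% 360 - 180
  expect_lt(sqrt(mean(dphi^2)), 1)
})

test_that("mapping is invariant to rigid motions of the acquisition frame", {
  cfg <- lens_preset("mature", seed = 4)
  truth <- sample_epithelium(cfg)
  pts <- mounted_points(truth)
  lm <- gz_mr_landmarks(cfg)
  base_frame <- build_frame(pts, lm)
  base <- map_points(pts, base_frame)
  base_met <- lens_metrics(base_frame)
  xyz <- as.matrix(pts[, c("x_um", "y_um", "z_um")])
  for (s in 1:3) {
    mo <- random_rigid_motion(100 + s)
    pts2 <- pts
    pts2[, c("x_um", "y_um", "z_um")] <- apply_rigid(xyz, mo)
    frame2 <- build_frame(pts2, apply_rigid(lm, mo))
    mapped2 <- map_points(pts2, frame2)
    expect_equal(mapped2$theta_deg, base$theta_deg, tolerance = 1e-6)
    dphi <- (mapped2$phi_deg - base$phi_deg + 180) %% 360 - 180
    expect_lt(max(abs(dphi)), 1e-6)
    met2 <- lens_metrics(frame2)
    expect_equal(met2$aspect_ratio, base_met$aspect_ratio, tolerance = 1e-6)
    expect_equal(met2$hemisphere_volume, base_met$hemisphere_volume,
                 tolerance = 1e-6)
  }
})

test_that("lens metrics follow the spheroid formulas", {
  met <- lens_metrics(list(R_max = 1, R_min = 1))
  expect_equal(met$aspect_ratio, 1)
  expect_equal(met$hemisphere_volume, 2 * pi / 3, tolerance = 1e-12)
  expect_equal(met$spheroid_volume, 4 * pi / 3, tolerance = 1e-12)
  expect_error(lens_metrics(list(R_max = -1, R_min = 1)), "positive")
})
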