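# Phantom generator: planted density, Poisson sampling, tilt, rendering.

test_that("constant-density cap count matches the closed-form Poisson mean", {
  # d(theta) = D everywhere on a hemisphere of radius r: mean = D * 2 pi r^2
  D <- 0.5; r <- 600
  cfg <- synth_config(
    r_max = r, r_min = r, theta_cz_flat = 30, theta_cz_end = 40,
    theta_peak = 60, mr_fraction = 0, theta_edge = 90,
    d_pole = D, d_cz = D, d_peak = D, d_mr = D, seed = 11
  )
  expected <- D / 1000 * cap_area(90, r)
  expect_equal(expected_cell_count(cfg), expected, tolerance = 1e-12)
  counts <- vapply(1:8, function(s) {
    cfg$seed <- s
    nrow(sample_epithelium(cfg))
  }, numeric(1))
  expect_true(all(abs(counts - expected) < 4 * sqrt(expected)))
})

test_that("expected_cell_count agrees with numerical quadrature", {
  for (preset in c("mature", "young")) {
    cfg <- lens_preset(preset)
    nodes <- sort(unique(c(0, cfg$theta_cz_flat, cfg$theta_cz_end,
                           cfg$theta_peak, cfg$theta_mr_start,
                           cfg$theta_edge)))
    num <- 0
    for (i in seq_len(length(nodes) - 1)) {
      num <- num + integrate(
        function(th) planted_density(cfg, th) * sin(th * pi / 180) * pi / 180,
        nodes[i], nodes[i + 1], rel.tol = 1e-10
      )$value
    }
    num <- num * 2 * pi * cfg$r_max^2 / 1000
    expect_equal(expected_cell_count(cfg), num, tolerance = 1e-7)
  }
})

test_that("zero planted densities give an empty epithelium", {
  cfg <- synth_config(d_pole = 0, d_cz = 0, d_peak = 0, d_mr = 0, seed = 1)
  expect_equal(nrow(sample_epithelium(cfg)), 0L)
})

test_that("per-zone counts track the planted density integrals", {
  cfg <- lens_preset("mature", seed = 5)
  truth <- sample_epithelium(cfg)
  zone_mean <- function(lo, hi) {
    integrate(
      function(th) planted_density(cfg, th) * sin(th * pi / 180) * pi / 180,
      lo, hi, rel.tol = 1e-9
    )$value * 2 * pi * cfg$r_max^2 / 1000
  }
  expected <- c(
    CZ = zone_mean(0, cfg$theta_cz_end),
    GZ = zone_mean(cfg$theta_cz_end, cfg$theta_mr_start),
    MR = zone_mean(cfg$theta_mr_start, cfg$theta_edge)
  )
  observed <- table(factor(truth$true_zone, names(expected)))
  expect_true(all(abs(observed - expected) / expected < 0.10))
})

test_that("ground truth lies exactly on the spheroid and inside the cap", {
  cfg <- lens_preset("young", seed = 3)
  truth <- sample_epithelium(cfg)
  res <- truth$x_um^2 / cfg$r_max^2 + truth$y_um^2 / cfg$r_max^2 +
    truth$z_um^2 / cfg$r_min^2
  expect_lt(max(abs(res - 1)), 1e-9)
  expect_true(all(truth$true_theta_deg >= 0 &
                    truth$true_theta_deg <= cfg$theta_edge))
})

test_that("sampling and rendering are bit-reproducible for a fixed seed", {
  cfg <- small_mature(seed = 9)
  t1 <- sample_epithelium(cfg); t2 <- sample_epithelium(cfg)
  expect_identical(t1$x_um, t2$x_um)
  g1 <- render_stack(t1, cfg); g2 <- render_stack(t2, cfg)
  expect_identical(g1$data, g2$data)
})

test_that("tilt is a rigid rotation: identity, period and inverse", {
  cfg <- lens_preset("mature", seed = 2)
  truth <- sample_epithelium(cfg)
  xyz <- as.matrix(truth[, c("x_um", "y_um", "z_um")])
  expect_equal(coord_od <- as.matrix(apply_tilt(truth, 0)[, c("x_um", "y_um", "z_um")]),
               xyz, tolerance = 1e-15)
  expect_equal(
    as.matrix(apply_tilt(truth, 360)[, c("x_um", "y_um", "z_um")]),
    xyz, tolerance = 1e-9
  )
  back <- apply_tilt(apply_tilt(truth, 35), -35)
  expect_equal(as.matrix(back[, c("x_um", "y_um", "z_um")]), xyz,
               tolerance = 1e-9)
  tilted <- apply_tilt(truth, 35)
  expect_equal(
    sqrt(rowSums(as.matrix(tilted[, c("x_um", "y_um", "z_um")])^2)),
    sqrt(rowSums(xyz^2)), tolerance = 1e-9
  )
})

test_that("meridional-row cells sit on a regular azimuthal lattice", {
  cfg <- lens_preset("mature", seed = 4)
  truth <- sample_epithelium(cfg)
  mr <- truth[truth$true_zone == "MR", ]
  mid <- (cfg$theta_mr_start + cfg$theta_edge) / 2
  n_col <- max(8, round(2 * pi * cfg$r_max * sin(mid * pi / 180) /
                          cfg$mr_column_pitch_um))
  pitch <- 360 / n_col
  offs <- mr$true_phi_deg / pitch
  expect_lt(max(abs(offs - round(offs))), 1e-9)
})

test_that("infeasible MR fraction is rejected as a config error", {
  expect_error(
    synth_config(theta_peak = 90, theta_edge = 95, mr_fraction = 0.9),
    "infeasible mr_fraction"
  )
})

test_that("a single rendered nucleus peaks at the planted voxel", {
  cfg <- synth_config(
    r_max = 30, r_min = 30, theta_cz_flat = 10, theta_cz_end = 20,
    theta_peak = 50, mr_fraction = 0, theta_edge = 90,
    d_pole = 0, d_cz = 0, d_peak = 0, d_mr = 0,
    noise_sd = 0, tilt_deg = 0, spacing = c(1000, 1000, 2000), seed = 1
  )
  truth <- point_table(x_um = 5, y_um = -3, z_um = 12)
  grid <- render_stack(truth, cfg)
  peak <- arrayInd(which.max(grid$data), dim(grid$data))
  planted <- um_to_voxel(grid, c(5, -3, 12))
  expect_true(all(abs(peak - planted) <= 0.5 + 1e-9))
})

test_that("a zero-cell rendering is background plus noise", {
  cfg <- synth_config(
    r_max = 60, r_min = 50, d_pole = 0, d_cz = 0, d_peak = 0, d_mr = 0,
    spacing = c(2000, 2000, 4000), seed = 21
  )
  grid <- render_stack(sample_epithelium(cfg), cfg)
  n <- prod(dim(grid$data))
  expect_lt(abs(mean(grid$data) - cfg$background),
            3 * cfg$noise_sd / sqrt(n))
})

test_that("two well-separated rendered cells give two maxima at the cells", {
  cfg <- synth_config(
    r_max = 40, r_min = 40, d_pole = 0.001, d_cz = 0.001, d_peak = 0.001,
    d_mr = 0.001, nucleus_radius = 4, noise_sd = 0, tilt_deg = 0,
    spacing = c(1000, 1000, 2000), seed = 2
  )
  truth <- point_table(x_um = c(-10, 10), y_um = c(0, 2), z_um = c(4, 6))
  grid <- render_stack(truth, cfg)
  # brute-force maxima scan of the noiseless rendering
  mx <- brute_force_maxima(grid$data - cfg$background, grid$spacing,
                           2 * cfg$nucleus_radius)
  expect_equal(nrow(mx), 2L)
  found <- voxel_to_um(grid, mx)
  planted <- as.matrix(truth[, c("x_um", "y_um", "z_um")])
  d <- as.matrix(dist(rbind(found, planted)))[1:2, 3:4]
  expect_lt(max(apply(d, 1, min)), max(grid$spacing) / 1000)
})
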