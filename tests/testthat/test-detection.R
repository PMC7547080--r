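# Nuclei detection: LoG map, dilation maxima, watershed scoring, pipeline.

make_grid <- function(a, spacing = c(1000, 1000, 2000)) voxel_grid(a, spacing)

test_that("LoG response is zero for constant images and linear in intensity", {
  g <- make_grid(array(7, c(12, 12, 6)))
  r <- log_likelihood_map(g, R = 4)
  expect_lt(max(abs(r$data)), 1e-9)

  set.seed(1)
  g2 <- make_grid(array(runif(12 * 12 * 6), c(12, 12, 6)))
  r1 <- log_likelihood_map(g2, R = 4)
  g3 <- g2; g3$data <- 2 * g2$data
  r2 <- log_likelihood_map(g3, R = 4)
  expect_equal(r2$data, 2 * r1$data, tolerance = 1e-12)
})

test_that("LoG rejects scales finer than the voxel spacing", {
  g <- make_grid(array(0, c(8, 8, 4)), spacing = c(1515.2, 1515.2, 5977.2))
  expect_error(log_likelihood_map(g, R = 4), "scale unresolvable")
})

test_that("LoG argmax sits on a rendered nucleus centre", {
  cfg <- synth_config(
    r_max = 30, r_min = 30, d_pole = 0, d_cz = 0, d_peak = 0, d_mr = 0,
    nucleus_radius = 4, noise_sd = 0, tilt_deg = 0,
    spacing = c(1000, 1000, 2000), seed = 1
  )
  truth <- point_table(x_um = 2, y_um = -4, z_um = 6)
  grid <- render_stack(truth, cfg)
  resp <- log_likelihood_map(grid, R = 4)
  peak <- arrayInd(which.max(resp$data), dim(resp$data))
  expect_true(all(abs(peak - um_to_voxel(grid, c(2, -4, 6))) <= 0.5 + 1e-9))
})

test_that("local_maxima matches the brute-force neighbourhood oracle", {
  spacing <- c(1000, 1000, 2500)
  for (s in 1:4) {
    set.seed(s)
    a <- array(rnorm(14 * 12 * 8), c(14, 12, 8))
    a <- epilens:::gaussian_smooth3(a, c(1, 1, 0.6))
    if (s %% 2 == 0) a <- round(a, 1)  # quantized: forces plateaus/ties
    lm <- local_maxima(make_grid(a, spacing), R = 3.2)
    bf <- brute_force_maxima(a, spacing, R = 3.2)
    expect_identical(unname(lm), unname(bf))
  }
})

test_that("dilation agrees with the brute-force ellipsoid oracle", {
  set.seed(3)
  a <- array(rnorm(10 * 9 * 5), c(10, 9, 5))
  sp <- c(1200, 1000, 3000)
  offs <- epilens:::ellipsoid_offsets(4, sp / 1000)
  expect_equal(
    epilens:::dilate_ellipsoid(a, offs),
    brute_force_dilation(a, sp, 4)
  )
})

test_that("degenerate maxima inputs behave per contract", {
  g <- make_grid(array(0, c(10, 10, 5)))
  expect_equal(nrow(local_maxima(g, R = 3)), 0L)

  # strictly increasing ramp: only the far corner is a neighbourhood maximum
  d <- c(9, 8, 4)
  ramp <- array(0, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    ramp[i, j, k] <- i + 100 * j + 10000 * k
  }
  mx <- local_maxima(make_grid(ramp), R = 3)
  expect_equal(unname(mx), matrix(d, 1))
})

test_that("otsu separates a clean bimodal mixture", {
  set.seed(2)
  x <- c(rnorm(4000, 10, 2), rnorm(1000, 60, 4))
  thr <- otsu_threshold(x)
  # any threshold in the inter-mode gap is a valid optimum; check separation
  expect_equal(mean(x < thr), 0.8, tolerance = 0.01)
})

test_that("an isolated spherical blob scores as highly circular", {
  # isotropic fine sampling: discretized ball circularity ~ 1
  d <- c(21, 21, 21)
  a <- array(10, d)
  ctr <- c(11, 11, 11)
  for (k in 1:d[3]) {
    r2 <- outer((1:d[1] - ctr[1])^2, (1:d[2] - ctr[2])^2, `+`) + (k - ctr[3])^2
    a[, , k] <- a[, , k] + 100 * (sqrt(r2) <= 6)
  }
  g <- make_grid(a, spacing = c(1000, 1000, 1000))
  seeds <- matrix(ctr, 1)
  seg <- segment_and_score(g, seeds, detection_params(R = 6, mask_threshold = 50))
  expect_equal(nrow(seg), 1L)
  expect_gte(seg$circularity, 0.9)
})

test_that("a one-voxel-wide line scores as non-circular", {
  a <- array(0, c(25, 9, 5))
  a[3:23, 5, 3] <- 100
  g <- make_grid(a, spacing = c(1000, 1000, 1000))
  seg <- segment_and_score(g, matrix(c(13, 5, 3), 1),
                           detection_params(R = 3, mask_threshold = 50))
  expect_lt(seg$circularity, 0.2)
})

test_that("two overlapping blobs with two seeds split into two regions", {
  cfg <- synth_config(
    r_max = 40, r_min = 40, d_pole = 0.001, d_cz = 0.001, d_peak = 0.001,
    d_mr = 0.001, nucleus_radius = 4, noise_sd = 0, tilt_deg = 0,
    spacing = c(1000, 1000, 1000), seed = 2
  )
  # centres 1.5 R apart: blobs overlap by half a radius
  truth <- point_table(x_um = c(-3, 3), y_um = c(0, 0), z_um = c(0, 0))
  grid <- render_stack(truth, cfg)
  seeds <- round(um_to_voxel(grid, as.matrix(truth[, c("x_um", "y_um", "z_um")])))
  storage.mode(seeds) <- "integer"
  seg <- segment_and_score(grid, seeds, detection_params(R = 4, mask_threshold = 30))
  expect_equal(nrow(seg), 2L)
  planted <- as.matrix(truth[, c("x_um", "y_um", "z_um")])
  got <- as.matrix(seg[, c("x_um", "y_um", "z_um")])
  d <- sqrt(rowSums((got - planted)^2))  # nearest-planted pairing holds here
  expect_lt(max(d), 4 / 2)
})

test_that("a seed outside the mask is dropped and logged", {
  a <- array(0, c(10, 10, 4)); a[5, 5, 2] <- 100
  g <- make_grid(a, c(1000, 1000, 1000))
  seg <- segment_and_score(
    g, rbind(c(5L, 5L, 2L), c(1L, 1L, 1L)),
    detection_params(R = 2, mask_threshold = 50)
  )
  expect_equal(nrow(seg), 1L)
  expect_equal(attr(seg, "dropped"), 2L)
})

test_that("detection is equivariant to whole-voxel translation", {
  cfg <- synth_config(
    r_max = 25, r_min = 25, theta_cz_flat = 20, theta_cz_end = 40,
    theta_peak = 60, theta_edge = 90, mr_fraction = 0,
    d_pole = 1.2, d_cz = 1.2, d_peak = 1.2, d_mr = 1.2,
    nucleus_radius = 4, noise_sd = 0, tilt_deg = 0,
    spacing = c(1000, 1000, 2000), seed = 6
  )
  truth <- sample_epithelium(cfg)
  grid <- render_stack(truth, cfg)
  params <- detection_params(R = 4, intensity_threshold = 40,
                             mask_threshold = 30)
  base <- detect_nuclei(grid, params)

  shift <- c(2L, 1L, 3L)
  d <- dim(grid$data)
  shifted <- array(cfg$background, d + 2L * shift)
  shifted[shift[1] + 1:d[1], shift[2] + 1:d[2], shift[3] + 1:d[3]] <- grid$data
  gs <- voxel_grid(shifted, grid$spacing, origin = grid$origin)
  moved <- detect_nuclei(gs, params)
  expect_equal(nrow(moved), nrow(base))
  phys_shift <- shift * grid$spacing / 1000
  ord_b <- order(base$x_um, base$y_um, base$z_um)
  ord_m <- order(moved$x_um, moved$y_um, moved$z_um)
  expect_equal(
    as.matrix(moved[ord_m, c("x_um", "y_um", "z_um")]),
    sweep(as.matrix(base[ord_b, c("x_um", "y_um", "z_um")]), 2, -phys_shift),
    tolerance = 1e-9, ignore_attr = TRUE
  )
})

test_that("raising either threshold never increases the detection count", {
  cfg <- small_mature(seed = 2, r_max = 120, r_min = 84)
  truth <- sample_epithelium(cfg)
  grid <- render_stack(truth, cfg)
  n_at <- function(int_thr, circ_thr) {
    nrow(detect_nuclei(grid, detection_params(
      intensity_threshold = int_thr, circularity_threshold = circ_thr
    )))
  }
  counts_int <- vapply(c(30, 45, 60, 80), n_at, numeric(1), circ_thr = 0.3)
  expect_true(all(diff(counts_int) <= 0))
  counts_circ <- vapply(c(0.1, 0.3, 0.5, 0.7), n_at, numeric(1),
                        int_thr = 40)
  expect_true(all(diff(counts_circ) <= 0))
  # perfect circularity is unattainable on a discrete grid
  expect_equal(n_at(40, 1.0), 0L)
})

test_that("pure noise yields no detections at default thresholds", {
  for (s in c(31, 32)) {
    cfg <- synth_config(
      r_max = 55, r_min = 45, d_pole = 0, d_cz = 0, d_peak = 0, d_mr = 0,
      spacing = c(1500, 1500, 3000), seed = s
    )
    grid <- render_stack(sample_epithelium(cfg), cfg)
    expect_equal(nrow(detect_nuclei(grid)), 0L)
  }
})

test_that("greedy matching scores precision and recall sensibly", {
  a <- rbind(c(0, 0, 0), c(10, 0, 0), c(40, 0, 0))
  b <- rbind(c(1, 0, 0), c(10.5, 0, 0), c(20, 0, 0), c(41, 0, 0))
  m <- match_point_sets(a, b, radius = 2)
  expect_equal(nrow(m$matches), 3L)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 0.75)
})
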