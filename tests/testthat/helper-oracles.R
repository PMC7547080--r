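# Independent oracles used to validate the fast implementations.

# Brute-force local maxima: voxel kept iff no voxel within the physical
# ellipsoid of radius R is larger, no equal-valued *kept* voxel with a
# smaller linear index lies within range, and the value is positive.
brute_force_maxima <- function(a, spacing_nm, R) {
  sp <- spacing_nm / 1000
  d <- dim(a)
  idx <- order(seq_len(prod(d)))  # linear order
  keep <- logical(prod(d))
  coords <- arrayInd(seq_len(prod(d)), d)
  phys <- sweep(coords, 2, sp, `*`)
  for (v in seq_len(prod(d))) {
    if (a[v] <= 0) next
    dv <- sweep(phys, 2, phys[v, ], `-`)
    inrange <- rowSums((dv / R)^2) <= 1
    inrange[v] <- FALSE
    if (any(a[inrange] > a[v])) next
    eq <- which(inrange & a == a[v] & keep)
    if (length(eq) && any(eq < v)) next
    keep[v] <- TRUE
  }
  out <- coords[keep, , drop = FALSE]
  colnames(out) <- c("i", "j", "k")
  out
}

# Brute-force grayscale dilation by the same ellipsoid (centre included).
brute_force_dilation <- function(a, spacing_nm, R) {
  sp <- spacing_nm / 1000
  d <- dim(a)
  out <- a
  coords <- arrayInd(seq_len(prod(d)), d)
  phys <- sweep(coords, 2, sp, `*`)
  for (v in seq_len(prod(d))) {
    dv <- sweep(phys, 2, phys[v, ], `-`)
    inrange <- rowSums((dv / R)^2) <= 1
    out[v] <- max(a[inrange])
  }
  out
}

# Points on a 3D circle with a given centre, radius and unit normal.
circle_points <- function(center, radius, normal, angles_deg) {
  n <- normal / sqrt(sum(normal^2))
  seed <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- seed - sum(seed * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    n[2] * e1[3] - n[3] * e1[2],
    n[3] * e1[1] - n[1] * e1[3],
    n[1] * e1[2] - n[2] * e1[1]
  )
  t(vapply(angles_deg * pi / 180, function(a) {
    center + radius * (cos(a) * e1 + sin(a) * e2)
  }, numeric(3)))
}

# Closed-form spherical cap / band area (unit radius unless scaled).
cap_area <- function(theta_deg, r = 1) 2 * pi * r^2 * (1 - cos(theta_deg * pi / 180))

# Random rigid motion (seeded): rotation matrix + translation.
random_rigid_motion <- function(seed) {
  set.seed(seed)
  axis <- rnorm(3)
  list(
    R = epilens::rotation_matrix(runif(1, 0, 360), axis),
    t = runif(3, -500, 500)
  )
}

apply_rigid <- function(xyz, motion) {
  sweep(xyz %*% t(motion$R), 2, motion$t, `+`)
}

# Shared small phantom for detection tests (reduced radius, same densities,
# spacing, noise and nucleus size as the mature preset).
small_mature <- function(seed = 1, ...) {
  lens_preset("mature", seed = seed, r_max = 200, r_min = 140, ...)
}
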