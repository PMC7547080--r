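#' Sample a ground-truthed epithelium point cloud
#'
#' Draws an inhomogeneous Poisson point process with intensity
#' [planted_density()] on the spheroid cap `theta in [0, theta_edge]`, by
#' thinning a homogeneous process on the normalized sphere. Points in the
#' meridional rows are additionally snapped to a regular constant-phi column
#' lattice to emulate the aligned cell columns of that zone. Sampling is
#' deterministic given `config$seed`.
#'
#' The returned table stores the untilted spheroid-surface coordinates
#' (`x_um`, `y_um`, `z_um`; every point satisfies
#' `x^2/r_max^2 + y^2/r_max^2 + z^2/r_min^2 = 1`) plus ground-truth columns
#' `true_theta_deg`, `true_phi_deg`, `true_zone`. Mounting tilt is applied
#' separately (see [apply_tilt()] / [mounted_points()]).
#'
#' @param config a [synth_config()].
#' @return a `point_table` of class `lens_truth` with the generating config in
#'   `attr(, "config")`.
#' @export
sample_epithelium <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  d_max <- max(planted_density(config, seq(0, config$theta_edge, by = 0.1)))
  ce <- cos(deg2rad(config$theta_edge))
  cap_area_um2 <- 2 * pi * (1 - ce) * config$r_max^2

  pts <- with_seed(config$seed, {
    n_hom <- if (d_max > 0) rpois(1, d_max / 1000 * cap_area_um2) else 0L
    if (n_hom == 0) {
      cbind(theta = numeric(), phi = numeric())
    } else {
      cos_t <- runif(n_hom, ce, 1)
      theta <- rad2deg(acos(cos_t))
      phi <- runif(n_hom, 0, 360)
      keep <- runif(n_hom) < planted_density(config, theta) / d_max
      cbind(theta = theta[keep], phi = phi[keep])
    }
  })

  theta <- pts[, "theta"]; phi <- pts[, "phi"]
  zone <- rep("GZ", length(theta))
  zone[theta <= config$theta_cz_end] <- "CZ"
  zone[theta >= config$theta_mr_start] <- "MR"

  # cosmetic MR alignment: snap phi to a regular column lattice
  mr <- zone == "MR"
  if (any(mr) && config$mr_column_pitch_um > 0) {
    mid <- (config$theta_mr_start + config$theta_edge) / 2
    circ <- 2 * pi * config$r_max * sin(deg2rad(mid))
    n_col <- max(8L, round(circ / config$mr_column_pitch_um))
    pitch <- 360 / n_col
    phi[mr] <- (round(phi[mr] / pitch) * pitch) %% 360
  }

  st <- sin(deg2rad(theta))
  truth <- point_table(
    x_um = config$r_max * st * cos(deg2rad(phi)),
    y_um = config$r_max * st * sin(deg2rad(phi)),
    z_um = config$r_min * cos(deg2rad(theta)),
    true_theta_deg = theta,
    true_phi_deg = phi,
    true_zone = zone
  )
  attr(truth, "config") <- config
  class(truth) <- c("lens_truth", class(truth))
  truth
}

#' Rigidly tilt a point cloud about an axis through the lens centre
#'
#' Emulates the mounting tilt of whole lenses in the support matrix
#' (approximately 35 degrees by default in the presets). Rotation preserves
#' all pairwise distances and norms.
#'
#' @param points a point table or n x 3 matrix (um).
#' @param tilt_deg rotation angle in degrees.
#' @param axis rotation axis (`"x"`, `"y"`, `"z"` or a vector).
#' @return points of the same class with rotated coordinates.
#' @export
apply_tilt <- function(points, tilt_deg, axis = "x") {
  xyz <- coord_matrix(points)
  set_coords(points, xyz %*% t(rotation_matrix(tilt_deg, axis)))
}

#' As-mounted coordinates of a phantom
#'
#' Applies the configured mounting tilt to ground-truth points, giving the
#' cloud as it would appear in the acquisition frame.
#'
#' @param truth output of [sample_epithelium()].
#' @param config the generating [synth_config()]; defaults to the config
#'   attached to `truth`.
#' @return tilted `point_table` (ground-truth columns preserved).
#' @export
mounted_points <- function(truth, config = attr(truth, "config")) {
  stopifnot(inherits(config, "synth_config"))
  apply_tilt(truth, config$tilt_deg, "x")
}

#' Landmark points at the GZ/MR boundary
#'
#' Returns three (or more) points on the spheroid surface at the planted
#' germinative-zone/meridional-row boundary latitude, equally spaced in
#' azimuth — the synthetic analogue of the user-picked landmarks from which
#' the near-equatorial plane is fitted.
#'
#' @param config a [synth_config()].
#' @param phi_deg azimuths of the landmarks, degrees.
#' @param tilted if `TRUE` (default) the landmarks are returned in the
#'   as-mounted frame (tilted with the cloud).
#' @return length(phi_deg) x 3 matrix of um coordinates.
#' @export
gz_mr_landmarks <- function(config, phi_deg = c(0, 120, 240), tilted = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  th <- deg2rad(config$theta_mr_start)
  p <- cbind(
    config$r_max * sin(th) * cos(deg2rad(phi_deg)),
    config$r_max * sin(th) * sin(deg2rad(phi_deg)),
    config$r_min * cos(th)
  )
  if (tilted) p <- apply_tilt(p, config$tilt_deg, "x")
  p
}
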