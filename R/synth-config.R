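#' Synthetic lens phantom configuration
#'
#' Defines the ground-truth generative model for a spheroid-cap epithelium:
#' lens geometry (equatorial radius `r_max`, polar radius `r_min`), a planted
#' polar-angle density profile, nucleus rendering and mounting parameters.
#'
#' The planted surface density d(theta), in cells per 1000 um^2 of the
#' affinely normalized sphere scaled by `r_max`, is piecewise linear through
#' `(0, d_pole) - (theta_cz_flat, d_pole) - (theta_cz_end, d_cz) -
#' (theta_peak, d_peak) - (theta_mr_start, d_mr) - (theta_edge, d_mr)`:
#' a central-zone plateau declining to its minimum at the CZ/GZ boundary
#' (`theta_cz_end`), a germinative-zone peak at `theta_peak`, a fall into the
#' meridional rows and a low MR tail. `theta_mr_start` is not free: it is
#' solved so the MR band occupies exactly `mr_fraction` of the epithelial cap
#' area. Setting `d_pole = d_cz` recovers a flat CZ.
#'
#' @param r_max,r_min equatorial and polar semi-axes, um (`r_min <= r_max`).
#' @param theta_cz_flat end of the flat anterior plateau, degrees.
#' @param theta_cz_end planted density minimum (CZ/GZ boundary), degrees.
#' @param theta_peak planted density maximum, degrees.
#' @param mr_fraction fraction of total epithelial band area occupied by the
#'   meridional rows, in `[0, 1)`.
#' @param theta_edge posterior edge of the epithelium, degrees.
#' @param d_pole,d_cz,d_peak,d_mr planted densities, cells per 1000 um^2.
#' @param nucleus_radius rendered nucleus radius, um.
#' @param peak_intensity,background,noise_sd rendering intensity model.
#' @param tilt_deg mounting tilt about the x axis, degrees.
#' @param spacing voxel spacing for rendering, nm (x, y, z).
#' @param mr_column_pitch_um azimuthal pitch of the meridional-row column
#'   lattice, um of arc at the MR mid-latitude.
#' @param seed integer RNG seed; the same config + seed reproduces the phantom
#'   bit for bit.
#' @return object of class `synth_config`.
#' @seealso [lens_preset()] for the reference configurations.
#' @export
synth_config <- function(r_max = 1000, r_min = 700,
                         theta_cz_flat = 65, theta_cz_end = 75,
                         theta_peak = 90, mr_fraction = 0.05,
                         theta_edge = 117,
                         d_pole = 0.55, d_cz = 0.30, d_peak = 0.90,
                         d_mr = 0.36,
                         nucleus_radius = 6, peak_intensity = 100,
                         background = 10, noise_sd = 5,
                         tilt_deg = 35,
                         spacing = c(1515.2, 1515.2, 5977.2),
                         mr_column_pitch_um = 30,
                         seed = 1L) {
  cfg <- list(
    r_max = r_max, r_min = r_min,
    theta_cz_flat = theta_cz_flat, theta_cz_end = theta_cz_end,
    theta_peak = theta_peak, mr_fraction = mr_fraction,
    theta_edge = theta_edge,
    d_pole = d_pole, d_cz = d_cz, d_peak = d_peak, d_mr = d_mr,
    nucleus_radius = nucleus_radius, peak_intensity = peak_intensity,
    background = background, noise_sd = noise_sd,
    tilt_deg = tilt_deg, spacing = as.numeric(spacing),
    mr_column_pitch_um = mr_column_pitch_um,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    if (!(r_max > 0 && r_min > 0 && r_min <= r_max)) {
      stop("require 0 < r_min <= r_max")
    }
    if (!(0 < theta_cz_end && theta_cz_end < theta_peak &&
          theta_peak < theta_edge && theta_edge <= 180)) {
      stop("require 0 < theta_cz_end < theta_peak < theta_edge <= 180")
    }
    if (!(theta_cz_flat >= 0 && theta_cz_flat <= theta_cz_end)) {
      stop("require 0 <= theta_cz_flat <= theta_cz_end")
    }
    if (mr_fraction < 0 || mr_fraction >= 1) stop("mr_fraction must be in [0, 1)")
    if (any(c(d_pole, d_cz, d_peak, d_mr) < 0)) stop("densities must be >= 0")
    if (d_cz > d_peak) stop("require d_cz <= d_peak")
    if (d_pole < d_cz) stop("require d_pole >= d_cz (minimum sits at theta_cz_end)")
    if (nucleus_radius <= 0) stop("nucleus_radius must be positive")
    if (any(spacing <= 0) || length(spacing) != 3) {
      stop("spacing must be three positive values (nm)")
    }
  })
  # MR onset from the planted area fraction; must fall beyond the peak
  cfg$theta_mr_start <- theta_mr_from_fraction(
    cfg$mr_fraction, cfg$theta_edge
  )
  if (cfg$mr_fraction > 0 &&
      !(cfg$theta_mr_start > cfg$theta_peak &&
        cfg$theta_mr_start < cfg$theta_edge)) {
    stop(
      "infeasible mr_fraction: implied MR onset ",
      format(cfg$theta_mr_start, digits = 5),
      " deg does not lie in (theta_peak, theta_edge)"
    )
  }
  class(cfg) <- "synth_config"
  cfg
}

# Solve cos(theta_mr) = cos(theta_edge) + f * (1 - cos(theta_edge)) so that the
# band [theta_mr, theta_edge] holds fraction f of the cap area.
theta_mr_from_fraction <- function(f, theta_edge) {
  ce <- cos(deg2rad(theta_edge))
  rad2deg(acos(ce + f * (1 - ce)))
}

#' Reference phantom presets
#'
#' `"mature"` emulates an adult lens: lentoid shape (aspect ratio
#' `r_min/r_max = 0.7`), density minimum planted at 75 deg, peak at 90 deg,
#' meridional rows occupying 5 percent of the epithelium, 35 deg mounting
#' tilt. `"young"` emulates a juvenile lens: near-spheroid shape (aspect
#' 0.9), near-uniform density with a mild peak at 95 deg.
#'
#' Absolute densities are scaled to give roughly 4000-5000 cells per phantom
#' so a full pipeline run takes seconds; real murine lenses carry ~50,000
#' epithelial cells, and density scale is a free parameter.
#'
#' @param name `"mature"` or `"young"`.
#' @param ... overrides passed on to [synth_config()].
#' @return a [synth_config()].
#' @export
lens_preset <- function(name = c("mature", "young"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    mature = list(
      r_max = 1000, r_min = 700,
      theta_cz_flat = 65, theta_cz_end = 75, theta_peak = 90,
      mr_fraction = 0.05, theta_edge = 117,
      d_pole = 0.55, d_cz = 0.30, d_peak = 0.90, d_mr = 0.36
    ),
    young = list(
      r_max = 900, r_min = 810,
      theta_cz_flat = 40, theta_cz_end = 55, theta_peak = 95,
      mr_fraction = 0.05, theta_edge = 117,
      d_pole = 0.60, d_cz = 0.50, d_peak = 0.80, d_mr = 0.35
    )
  )
  do.call(synth_config, utils::modifyList(base, list(...)))
}

#' Planted density profile d(theta)
#'
#' Evaluates the generative surface density (cells per 1000 um^2 on the
#' normalized sphere scaled by `r_max`) at polar angles `theta_deg`.
#'
#' @param config a [synth_config()].
#' @param theta_deg polar angles, degrees.
#' @return numeric densities; zero beyond `theta_edge`.
#' @export
planted_density <- function(config, theta_deg) {
  stopifnot(inherits(config, "synth_config"))
  nodes_t <- c(
    0, config$theta_cz_flat, config$theta_cz_end, config$theta_peak,
    config$theta_mr_start, config$theta_edge
  )
  nodes_d <- c(
    config$d_pole, config$d_pole, config$d_cz, config$d_peak,
    config$d_mr, config$d_mr
  )
  keep <- !duplicated(nodes_t)
  f <- approxfun(nodes_t[keep], nodes_d[keep], rule = 2)
  out <- f(theta_deg)
  out[theta_deg > config$theta_edge] <- 0
  out
}

#' Expected cell count of a phantom
#'
#' Closed-form integral of the planted density over the cap,
#' `N = (r_max^2 / 1000) * Int_0^theta_edge d(theta) 2 pi sin(theta) dtheta`,
#' using the exact antiderivative of `(a + b*theta) sin(theta)` on each linear
#' piece.
#'
#' @param config a [synth_config()].
#' @return expected number of cells (the Poisson mean).
#' @export
expected_cell_count <- function(config) {
  nodes <- sort(unique(c(
    0, config$theta_cz_flat, config$theta_cz_end, config$theta_peak,
    config$theta_mr_start, config$theta_edge
  )))
  total <- 0
  for (i in seq_len(length(nodes) - 1)) {
    t1 <- deg2rad(nodes[i]); t2 <- deg2rad(nodes[i + 1])
    d1 <- planted_density(config, nodes[i])
    d2 <- planted_density(config, nodes[i + 1])
    if (t2 - t1 < 1e-12) next
    b <- (d2 - d1) / (t2 - t1)
    a <- d1 - b * t1
    anti <- function(t) -(a + b * t) * cos(t) + b * sin(t)
    total <- total + (anti(t2) - anti(t1))
  }
  2 * pi * config$r_max^2 * total / 1000
}
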