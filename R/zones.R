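# Polar-angle density profile, extremum angles, zonal segmentation and
# per-cell local density on the normalized sphere.

#' Surface area of a spherical band
#'
#' Band between polar angles `theta1 < theta2` on the normalized sphere
#' scaled by `R_max`: `2 pi R_max^2 (cos theta1 - cos theta2)`.
#'
#' @param theta1,theta2 polar angles, degrees.
#' @param R_max scale radius, um.
#' @return band area, um^2.
#' @export
theta_band_area <- function(theta1, theta2, R_max = 1) {
  2 * pi * R_max^2 * (cos(deg2rad(theta1)) - cos(deg2rad(theta2)))
}

#' Polar-angle surface density profile
#'
#' Bins mapped nuclei by `theta`, converts counts to surface densities with
#' exact band areas on the normalized sphere scaled by `R_max`, and smooths
#' by a centred, band-area-weighted moving average (pooled counts over pooled
#' area, edge-truncated). Area weighting matters because polar bins subtend
#' far less surface than equatorial bins: an unweighted average would let the
#' near-empty polar bins dominate the variance of the smoothed profile.
#'
#' @param points mapped `point_table` (needs `theta_deg`) or a numeric vector
#'   of theta values in degrees.
#' @param R_max equatorial radius used for area scaling, um (taken from
#'   `frame` if given).
#' @param frame optional [build_frame()] result supplying `R_max`.
#' @param bin_width bin width in degrees; must divide 180.
#' @param smooth_window moving-average window in bins (odd).
#' @return data frame of class `density_profile` with columns `theta_lo`,
#'   `theta_hi`, `theta_mid`, `count`, `area_um2`, `density` and
#'   `density_smooth` (cells per 1000 um^2).
#' @export
theta_density_profile <- function(points, R_max = NULL, frame = NULL,
                                  bin_width = 5, smooth_window = 3) {
  theta <- if (is.numeric(points)) points else points$theta_deg
  theta <- theta[!is.na(theta)]
  if (!length(theta)) stop("no mapped nuclei: theta angles are all missing")
  if (abs(180 / bin_width - round(180 / bin_width)) > 1e-9) {
    stop("bin_width must divide 180")
  }
  if (smooth_window < 1 || smooth_window %% 2 == 0) {
    stop("smooth_window must be a positive odd number of bins")
  }
  R_max <- R_max %||% frame$R_max %||% 1
  edges <- seq(0, 180, by = bin_width)
  nb <- length(edges) - 1L
  bin <- pmin(findInterval(theta, edges, rightmost.closed = TRUE), nb)
  count <- tabulate(bin, nbins = nb)
  area <- theta_band_area(edges[-length(edges)], edges[-1], R_max)
  density <- count / area * 1000
  half <- (smooth_window - 1L) / 2L
  smooth <- vapply(seq_len(nb), function(i) {
    w <- max(1L, i - half):min(nb, i + half)
    sum(count[w]) / sum(area[w]) * 1000
  }, numeric(1))
  out <- data.frame(
    theta_lo = edges[-length(edges)], theta_hi = edges[-1],
    theta_mid = (edges[-length(edges)] + edges[-1]) / 2,
    count = count, area_um2 = area,
    density = density, density_smooth = smooth
  )
  attr(out, "bin_width") <- bin_width
  attr(out, "smooth_window") <- smooth_window
  attr(out, "R_max") <- R_max
  attr(out, "n_points") <- length(theta)
  attr(out, "theta_edge") <- max(theta)
  class(out) <- c("density_profile", "data.frame")
  out
}

#' Density-profile extremum angles
#'
#' `theta_max_angle` is the centre of the global maximum bin of the smoothed
#' density (largest theta among ties); `theta_min_angle` is the centre of the
#' minimum bin restricted to angles below the maximum, again taking the
#' largest theta among ties — the posterior edge of the anterior low-density
#' plateau. A profile whose relative contrast `(max - min)/max` is below 0.1
#' is flagged `low_contrast` (the extrema are then weakly determined).
#'
#' @param profile a [theta_density_profile()] result (at least 5 bins).
#' @return list `theta_min_angle`, `theta_max_angle`, `low_contrast`.
#' @export
profile_extrema <- function(profile) {
  stopifnot(inherits(profile, "density_profile"))
  if (nrow(profile) < 5) stop("profile needs at least 5 bins")
  s <- profile$density_smooth
  imax <- max(which(s == max(s)))
  if (imax == 1L) imax <- 2L  # degenerate: keep a bin available below the max
  below <- s[seq_len(imax - 1L)]
  imin <- max(which(below == min(below)))
  contrast <- if (max(s) > 0) (max(s) - min(below)) / max(s) else 0
  list(
    theta_min_angle = profile$theta_mid[imin],
    theta_max_angle = profile$theta_mid[imax],
    low_contrast = contrast < 0.1
  )
}

#' Zonal segmentation of the epithelium
#'
#' Segments the cap into the central zone CZ `[0, theta_min]`, germinative
#' zone GZ `(theta_min, theta_mr)` and meridional rows MR
#' `[theta_mr, theta_edge]`. The MR onset is the centre of the first bin
#' beyond the density maximum where the smoothed density falls below
#' `drop_fraction` times the peak (fallback with a warning flag: the last
#' populated bin). `theta_edge` is the largest mapped theta. Zone sizes are
#' reported as band-area percentages of the cap `[0, theta_edge]`.
#'
#' @param profile a [theta_density_profile()] result.
#' @param points the mapped `point_table` (or numeric theta vector) the
#'   profile was built from.
#' @param drop_fraction fraction of the peak density defining the MR onset.
#' @param mr_start_override optional explicit MR onset in degrees (e.g. the
#'   mean theta of user landmarks at the GZ/MR boundary), bypassing the
#'   density-drop rule.
#' @return object of class `zone_segmentation`: extremum angles, `theta_mr_start`,
#'   `theta_edge`, per-nucleus `zone`, `percent` (named CZ/GZ/MR, summing to
#'   100), per-zone `counts`, and `warnings`.
#' @export
zone_segmentation <- function(profile, points, drop_fraction = 0.5,
                              mr_start_override = NULL) {
  stopifnot(inherits(profile, "density_profile"))
  theta <- if (is.numeric(points)) points else points$theta_deg
  theta <- theta[!is.na(theta)]
  ext <- profile_extrema(profile)
  theta_edge <- max(theta)
  warn <- character()

  if (!is.null(mr_start_override)) {
    theta_mr <- mr_start_override
  } else {
    s <- profile$density_smooth
    imax <- which(profile$theta_mid == ext$theta_max_angle)
    peak <- s[imax]
    after <- which(seq_along(s) > imax & s < drop_fraction * peak)
    if (length(after)) {
      theta_mr <- profile$theta_mid[after[1]]
    } else {
      pop <- which(profile$count > 0)
      theta_mr <- profile$theta_mid[tail(pop, 1)]
      warn <- c(warn, "density never fell below drop_fraction * peak; MR onset set to the last populated bin")
    }
  }
  if (theta_mr > theta_edge) {
    warn <- c(warn, "MR onset beyond the last mapped nucleus; MR is empty")
    theta_mr <- theta_edge
  }

  zone <- rep("GZ", length(theta))
  zone[theta <= ext$theta_min_angle] <- "CZ"
  zone[theta >= theta_mr] <- "MR"
  cap <- theta_band_area(0, theta_edge)
  percent <- c(
    CZ = theta_band_area(0, ext$theta_min_angle),
    GZ = theta_band_area(ext$theta_min_angle, theta_mr),
    MR = theta_band_area(theta_mr, theta_edge)
  ) / cap * 100

  structure(
    list(
      theta_min_angle = ext$theta_min_angle,
      theta_max_angle = ext$theta_max_angle,
      low_contrast = ext$low_contrast,
      theta_mr_start = theta_mr,
      theta_edge = theta_edge,
      drop_fraction = if (is.null(mr_start_override)) drop_fraction else NA_real_,
      zone = zone,
      percent = percent,
      counts = c(
        CZ = sum(zone == "CZ"), GZ = sum(zone == "GZ"), MR = sum(zone == "MR")
      ),
      warnings = warn
    ),
    class = "zone_segmentation"
  )
}

#' @export
print.zone_segmentation <- function(x, ...) {
  cat(sprintf(
    paste0(
      "zone_segmentation: min %.1f deg, max %.1f deg, MR onset %.1f deg, ",
      "edge %.1f deg\n  percent of epithelium: CZ %.1f / GZ %.1f / MR %.1f\n"
    ),
    x$theta_min_angle, x$theta_max_angle, x$theta_mr_start, x$theta_edge,
    x$percent["CZ"], x$percent["GZ"], x$percent["MR"]
  ))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Per-nucleus local surface density (heat-map values)
#'
#' k-nearest-neighbour density on the normalized sphere: for each nucleus,
#' `k` divided by the area of the geodesic disc reaching its k-th nearest
#' neighbour (great-circle radius, scaled by `R_max`). Values are classed
#' into 5 quantile levels for the classic blue-to-red heat map.
#'
#' @param points mapped `point_table` (needs `theta_deg`, `phi_deg`).
#' @param R_max scale radius, um (or a `frame` with one).
#' @param k neighbour count (default 6, the planar coordination number of an
#'   epithelial sheet); requires at least `k + 1` nuclei.
#' @param frame optional [build_frame()] result supplying `R_max`.
#' @return data frame `density` (cells per 1000 um^2) and `heat_class`
#'   (integer 1-5, low to high).
#' @export
local_density_map <- function(points, R_max = NULL, k = 6, frame = NULL) {
  R_max <- R_max %||% frame$R_max %||% stop("R_max (or frame) required")
  theta <- deg2rad(points$theta_deg)
  phi <- deg2rad(points$phi_deg)
  if (any(is.na(theta)) || any(is.na(phi))) {
    stop("points must be mapped (theta/phi assigned) before density mapping")
  }
  n <- length(theta)
  if (n < k + 1) stop("need at least k + 1 = ", k + 1, " nuclei")
  U <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  gk <- numeric(n)
  chunk <- max(1L, floor(2e7 / n))
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(n, start + chunk - 1L)
    cosg <- pmin(pmax(U[rows, , drop = FALSE] %*% t(U), -1), 1)
    g <- acos(cosg)
    gk[rows] <- apply(g, 1, function(x) sort(x)[k + 1L])  # [1] is self (0)
  }
  dens <- k / (2 * pi * (1 - cos(gk)) * R_max^2) * 1000
  qs <- quantile(dens, probs = seq(0.2, 0.8, by = 0.2), names = FALSE)
  data.frame(
    density = dens,
    heat_class = findInterval(dens, qs) + 1L
  )
}
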