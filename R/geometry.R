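# Equatorial-frame geometry: 3-point circle, anterior pole, spheroid
# refinement, canonical alignment and spherical-angle assignment.

#' Circle through three points in 3D
#'
#' Circumcircle of the triangle `p1 p2 p3`: centre, radius and the unit
#' normal of the supporting plane (sign arbitrary until oriented with
#' [orient_normal()]).
#'
#' @param p1,p2,p3 length-3 numeric points, um.
#' @return list with `C` (centre), `radius`, `n` (unit normal).
#' @export
fit_circle_3pt <- function(p1, p2, p3) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  u <- p2 - p1; v <- p3 - p1
  w <- c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
  w2 <- sum(w^2)
  scale <- max(sum(u^2), sum(v^2), .Machine$double.eps)
  if (sqrt(w2) < 1e-12 * scale) {
    stop("degenerate landmarks: the three points are collinear or coincident")
  }
  # circumcentre via the standard barycentric formula
  alpha <- sum(v^2) * (sum(u^2) - sum(u * v)) / (2 * w2)
  beta <- sum(u^2) * (sum(v^2) - sum(u * v)) / (2 * w2)
  C <- p1 + alpha * u + beta * v
  list(
    C = C,
    radius = sqrt(sum((p1 - C)^2)),
    n = w / sqrt(w2)
  )
}

#' Orient a plane normal toward the data hemisphere
#'
#' Flips `n` when fewer than half of the points lie on its positive side of
#' the plane through `C`; an exactly balanced split is ambiguous and raises
#' an error (pick better landmarks).
#'
#' @param points point table or n x 3 matrix.
#' @param C plane point (circle centre).
#' @param n unit normal.
#' @return oriented unit normal.
#' @export
orient_normal <- function(points, C, n) {
  xyz <- coord_matrix(points)
  if (nrow(xyz) == 0) stop("cannot orient normal: no points")
  side <- as.vector(xyz %*% n) - sum(C * n)
  pos <- sum(side > 0)
  neg <- sum(side < 0)
  if (pos == neg) {
    stop("ambiguous orientation: points split evenly across the landmark plane")
  }
  if (pos > neg) n else -n
}

#' Geometric anterior pole
#'
#' The anterior pole is the detected nucleus met by the ray from the circle
#' centre `C` along the oriented normal `n`: the nucleus with the smallest
#' perpendicular distance to the ray (ties broken in favour of the farther
#' nucleus along the ray), gated at `tol_frac * R_max` perpendicular distance.
#'
#' @param points point table or n x 3 matrix.
#' @param C circle centre.
#' @param n oriented unit normal.
#' @param R_max gate scale, um (typically the fitted circle radius).
#' @param tol_frac perpendicular gate as a fraction of `R_max`. The default
#'   0.1 is sized for phantom-scale densities (~0.5 cells / 1000 um^2 near
#'   the pole), where the nearest nucleus to the ray is tens of um away;
#'   tighten for dense real-lens data.
#' @return list with `AP` (coordinates), `index` (row in `points`),
#'   `t` (distance along the ray), `perp` (perpendicular distance).
#' @export
find_anterior_pole <- function(points, C, n, R_max, tol_frac = 0.1) {
  xyz <- coord_matrix(points)
  if (nrow(xyz) == 0) stop("no pole found: point set is empty")
  v <- sweep(xyz, 2, C)
  t_along <- as.vector(v %*% n)
  perp2 <- rowSums(v^2) - t_along^2
  perp <- sqrt(pmax(perp2, 0))
  ok <- t_along > 0 & perp <= tol_frac * R_max
  if (!any(ok)) {
    stop(
      "no pole found: no nucleus within ", format(tol_frac * R_max, digits = 4),
      " um of the polar ray (check the landmark plane)"
    )
  }
  idx <- which(ok)
  best <- idx[order(perp[idx], -t_along[idx])][1]
  list(AP = xyz[best, ], index = best, t = t_along[best], perp = perp[best])
}

# Least-squares axisymmetric spheroid about a known axis (through C along n).
# For each trial centre offset z0 the model rho^2/Rmax^2 + (z-z0)^2/Rmin^2 = 1
# is linear in (1/Rmax^2, 1/Rmin^2); z0 is profiled by 1D minimization.
fit_spheroid_axis <- function(points, C, n) {
  xyz <- coord_matrix(points)
  v <- sweep(xyz, 2, C)
  z <- as.vector(v %*% n)
  rho2 <- pmax(rowSums(v^2) - z^2, 0)
  s <- max(abs(z), sqrt(rho2), 1)    # scale for conditioning
  z <- z / s; rho2 <- rho2 / s^2
  sse <- function(z0) {
    u <- rho2; w <- (z - z0)^2
    M <- cbind(u, w)
    fit <- tryCatch(qr.solve(crossprod(M), crossprod(M, rep(1, length(u)))),
                    error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit)) || any(fit <= 0)) return(Inf)
    sum((M %*% fit - 1)^2)
  }
  zs <- seq(min(z), max(z), length.out = 101)
  vals <- vapply(zs, sse, numeric(1))
  k <- which.min(vals)
  lo <- zs[max(1, k - 1)]; hi <- zs[min(length(zs), k + 1)]
  opt <- optimize(sse, c(lo, hi), tol = 1e-12)
  z0 <- opt$minimum
  M <- cbind(rho2, (z - z0)^2)
  ab <- qr.solve(crossprod(M), crossprod(M, rep(1, nrow(M))))
  list(
    center = C + z0 * s * n,
    R_max = s / sqrt(ab[1]),
    R_min = s / sqrt(ab[2]),
    rms = sqrt(opt$objective / nrow(M))
  )
}

#' Build the equatorial frame of a lens
#'
#' End-to-end geometric determination from three landmarks at the GZ/MR
#' boundary: (1) fit the landmark circle and its near-equatorial plane,
#' (2) orient the plane normal toward the data hemisphere, (3) find the
#' anterior pole along the polar ray, (4) refine the true equatorial radius
#' `R_max`, polar radius `R_min` and spheroid centre by an axisymmetric
#' least-squares spheroid fit to the whole cloud (the landmark circle sits at
#' the GZ/MR latitude, slightly below the true equator, so its radius alone
#' underestimates `R_max`). Radial distances `D1..D3` (landmarks to circle
#' centre) and `D4` (anterior pole to circle centre) are reported as-is.
#'
#' @param points point table or n x 3 matrix of detected nuclei, um.
#' @param landmarks 3 x 3 matrix (rows p1, p2, p3), um.
#' @param ap_tol_frac perpendicular gate for pole detection, fraction of the
#'   circle radius.
#' @return object of class `lens_frame`: landmark circle (`C`,
#'   `circle_radius`, oriented `n`), anterior pole `AP`, spheroid `center`,
#'   `R_max`, `R_min`, distances `D` (D1..D4) and fit diagnostics.
#' @export
build_frame <- function(points, landmarks, ap_tol_frac = 0.1) {
  landmarks <- as.matrix(landmarks)
  stopifnot(nrow(landmarks) == 3, ncol(landmarks) == 3)
  circ <- fit_circle_3pt(landmarks[1, ], landmarks[2, ], landmarks[3, ])
  n <- orient_normal(points, circ$C, circ$n)
  ap <- find_anterior_pole(points, circ$C, n, circ$radius, ap_tol_frac)
  sph <- fit_spheroid_axis(points, circ$C, n)
  structure(
    list(
      landmarks = landmarks,
      C = circ$C, circle_radius = circ$radius, n = n,
      AP = ap$AP, ap_index = ap$index,
      center = sph$center, R_max = sph$R_max, R_min = sph$R_min,
      spheroid_rms = sph$rms,
      D = c(
        D1 = sqrt(sum((landmarks[1, ] - circ$C)^2)),
        D2 = sqrt(sum((landmarks[2, ] - circ$C)^2)),
        D3 = sqrt(sum((landmarks[3, ] - circ$C)^2)),
        D4 = sqrt(sum((ap$AP - circ$C)^2))
      )
    ),
    class = "lens_frame"
  )
}

#' @export
print.lens_frame <- function(x, ...) {
  cat(sprintf(
    paste0(
      "lens_frame: R_max %.1f um, R_min %.1f um (aspect %.3f)\n",
      "  landmark circle radius %.1f um, D1-D4: %s um\n"
    ),
    x$R_max, x$R_min, x$R_min / x$R_max, x$circle_radius,
    paste(sprintf("%.1f", x$D), collapse = ", ")
  ))
  invisible(x)
}

#' Radial distances D1-D4
#'
#' Distances from the three landmarks and the anterior pole to the centre of
#' the fitted landmark circle.
#'
#' @param frame a [build_frame()] result.
#' @return named numeric vector `D1, D2, D3, D4` (um).
#' @export
radial_distances <- function(frame) {
  stopifnot(inherits(frame, "lens_frame"))
  frame$D
}

#' Rigidly align a point cloud to the canonical lens frame
#'
#' Rotates the cloud so the oriented equatorial normal becomes the +z axis,
#' translates the spheroid centre to the origin, and fixes the azimuthal
#' gauge by placing the first landmark at `phi = 0`. Anchoring the azimuth to
#' a landmark makes the whole mapping invariant under rigid motions of the
#' acquisition frame (a free azimuth would rotate with the mounting). All
#' pairwise distances are preserved. The transform is returned in attributes
#' (`rotation`, `translation`): `aligned = (p - center) %*% t(rotation)`.
#'
#' @param points point table or n x 3 matrix.
#' @param frame a [build_frame()] result.
#' @return points of the same class in the canonical frame.
#' @export
align_to_canonical <- function(points, frame) {
  stopifnot(inherits(frame, "lens_frame"))
  Rm <- rotation_between(frame$n, c(0, 0, 1))
  p1c <- as.vector(Rm %*% (frame$landmarks[1, ] - frame$center))
  if (sqrt(sum(p1c[1:2]^2)) > 1e-12) {
    gauge <- atan2(p1c[2], p1c[1])
    Rm <- rotation_matrix(-rad2deg(gauge), "z") %*% Rm
  }
  xyz <- sweep(coord_matrix(points), 2, frame$center) %*% t(Rm)
  out <- set_coords(points, xyz)
  attr(out, "rotation") <- Rm
  attr(out, "translation") <- -frame$center
  out
}

#' Spherical-angle coordinates on the normalized lens
#'
#' Points in the canonical frame are affinely normalized onto the unit sphere
#' (`x/R_max, y/R_max, z/R_min`), then assigned the polar angle `theta`
#' (degrees from the +z anterior-pole axis: pole 0, equator 90) and azimuth
#' `phi` in `[0, 360)`. Normalization makes `theta` well defined on lentoid
#' (non-spherical) lenses.
#'
#' @param points canonical-frame point table or n x 3 matrix.
#' @param R_max,R_min spheroid semi-axes, um.
#' @return data frame with `theta_deg`, `phi_deg`, and `r_norm` (normalized
#'   radius, 1 on the spheroid surface).
#' @export
spherical_coordinates <- function(points, R_max, R_min) {
  xyz <- coord_matrix(points)
  q <- cbind(xyz[, 1] / R_max, xyz[, 2] / R_max, xyz[, 3] / R_min)
  r <- sqrt(rowSums(q^2))
  if (any(r < 1e-12)) stop("undefined angle: point at the lens centre")
  theta <- rad2deg(acos(pmin(pmax(q[, 3] / r, -1), 1)))
  phi <- rad2deg(atan2(q[, 2], q[, 1])) %% 360
  phi[phi >= 360] <- 0  # guard the half-open range against rounding
  data.frame(theta_deg = theta, phi_deg = phi, r_norm = r)
}

#' Map a detected point cloud onto lens spherical coordinates
#'
#' Convenience wrapper: align to the canonical frame and fill `theta_deg` /
#' `phi_deg` in the table.
#'
#' @param points point table (raw acquisition frame).
#' @param frame a [build_frame()] result.
#' @return canonical-frame `point_table` with angles assigned.
#' @export
map_points <- function(points, frame) {
  aligned <- align_to_canonical(points, frame)
  ang <- spherical_coordinates(aligned, frame$R_max, frame$R_min)
  aligned$theta_deg <- ang$theta_deg
  aligned$phi_deg <- ang$phi_deg
  aligned
}

#' Whole-lens shape metrics
#'
#' Aspect ratio `R_min / R_max`, anterior hemisphere volume
#' `(2/3) pi R_max^2 R_min`, and the full oblate-spheroid volume (twice the
#' hemisphere).
#'
#' @param frame a [build_frame()] result, or a list with `R_max`, `R_min`.
#' @return named list `aspect_ratio`, `hemisphere_volume`, `spheroid_volume`
#'   (um^3).
#' @export
lens_metrics <- function(frame) {
  if (!(frame$R_max > 0 && frame$R_min > 0)) stop("radii must be positive")
  hemi <- 2 / 3 * pi * frame$R_max^2 * frame$R_min
  list(
    aspect_ratio = frame$R_min / frame$R_max,
    hemisphere_volume = hemi,
    spheroid_volume = 2 * hemi
  )
}
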