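`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about a coordinate or arbitrary axis
#'
#' Right-handed rotation by `angle_deg` degrees about `axis`, which is either
#' one of `"x"`, `"y"`, `"z"` or a length-3 direction vector.
#'
#' @param angle_deg rotation angle in degrees.
#' @param axis axis name or numeric direction vector (need not be unit length).
#' @return 3x3 orthonormal rotation matrix.
#' @export
rotation_matrix <- function(angle_deg, axis = "x") {
  if (is.character(axis)) {
    axis <- switch(match.arg(axis, c("x", "y", "z")),
      x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1)
    )
  }
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || nrm == 0) stop("rotation axis must be a nonzero vector")
  u <- axis / nrm
  a <- deg2rad(angle_deg)
  ca <- cos(a); sa <- sin(a)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  ca * diag(3) + sa * ux + (1 - ca) * tcrossprod(u)
}

# Rotation taking unit vector `from` onto unit vector `to` (Rodrigues).
rotation_between <- function(from, to) {
  f <- from / sqrt(sum(from^2)); t2 <- to / sqrt(sum(to^2))
  v <- c(
    f[2] * t2[3] - f[3] * t2[2],
    f[3] * t2[1] - f[1] * t2[3],
    f[1] * t2[2] - f[2] * t2[1]
  )
  s <- sqrt(sum(v^2)); c0 <- sum(f * t2)
  if (s < 1e-15) {
    if (c0 > 0) return(diag(3))
    # antipodal: rotate pi about any axis orthogonal to `f`
    ortho <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- ortho - sum(ortho * f) * f
    return(rotation_matrix(180, axis))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c0) / s^2)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Extract an n x 3 coordinate matrix (um) from a point table or matrix.
coord_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 3)
    return(unname(points))
  }
  if (is.data.frame(points)) {
    need <- c("x_um", "y_um", "z_um")
    if (!all(need %in% names(points))) {
      stop("point table lacks coordinate columns x_um/y_um/z_um")
    }
    return(unname(as.matrix(points[, need])))
  }
  stop("points must be a matrix or a point table data frame")
}

# Write coordinates back preserving the container type.
set_coords <- function(points, xyz) {
  if (is.matrix(points)) return(xyz)
  points$x_um <- xyz[, 1]; points$y_um <- xyz[, 2]; points$z_um <- xyz[, 3]
  points
}
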