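#' Voxel grid with physical spacing
#'
#' A `voxel_grid` couples a 3D intensity array with its physical voxel spacing
#' so that all downstream analysis runs in micrometres. The array is indexed
#' `[x, y, z]` with x the fastest axis; voxel `(i, j, k)` (1-based) has
#' physical centre `((i-1)*sx, (j-1)*sy, (k-1)*sz)/1000 + origin` in um, where
#' `spacing = c(sx, sy, sz)` is in nanometres per voxel.
#'
#' @param data numeric or integer 3D array, dimensions `(nx, ny, nz)`.
#'   A matrix is promoted to a single-slice stack.
#' @param spacing numeric length-3, voxel spacing in nm (x, y, z); all > 0.
#' @param origin physical coordinate (um) of voxel (1,1,1); default `c(0,0,0)`.
#' @return object of class `voxel_grid` with fields `data`, `spacing`, `origin`.
#' @export
voxel_grid <- function(data, spacing, origin = c(0, 0, 0)) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L) stop("voxel_grid data must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three strictly positive values (nm per voxel)")
  }
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "voxel_grid: %d x %d x %d voxels, spacing %.1f x %.1f x %.1f nm (%s)\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    if (is.integer(x$data)) "integer" else "float"
  ))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

# nm -> um spacing helper
spacing_um <- function(grid) grid$spacing / 1000

#' Map voxel indices to physical coordinates
#'
#' @param grid a [voxel_grid()].
#' @param ijk n x 3 matrix (or length-3 vector) of 1-based voxel indices;
#'   fractional indices are allowed.
#' @return n x 3 matrix of physical um coordinates (voxel-centre convention).
#' @export
voxel_to_um <- function(grid, ijk) {
  ijk <- rbind(ijk)
  sweep(sweep(ijk - 1, 2, spacing_um(grid), `*`), 2, grid$origin, `+`)
}

#' Inverse of [voxel_to_um()]
#'
#' @inheritParams voxel_to_um
#' @param xyz n x 3 matrix of physical um coordinates.
#' @return n x 3 matrix of fractional 1-based voxel indices.
#' @export
um_to_voxel <- function(grid, xyz) {
  xyz <- rbind(xyz)
  sweep(sweep(xyz, 2, grid$origin, `-`), 2, spacing_um(grid), `/`) + 1
}
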