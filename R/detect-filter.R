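# Separable Gaussian smoothing and the scale-normalized LoG likelihood map.

# 1D convolution along one array axis with replicate (edge-clamp) borders,
# implemented as a banded sparse-matrix product so large stacks stay fast.
conv_axis <- function(a, kernel, axis) {
  d <- dim(a)
  n <- d[axis]
  half <- (length(kernel) - 1L) / 2L
  offs <- seq.int(-half, half)
  i <- rep(seq_len(n), each = length(offs))
  j <- pmin(pmax(i + offs, 1L), n)  # replicate borders
  K <- Matrix::sparseMatrix(
    i = i, j = j, x = rep(kernel, times = n), dims = c(n, n)
  )
  perm <- c(axis, setdiff(seq_len(3L), axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  dim(ap) <- c(n, prod(dp[-1]))
  out <- as.matrix(K %*% ap)
  dim(out) <- dp
  aperm(out, order(perm))
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- dnorm(seq.int(-half, half), sd = sigma_vox)
  k / sum(k)
}

# Smooth a 3D array with per-axis Gaussian sigmas given in voxels.
gaussian_smooth3 <- function(a, sigma_vox) {
  for (ax in 1:3) {
    k <- gaussian_kernel_1d(sigma_vox[ax])
    if (length(k) > 1) a <- conv_axis(a, k, ax)
  }
  a
}

#' Laplacian-of-Gaussian blob likelihood map
#'
#' Convolves the stack with a Gaussian of physical scale `sigma = R / sqrt(3)`
#' (the scale at which a solid sphere of radius `R` maximizes the response)
#' and returns the negated, scale-normalized Laplacian `-sigma^2 *
#' Laplacian(G * I)`, computed with physical-unit second differences so that
#' anisotropic voxels are handled correctly. Bright blobs of radius about `R`
#' give positive peaks; a constant image gives an identically zero response,
#' and the map is linear in image intensity.
#'
#' @param grid a [voxel_grid()].
#' @param R expected nucleus radius, um. Must be at least the largest voxel
#'   dimension, otherwise the scale is unresolvable at this spacing.
#' @return a [voxel_grid()] holding the likelihood map (same shape/spacing).
#' @export
log_likelihood_map <- function(grid, R) {
  stopifnot(inherits(grid, "voxel_grid"))
  sp <- spacing_um(grid)
  if (R < max(sp)) {
    stop(
      "scale unresolvable at this spacing: R = ", R,
      " um is smaller than the largest voxel dimension (",
      format(max(sp), digits = 5), " um)"
    )
  }
  sigma <- R / sqrt(3)
  sm <- gaussian_smooth3(grid$data * 1.0, sigma / sp)
  lap <- 0
  for (ax in 1:3) {
    lap <- lap + conv_axis(sm, c(1, -2, 1), ax) / sp[ax]^2
  }
  out <- grid
  out$data <- -sigma^2 * lap
  out
}
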