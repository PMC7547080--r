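#' Render a phantom point cloud as a noisy confocal-like z-stack
#'
#' Each cell contributes an additive anisotropic Gaussian blob of physical
#' standard deviation `nucleus_radius / 2` per axis and amplitude
#' `peak_intensity`, on a constant `background`, with i.i.d. Gaussian read
#' noise of standard deviation `noise_sd`. The image frame covers the
#' as-mounted (tilted) cloud plus one nucleus radius of margin; the frame
#' offset is recorded in the grid's `origin` so stack coordinates map back to
#' lens coordinates. Deterministic given `config$seed`.
#'
#' @param truth output of [sample_epithelium()].
#' @param config the generating [synth_config()]; defaults to the attached one.
#' @return a [voxel_grid()] (double intensities).
#' @export
render_stack <- function(truth, config = attr(truth, "config")) {
  stopifnot(inherits(config, "synth_config"))
  sp_um <- config$spacing / 1000
  if (config$nucleus_radius < max(sp_um)) {
    warning(
      "nucleus_radius (", config$nucleus_radius, " um) is below the coarsest ",
      "voxel dimension (", max(sp_um), " um); detection will be unreliable"
    )
  }
  xyz <- coord_matrix(mounted_points(truth, config))
  margin <- config$nucleus_radius + 2 * sp_um
  if (nrow(xyz) > 0) {
    lo <- apply(xyz, 2, min) - margin
    hi <- apply(xyz, 2, max) + margin
  } else {
    # empty phantom: frame the (tilted) spheroid bounding box
    r <- c(config$r_max, config$r_max, config$r_min)
    lo <- -r - margin; hi <- r + margin
  }
  n_vox <- pmax(2L, ceiling((hi - lo) / sp_um) + 1L)
  grid <- voxel_grid(
    array(config$background, dim = n_vox),
    spacing = config$spacing, origin = lo
  )
  sigma <- rep(config$nucleus_radius / 2, 3)
  half <- pmax(1L, ceiling(3 * sigma / sp_um))

  for (m in seq_len(nrow(xyz))) {
    cv <- (xyz[m, ] - lo) / sp_um + 1  # fractional voxel index of the centre
    ix <- max(1L, floor(cv[1] - half[1])):min(n_vox[1], ceiling(cv[1] + half[1]))
    iy <- max(1L, floor(cv[2] - half[2])):min(n_vox[2], ceiling(cv[2] + half[2]))
    iz <- max(1L, floor(cv[3] - half[3])):min(n_vox[3], ceiling(cv[3] + half[3]))
    gx <- exp(-((ix - cv[1]) * sp_um[1])^2 / (2 * sigma[1]^2))
    gy <- exp(-((iy - cv[2]) * sp_um[2])^2 / (2 * sigma[2]^2))
    gz <- exp(-((iz - cv[3]) * sp_um[3])^2 / (2 * sigma[3]^2))
    blob <- config$peak_intensity * outer(outer(gx, gy), gz)
    grid$data[ix, iy, iz] <- grid$data[ix, iy, iz] + blob
  }

  if (config$noise_sd > 0) {
    grid$data <- grid$data + with_seed(
      config$seed + 1L,
      array(rnorm(prod(n_vox), 0, config$noise_sd), dim = n_vox)
    )
  }
  grid
}

# Note on frames: a rendered grid carries its `origin`, and voxel_to_um()
# folds it in, so detections on a rendered stack come out directly in lens
# coordinates — comparable to mounted_points() without any shift.
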