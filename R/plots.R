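# Basic figures: theta density profile and transect density curve.

#' Plot a polar-angle density profile
#'
#' Raw and smoothed density against theta, with optional extremum and zone
#' annotations.
#'
#' @param profile a [theta_density_profile()] result.
#' @param segmentation optional [zone_segmentation()] result to annotate.
#' @param ... passed to [plot()].
#' @return invisibly, `NULL`.
#' @export
plot_density_profile <- function(profile, segmentation = NULL, ...) {
  plot(
    profile$theta_mid, profile$density,
    type = "h", col = "grey70", lwd = 2,
    xlab = expression(theta * " (degrees from anterior pole)"),
    ylab = expression("density (cells / 1000 " * mu * m^2 * ")"),
    ...
  )
  lines(profile$theta_mid, profile$density_smooth, col = "firebrick", lwd = 2)
  if (!is.null(segmentation)) {
    abline(v = segmentation$theta_min_angle, lty = 2, col = "steelblue")
    abline(v = segmentation$theta_max_angle, lty = 2, col = "firebrick")
    abline(v = segmentation$theta_mr_start, lty = 3)
    legend(
      "topleft", bty = "n", lty = c(2, 2, 3),
      col = c("steelblue", "firebrick", "black"),
      legend = c("profile minimum", "profile maximum", "MR onset")
    )
  }
  invisible(NULL)
}

#' Plot a transect density profile
#'
#' @param roi_profile an [roi_density()] result.
#' @param ... passed to [plot()].
#' @return invisibly, `NULL`.
#' @export
plot_roi_profile <- function(roi_profile, ...) {
  s_mid <- (roi_profile$s_lo + roi_profile$s_hi) / 2
  plot(
    s_mid, roi_profile$density_per_um, type = "b", pch = 16,
    xlab = expression("arc position along transect (" * mu * "m)"),
    ylab = expression("nuclei per neighbourhood / " * mu * "m"),
    ...
  )
  invisible(NULL)
}
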