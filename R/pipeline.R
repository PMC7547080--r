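# End-to-end orchestration with plain-file handoffs and a run manifest.

#' Run the whole-lens mapping pipeline
#'
#' Executes detect -> map -> zones (and optionally roi) on either a real
#' stack or a synthetic preset, writing every stage product as a plain file:
#' `nuclei.csv`, `mapped.csv`, `frame.json`, `profile.csv`, `zones.csv`,
#' per-nucleus `zone_points.csv`, optional `roi.csv`, and `manifest.json`
#' echoing the effective configuration. With a synthetic preset the stack is
#' not rendered by default (the ground-truth cloud feeds the geometric
#' stages directly, which is how the phantom validates mapping); set
#' `render = TRUE` to run detection on a rendered stack instead.
#'
#' @param stack path to a TIFF stack, or `NULL` when `preset` is given.
#' @param preset `"mature"` or `"young"` for a synthetic run.
#' @param landmarks 3 x 3 matrix of GZ/MR boundary landmarks (um). Required
#'   for real stacks; defaults to the planted boundary for synthetic runs.
#' @param outdir output directory (created if needed).
#' @param params a [detection_params()].
#' @param roi optional [roi_spec()] for transect analysis.
#' @param seed integer seed for synthetic generation.
#' @param render render and detect the synthetic stack rather than using the
#'   ground-truth cloud.
#' @param config optional [synth_config()] overriding `preset`/`seed`.
#' @param bin_width,smooth_window,drop_fraction zone-profile settings.
#' @return invisibly, a list with the mapped points, frame, profile and
#'   segmentation (plus roi profile if requested).
#' @export
run_pipeline <- function(stack = NULL, preset = NULL, landmarks = NULL,
                         outdir, params = detection_params(), roi = NULL,
                         seed = 1L, render = FALSE, config = NULL,
                         bin_width = 5, smooth_window = 3,
                         drop_fraction = 0.5) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "epilens",
    version = as.character(utils::packageVersion("epilens")),
    seed = seed,
    detection = unclass(params),
    bin_width = bin_width, smooth_window = smooth_window,
    drop_fraction = drop_fraction
  )

  if (!is.null(stack)) {
    grid <- read_stack(stack)
    if (is.null(landmarks)) stop("map: landmarks required for a real stack")
    nuclei <- detect_nuclei(grid, params)
    manifest$input <- list(
      stack = stack, md5 = unname(tools::md5sum(stack))
    )
  } else {
    cfg <- config %||% lens_preset(preset %||% "mature", seed = seed)
    manifest$synth <- unclass(cfg)
    truth <- sample_epithelium(cfg)
    write_points(truth, file.path(outdir, "truth.csv"))
    if (is.null(landmarks)) landmarks <- gz_mr_landmarks(cfg)
    if (render) {
      grid <- render_stack(truth, cfg)
      write_stack(grid, file.path(outdir, "stack.tif"))
      # the grid carries its origin, so detections are in lens coordinates
      nuclei <- detect_nuclei(grid, params)
    } else {
      nuclei <- mounted_points(truth, cfg)
    }
  }
  write_points(nuclei, file.path(outdir, "nuclei.csv"))
  manifest$n_nuclei <- nrow(nuclei)

  frame <- build_frame(nuclei, landmarks)
  mapped <- map_points(nuclei, frame)
  write_points(mapped, file.path(outdir, "mapped.csv"))
  metrics <- lens_metrics(frame)
  jsonlite::write_json(
    list(
      C = frame$C, circle_radius = frame$circle_radius, n = frame$n,
      AP = frame$AP, center = frame$center,
      R_max = frame$R_max, R_min = frame$R_min,
      D = as.list(frame$D), aspect_ratio = metrics$aspect_ratio,
      hemisphere_volume = metrics$hemisphere_volume,
      spheroid_volume = metrics$spheroid_volume
    ),
    file.path(outdir, "frame.json"),
    auto_unbox = TRUE, digits = NA
  )

  profile <- theta_density_profile(
    mapped, frame = frame, bin_width = bin_width,
    smooth_window = smooth_window
  )
  write.csv(profile, file.path(outdir, "profile.csv"), row.names = FALSE)
  seg <- zone_segmentation(profile, mapped, drop_fraction = drop_fraction)
  mapped$zone <- seg$zone
  write_points(mapped, file.path(outdir, "mapped.csv"))
  zsum <- data.frame(
    theta_min_angle = seg$theta_min_angle,
    theta_max_angle = seg$theta_max_angle,
    theta_mr_start = seg$theta_mr_start,
    theta_edge = seg$theta_edge,
    pct_cz = seg$percent["CZ"], pct_gz = seg$percent["GZ"],
    pct_mr = seg$percent["MR"],
    n_cz = seg$counts["CZ"], n_gz = seg$counts["GZ"], n_mr = seg$counts["MR"]
  )
  write.csv(zsum, file.path(outdir, "zones.csv"), row.names = FALSE)
  manifest$zones <- as.list(zsum)

  result <- list(
    nuclei = nuclei, frame = frame, mapped = mapped,
    profile = profile, segmentation = seg
  )
  if (!is.null(roi)) {
    rprof <- roi_density(mapped, roi)
    write.csv(rprof, file.path(outdir, "roi.csv"), row.names = FALSE)
    manifest$roi <- unclass(roi)
    result$roi <- rprof
  }
  jsonlite::write_json(
    manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
  )
  invisible(result)
}
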