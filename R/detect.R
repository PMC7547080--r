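#' Detection parameters
#'
#' One radius `R` drives both the LoG scale and the local-maximum
#' neighbourhood, mirroring the coupling of the detection model. Thresholds
#' are image-quality dependent and deliberately user-tunable.
#'
#' @param R expected nucleus radius, um (LoG scale and dilation radius).
#' @param intensity_threshold minimum peak intensity for a candidate: an
#'   absolute number, `"qNN"` for the NN-th stack percentile, `"otsu"`,
#'   `"floor"` for a robust noise floor of `median + 6 * MAD`, or `"auto"`
#'   (default) for the larger of the Otsu and floor thresholds.
#' @param circularity_threshold minimum region circularity in `[0, 1]`.
#' @param watershed_enabled split touching nuclei by seeded watershed and use
#'   region centroids; if `FALSE`, centroids are peak voxel centres and no
#'   circularity filtering is possible.
#' @param mask_threshold foreground threshold for segmentation: a number,
#'   `"qNN"`, `"otsu"`, `"floor"`, or `"auto"` (default).
#' @return object of class `detection_params`.
#' @export
detection_params <- function(R = 6, intensity_threshold = "auto",
                             circularity_threshold = 0.3,
                             watershed_enabled = TRUE,
                             mask_threshold = "auto") {
  if (R <= 0) stop("R must be positive")
  if (is.numeric(circularity_threshold) &&
      (circularity_threshold < 0 || circularity_threshold > 1)) {
    stop("circularity_threshold must be in [0, 1]")
  }
  structure(
    list(
      R = R, intensity_threshold = intensity_threshold,
      circularity_threshold = circularity_threshold,
      watershed_enabled = isTRUE(watershed_enabled),
      mask_threshold = mask_threshold
    ),
    class = "detection_params"
  )
}

#' Detect nuclear centroids in a z-stack
#'
#' Full detection pipeline: LoG likelihood map ([log_likelihood_map()]),
#' grayscale-dilation local maxima ([local_maxima()]), seeded watershed
#' segmentation with circularity scoring ([segment_and_score()]), then
#' intensity and circularity filtering. Candidates are kept iff their peak
#' intensity reaches `intensity_threshold` and (with watershed enabled) their
#' region circularity reaches `circularity_threshold`.
#'
#' @param grid a [voxel_grid()].
#' @param params a [detection_params()].
#' @return `point_table` of detected nuclei in um (stack frame), with
#'   `intensity` = peak intensity and `circularity` filled; stage counts in
#'   `attr(, "stage_counts")`.
#' @export
detect_nuclei <- function(grid, params = detection_params()) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(params, "detection_params"))
  resp <- log_likelihood_map(grid, params$R)
  seeds <- local_maxima(resp, params$R)
  int_thr <- resolve_threshold(params$intensity_threshold, grid$data)
  n_candidates <- nrow(seeds)
  # intensity gate before segmentation: sub-threshold candidates can never be
  # kept, and excluding them keeps the watershed seed set small
  seeds <- seeds[grid$data[seeds] >= int_thr, , drop = FALSE]

  if (params$watershed_enabled) {
    seg <- segment_and_score(grid, seeds, params)
    # split regions may introduce seeds below the gate; re-apply it
    keep <- seg$peak_intensity >= int_thr &
      !is.na(seg$circularity) &
      seg$circularity >= params$circularity_threshold
    kept <- seg[keep, , drop = FALSE]
    pt <- point_table(
      x_um = kept$x_um, y_um = kept$y_um, z_um = kept$z_um,
      id = seq_len(nrow(kept)),
      intensity = kept$peak_intensity,
      circularity = kept$circularity
    )
    pt$on_border <- kept$on_border
    counts <- c(
      candidates = n_candidates, above_intensity = nrow(seeds),
      segmented = nrow(seg), kept = nrow(kept)
    )
  } else {
    xyz <- voxel_to_um(grid, seeds)
    pt <- point_table(
      x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
      id = seq_len(nrow(seeds)),
      intensity = grid$data[seeds],
      circularity = NA_real_
    )
    counts <- c(
      candidates = n_candidates, above_intensity = nrow(seeds),
      segmented = NA, kept = nrow(seeds)
    )
  }
  attr(pt, "stage_counts") <- counts
  attr(pt, "intensity_threshold") <- int_thr
  pt
}

#' Match two point sets within a radius
#'
#' Greedy closest-pair matching (ascending distance, each point used once),
#' used to score detections against ground truth.
#'
#' @param detected,truth point tables or n x 3 matrices (um).
#' @param radius maximum match distance, um.
#' @return list with `matches` (two-column index matrix into detected/truth),
#'   `precision`, `recall`.
#' @export
match_point_sets <- function(detected, truth, radius) {
  a <- coord_matrix(detected); b <- coord_matrix(truth)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(list(
      matches = matrix(integer(), ncol = 2),
      precision = if (nrow(a)) 0 else NA_real_,
      recall = if (nrow(b)) 0 else NA_real_
    ))
  }
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  cand <- which(d2 <= radius^2, arr.ind = TRUE)
  if (nrow(cand)) cand <- cand[order(d2[cand]), , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  sel <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE; sel[r] <- TRUE
    }
  }
  m <- cand[sel, , drop = FALSE]
  list(
    matches = m,
    precision = nrow(m) / nrow(a),
    recall = nrow(m) / nrow(b)
  )
}
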