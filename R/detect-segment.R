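# Foreground thresholding, seeded watershed and region scoring.

#' Otsu threshold of an intensity array
#'
#' Classic between-class-variance maximization on a fixed-width histogram.
#' Used as the default foreground (mask) threshold for segmentation.
#'
#' @param x numeric vector or array.
#' @param levels number of histogram bins.
#' @return threshold value (a bin boundary on the intensity scale).
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- as.vector(x)
  r <- range(x, finite = TRUE)
  if (r[1] == r[2]) return(r[1])
  br <- seq(r[1], r[2], length.out = levels + 1L)
  h <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), levels),
                nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-length(br)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bcv[!is.finite(bcv)] <- -Inf
  br[which.max(bcv) + 1L]
}

# Seeded (marker-controlled) watershed by quantized Meyer flooding.
#
# altitude: numeric array (lower = flooded first); mask: logical array;
# seeds: n x 3 voxel indices. Returns an integer label array (0 = unclaimed);
# seed m gets label m. Flooding is restricted to the mask and grows only from
# seeded basins, level by level over `levels` altitude quanta; within a level,
# labels propagate by synchronous 6-neighbour sweeps, each voxel taking the
# label of its lowest-altitude labelled neighbour (axis order breaks ties),
# which makes the result deterministic.
watershed_seeded <- function(altitude, mask, seeds, levels = 256L) {
  d <- dim(altitude)
  stopifnot(identical(d, dim(mask)))
  labels <- array(0L, dim = d)
  if (nrow(seeds) == 0) return(labels)
  seed_idx <- seeds[, 1] + d[1] * (seeds[, 2] - 1L) + d[1] * d[2] * (seeds[, 3] - 1L)
  in_mask <- mask[seed_idx]
  labels[seed_idx[in_mask]] <- which(in_mask)
  attr(labels, "dropped_seeds") <- which(!in_mask)
  if (!any(in_mask)) return(labels)

  mvox <- which(mask & labels == 0L)
  if (!length(mvox)) return(labels)
  alt <- altitude[mvox]
  qbr <- seq(min(alt), max(alt), length.out = levels + 1L)
  lev <- pmin(findInterval(alt, qbr, rightmost.closed = TRUE), levels)

  pos <- array(0L, dim = d)          # voxel linear index -> row in mvox
  pos[mvox] <- seq_along(mvox)
  nb_off <- c(-1L, 1L, -d[1], d[1], -d[1] * d[2], d[1] * d[2])
  ijk <- arrayInd(mvox, d)
  nb_ok <- cbind(
    ijk[, 1] > 1L, ijk[, 1] < d[1],
    ijk[, 2] > 1L, ijk[, 2] < d[2],
    ijk[, 3] > 1L, ijk[, 3] < d[3]
  )
  pending <- rep(TRUE, length(mvox))
  frontier_of <- function(vox_lin, ijk3) {
    # pending mask voxels 6-adjacent to the given labelled voxels
    res <- integer(0)
    for (t in 1:6) {
      ok <- switch(t,
        ijk3[, 1] > 1L, ijk3[, 1] < d[1],
        ijk3[, 2] > 1L, ijk3[, 2] < d[2],
        ijk3[, 3] > 1L, ijk3[, 3] < d[3]
      )
      nb <- vox_lin[ok] + nb_off[t]
      p <- pos[nb]
      res <- c(res, p[p > 0L & pending[pmax(p, 1L)]])
    }
    unique(res[pending[res]])
  }
  seed_lin <- seed_idx[in_mask]
  cand <- logical(length(mvox))
  cand[frontier_of(seed_lin, arrayInd(seed_lin, d))] <- TRUE

  for (L in seq_len(levels)) {
    repeat {
      act <- which(cand & lev <= L)
      if (!length(act)) break
      best_lab <- integer(length(act))
      best_alt <- rep(Inf, length(act))
      vox <- mvox[act]
      for (t in 1:6) {
        ok <- nb_ok[act, t]
        nb <- vox[ok] + nb_off[t]
        lab <- labels[nb]
        has <- lab > 0L
        if (!any(has)) next
        hit <- which(ok)[has]
        a_nb <- altitude[nb[has]]
        better <- a_nb < best_alt[hit]
        upd <- hit[better]
        best_lab[upd] <- lab[has][better]
        best_alt[upd] <- a_nb[better]
      }
      got <- best_lab > 0L
      if (!any(got)) break
      newly <- act[got]
      labels[mvox[newly]] <- best_lab[got]
      pending[newly] <- FALSE
      cand[newly] <- FALSE
      grow <- frontier_of(mvox[newly], ijk[newly, , drop = FALSE])
      cand[grow] <- TRUE
    }
  }
  labels
}

#' Segment the stack around detected seeds and score region shape
#'
#' Defines the foreground as `grid >= mask_threshold`, runs a seeded watershed
#' on the inverted Gaussian-smoothed intensity (so each seed floods its own
#' basin, splitting partially overlapping nuclei), and scores every region
#' with a 3D circularity: `sqrt(lambda_min / lambda_max)` of the region's
#' second-moment matrix computed in physical um coordinates, with Sheppard's
#' discretization correction (`+ h^2/12` per axis) so thin regions at coarse
#' axial spacing are not spuriously degenerate. Regions touching the image
#' border are flagged.
#'
#' @param grid a [voxel_grid()] of raw intensities.
#' @param seeds voxel-index matrix from [local_maxima()].
#' @param params a [detection_params()].
#' Partially overlapping nuclei closer than the resolution of the smoothed
#' likelihood field (about `2 * sqrt(sigma_blob^2 + sigma_LoG^2)`) collapse
#' into a single seed upstream; such merged regions remain bimodal in the raw
#' intensity, so a second pass re-seeds any region holding two or more
#' in-region raw-intensity maxima separated by at least `R` and re-floods.
#' A single nucleus cannot trigger a split: all of its supra-mask voxels lie
#' well within one radius of its core.
#'
#' @return data frame with one row per surviving seed: centroid
#'   (intensity-weighted, um), peak intensity, circularity, voxel count,
#'   volume (um^3) and border flag; the label array is in `attr(, "labels")`.
#' @export
segment_and_score <- function(grid, seeds, params = detection_params()) {
  stopifnot(inherits(grid, "voxel_grid"))
  sp <- spacing_um(grid)
  thr <- resolve_threshold(params$mask_threshold, grid$data)
  mask <- grid$data >= thr
  sm <- gaussian_smooth3(grid$data * 1.0, (params$R / sqrt(3)) / sp)
  labels <- watershed_seeded(-sm, mask, seeds)

  split_seeds <- split_merged_regions(grid, labels, seeds, params$R, sp)
  if (nrow(split_seeds) > nrow(seeds)) {
    seeds <- split_seeds
    labels <- watershed_seeded(-sm, mask, seeds)
  }

  d <- dim(grid$data)
  n_seed <- nrow(seeds)
  out <- data.frame(
    seed_i = seeds[, 1], seed_j = seeds[, 2], seed_k = seeds[, 3],
    label = seq_len(n_seed),
    x_um = rep(NA_real_, n_seed), y_um = rep(NA_real_, n_seed),
    z_um = rep(NA_real_, n_seed),
    peak_intensity = if (n_seed) grid$data[seeds] else numeric(0),
    circularity = rep(NA_real_, n_seed), n_voxels = rep(0L, n_seed),
    volume_um3 = rep(NA_real_, n_seed), on_border = rep(FALSE, n_seed)
  )
  lab_idx <- which(labels > 0L)
  if (length(lab_idx)) {
    lab <- labels[lab_idx]
    ijk <- arrayInd(lab_idx, d)
    xyz <- voxel_to_um(grid, ijk)
    w <- grid$data[lab_idx]
    grp <- split(seq_along(lab), lab)
    shepard <- diag(sp^2 / 12)
    for (g in names(grp)) {
      rows <- grp[[g]]
      m <- as.integer(g)
      ww <- w[rows]
      if (sum(ww) <= 0) ww <- rep(1, length(rows))
      ctr <- colSums(xyz[rows, , drop = FALSE] * ww) / sum(ww)
      cov3 <- crossprod(sweep(xyz[rows, , drop = FALSE], 2,
                              colMeans(xyz[rows, , drop = FALSE]))) /
        length(rows) + shepard
      ev <- eigen(cov3, symmetric = TRUE, only.values = TRUE)$values
      out$x_um[m] <- ctr[1]; out$y_um[m] <- ctr[2]; out$z_um[m] <- ctr[3]
      out$circularity[m] <- sqrt(max(ev[3], 0) / ev[1])
      out$n_voxels[m] <- length(rows)
      out$volume_um3[m] <- length(rows) * prod(sp)
      out$on_border[m] <- any(ijk[rows, 1] %in% c(1L, d[1])) ||
        any(ijk[rows, 2] %in% c(1L, d[2])) ||
        any(ijk[rows, 3] %in% c(1L, d[3]))
    }
  }
  empty <- out$n_voxels == 0L
  if (any(empty)) {
    attr(out, "dropped") <- which(empty)
    out <- out[!empty, , drop = FALSE]
  }
  attr(out, "labels") <- labels
  attr(out, "mask_threshold") <- thr
  out
}

# Re-seed watershed regions that contain several raw-intensity cores.
# For each labelled region, find in-region local maxima of the raw intensity
# under the physical ellipsoid neighbourhood of radius R (brute force; the
# regions are small). Regions with >= 2 such cores contribute all of them as
# seeds; all other regions keep their original seed.
split_merged_regions <- function(grid, labels, seeds, R, sp) {
  d <- dim(grid$data)
  lab_idx <- which(labels > 0L)
  if (!length(lab_idx)) return(seeds)
  lab <- labels[lab_idx]
  new_seeds <- vector("list", nrow(seeds))
  for (m in seq_len(nrow(seeds))) new_seeds[[m]] <- seeds[m, , drop = FALSE]
  grp <- split(lab_idx, lab)
  for (g in names(grp)) {
    vox <- grp[[g]]
    # cap the in-region pairwise computation; regions beyond ~3000 voxels are
    # far larger than any nucleus and not meaningful split candidates
    if (length(vox) < 2L || length(vox) > 3000L) next
    ijk <- arrayInd(vox, d)
    vals <- grid$data[vox]
    pos <- sweep(ijk, 2, sp, `*`)
    # in-region maxima: no in-region voxel within the ellipsoid is larger,
    # equal values resolved by linear index
    d2 <- outer(rowSums((pos / R)^2), rowSums((pos / R)^2), `+`) -
      2 * tcrossprod(pos / R)
    within <- d2 <= 1
    is_max <- vapply(seq_along(vox), function(i) {
      nb <- within[i, ] & seq_along(vox) != i
      all(vals[nb] < vals[i] | (vals[nb] == vals[i] & vox[nb] > vox[i]))
    }, logical(1))
    if (sum(is_max) >= 2L) {
      new_seeds[[as.integer(g)]] <- ijk[is_max, , drop = FALSE]
    }
  }
  out <- do.call(rbind, new_seeds)
  colnames(out) <- c("i", "j", "k")
  out
}

# Threshold spec: a number (absolute), "qNN[.N]" (stack quantile, percent),
# "otsu", "floor" (median + 6 * MAD robust noise floor), or "auto" (the
# larger of the Otsu and floor thresholds — Otsu handles clean bimodal
# images, the floor guards against Otsu splitting the noise when foreground
# occupies a tiny image fraction).
resolve_threshold <- function(spec, data) {
  if (is.numeric(spec)) return(spec)
  if (is.character(spec)) {
    if (identical(spec, "otsu")) return(otsu_threshold(data))
    if (identical(spec, "floor")) {
      return(median(data) + 6 * mad(as.vector(data)))
    }
    if (identical(spec, "auto")) {
      return(max(
        otsu_threshold(data),
        median(data) + 6 * mad(as.vector(data))
      ))
    }
    if (grepl("^q[0-9.]+$", spec)) {
      q <- as.numeric(sub("^q", "", spec))
      if (is.finite(q) && q >= 0 && q <= 100) {
        return(as.numeric(quantile(data, q / 100, names = FALSE)))
      }
    }
  }
  stop("unrecognized threshold specification: ", deparse(spec))
}
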