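# Transect (region-of-interest) density analysis: local density along a
# user-defined anterior-to-equator vector, in the style of a gridded
# rectangular ROI with per-grid nucleus neighbourhoods.

#' Region-of-interest specification
#'
#' A transect from `P1` to `P2` of length `D`, divided into `n_grids` equal
#' segments. Nuclei within `capture_halfwidth` of the segment are anchors;
#' each grid's neighbourhood is the union of its anchors and their
#' `neighbor_k` nearest nuclei.
#'
#' @param P1,P2 transect endpoints, um (length-3).
#' @param n_grids number of equal-length grids (>= 1).
#' @param capture_halfwidth half-width of the capture rectangle, um.
#' @param neighbor_k number of nearest neighbours per anchor.
#' @return object of class `roi_spec`.
#' @export
roi_spec <- function(P1, P2, n_grids = 20, capture_halfwidth = 9,
                     neighbor_k = 6) {
  P1 <- as.numeric(P1); P2 <- as.numeric(P2)
  stopifnot(length(P1) == 3, length(P2) == 3)
  if (sqrt(sum((P2 - P1)^2)) == 0) stop("zero-length transect: P1 equals P2")
  if (n_grids < 1) stop("n_grids must be >= 1")
  if (capture_halfwidth <= 0) stop("capture_halfwidth must be positive")
  if (neighbor_k < 0) stop("neighbor_k must be >= 0")
  structure(
    list(
      P1 = P1, P2 = P2, n_grids = as.integer(n_grids),
      capture_halfwidth = capture_halfwidth, neighbor_k = as.integer(neighbor_k)
    ),
    class = "roi_spec"
  )
}

#' Local density along a transect
#'
#' Anchors are nuclei whose projection onto the segment `P1 P2` falls inside
#' it and whose perpendicular distance is at most the capture half-width.
#' Each anchor belongs to the grid containing its projection. A grid's
#' neighbourhood is the union of its anchors and each anchor's `neighbor_k`
#' nearest nuclei over the whole cloud (deduplicated within the grid; a
#' nucleus may appear in several grids). Density is the neighbourhood count
#' divided by the grid length, i.e. nuclei per neighbourhood per um.
#'
#' @param points point table or n x 3 matrix, um.
#' @param roi an [roi_spec()].
#' @return data frame of class `roi_profile` with one row per grid: arc
#'   interval (`s_lo`, `s_hi`, um from P1), `n_anchors`, `n_neighborhood`,
#'   `density_per_um`; transect length `D` in `attr(, "D")`.
#' @export
roi_density <- function(points, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  xyz <- coord_matrix(points)
  v <- roi$P2 - roi$P1
  D <- sqrt(sum(v^2))
  ng <- roi$n_grids
  glen <- D / ng

  out <- data.frame(
    grid = seq_len(ng),
    s_lo = (seq_len(ng) - 1) * glen,
    s_hi = seq_len(ng) * glen,
    n_anchors = 0L, n_neighborhood = 0L, density_per_um = 0
  )
  if (nrow(xyz)) {
    w <- sweep(xyz, 2, roi$P1)
    tproj <- as.vector(w %*% v) / D^2            # in [0,1] on the segment
    perp <- sqrt(pmax(rowSums(w^2) - (tproj * D)^2, 0))
    anchor <- tproj >= 0 & tproj <= 1 & perp <= roi$capture_halfwidth
    grid_of <- pmin(floor(tproj * ng) + 1L, ng)

    if (any(anchor)) {
      ai <- which(anchor)
      nbrs <- vector("list", length(ai))
      if (roi$neighbor_k > 0) {
        d2 <- outer(rowSums(xyz[ai, , drop = FALSE]^2), rowSums(xyz^2), `+`) -
          2 * tcrossprod(xyz[ai, , drop = FALSE], xyz)
        for (m in seq_along(ai)) {
          ord <- order(d2[m, ])
          nbrs[[m]] <- setdiff(ord, ai[m])[seq_len(min(roi$neighbor_k, nrow(xyz) - 1L))]
        }
      }
      for (g in seq_len(ng)) {
        rows <- which(grid_of[ai] == g)
        if (!length(rows)) next
        hood <- unique(c(ai[rows], unlist(nbrs[rows])))
        out$n_anchors[g] <- length(rows)
        out$n_neighborhood[g] <- length(hood)
        out$density_per_um[g] <- length(hood) / glen
      }
    }
  }
  attr(out, "D") <- D
  attr(out, "roi") <- roi
  class(out) <- c("roi_profile", "data.frame")
  out
}
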