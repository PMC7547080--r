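# Grayscale dilation by a discrete ellipsoid and local-maximum extraction.

# Integer offsets (excluding the origin) inside the ellipsoid of physical
# radius R at voxel spacing sp (um); semi-axes R/sp[k] voxels per axis.
ellipsoid_offsets <- function(R, sp) {
  half <- pmax(1L, floor(R / sp))
  g <- expand.grid(
    dx = -half[1]:half[1], dy = -half[2]:half[2], dz = -half[3]:half[3]
  )
  r2 <- (g$dx * sp[1] / R)^2 + (g$dy * sp[2] / R)^2 + (g$dz * sp[3] / R)^2
  keep <- r2 <= 1 & !(g$dx == 0 & g$dy == 0 & g$dz == 0)
  as.matrix(g[keep, , drop = FALSE])
}

# Grayscale dilation: per-voxel max over the structuring element (centre
# included). Outside-image neighbours contribute -Inf.
dilate_ellipsoid <- function(a, offsets) {
  d <- dim(a)
  out <- a
  for (r in seq_len(nrow(offsets))) {
    off <- offsets[r, ]
    sx <- seq_len(d[1]) + off[1]; okx <- sx >= 1L & sx <= d[1]
    sy <- seq_len(d[2]) + off[2]; oky <- sy >= 1L & sy <= d[2]
    sz <- seq_len(d[3]) + off[3]; okz <- sz >= 1L & sz <= d[3]
    if (!any(okx) || !any(oky) || !any(okz)) next
    sub <- out[okx, oky, okz, drop = FALSE]
    shifted <- a[sx[okx], sy[oky], sz[okz], drop = FALSE]
    out[okx, oky, okz] <- pmax(sub, shifted)
  }
  out
}

#' Local maxima of a likelihood map
#'
#' A voxel is a candidate nucleus location when its likelihood equals the
#' grayscale dilation of the map by a discrete ellipsoidal structuring element
#' of physical radius `R` (semi-axes `R/spacing` voxels, so the neighbourhood
#' is isotropic in physical space) and the likelihood is strictly positive.
#' Within a plateau of equal values spanning the structuring element, only the
#' voxel with the smallest linear (x-fastest) index is kept, so output is
#' deterministic.
#'
#' @param likelihood a [voxel_grid()], typically from [log_likelihood_map()]
#'   with the same `R`.
#' @param R neighbourhood radius, um.
#' @return integer matrix with columns `i, j, k` (1-based voxel indices),
#'   ordered by increasing linear index.
#' @export
local_maxima <- function(likelihood, R) {
  stopifnot(inherits(likelihood, "voxel_grid"))
  a <- likelihood$data
  offsets <- ellipsoid_offsets(R, spacing_um(likelihood))
  dil <- dilate_ellipsoid(a, offsets)
  idx <- which(a == dil & a > 0)
  if (!length(idx)) {
    return(matrix(integer(), ncol = 3, dimnames = list(NULL, c("i", "j", "k"))))
  }
  idx <- sort(idx)
  ijk <- arrayInd(idx, dim(a))
  # plateau tie-break: drop a candidate if an equal-valued candidate with a
  # smaller linear index lies within its structuring element
  vals <- a[idx]
  dup_vals <- unique(vals[duplicated(vals)])
  if (length(dup_vals)) {
    drop <- logical(length(idx))
    sp <- spacing_um(likelihood)
    for (v in dup_vals) {
      grp <- which(vals == v)
      for (gi in seq_along(grp)[-1]) {
        for (gj in seq_len(gi - 1)) {
          dv <- (ijk[grp[gi], ] - ijk[grp[gj], ]) * sp
          if (sum((dv / R)^2) <= 1 && !drop[grp[gj]]) {
            drop[grp[gi]] <- TRUE
            break
          }
        }
      }
    }
    ijk <- ijk[!drop, , drop = FALSE]
  }
  colnames(ijk) <- c("i", "j", "k")
  ijk
}
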