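# boundary voxels: in-mask voxels with a 6-neighbour outside the mask
boundary_voxels <- function(m) {
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  core & !nb
}

max_diameter <- function(coords) {
  n <- nrow(coords)
  if (n < 2) return(0)
  best <- 0
  step <- 1500L
  r2 <- rowSums(coords^2)
  for (s in seq(1, n, by = step)) {
    e <- min(s + step - 1L, n)
    g <- coords %*% t(coords[s:e, , drop = FALSE])
    d2 <- outer(r2, rep(1, e - s + 1)) + outer(rep(1, n), r2[s:e]) - 2 * g
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' Mesh-based morphology features of a tumor mask
#'
#' Surface and volume come from a closed triangulation of the mask boundary
#' (marching tetrahedra at the 0.5 level); the ratio `surface_area / volume`
#' is the surface-to-volume ratio that the prognostic model uses, minimized
#' over all shapes by a sphere (A/V = 3/r). Axis lengths derive from the
#' principal components of the voxel-center coordinates; `com_shift` (distance
#' in mm between the geometric and intensity-weighted centroids) is computed
#' when `vol` is supplied.
#'
#' @param mask An [roi_mask()], assumed resampled to isotropic voxels.
#' @param vol Optional [image_volume()] on the same grid for the
#'   intensity-weighted centre-of-mass shift.
#' @return Named numeric vector of `morph.*` features.
#' @examples
#' ph <- make_phantom(phantom_spec(radius_mm = 8))
#' f <- morphology_features(ph$mask)
#' f["morph.surf_to_vol_ratio"] # close to 3/8
#' @export
morphology_features <- function(mask, vol = NULL) {
  stopifnot(inherits(mask, "edr_mask"))
  check_nonempty_mask(mask)
  if (sum(mask$values) < 2) {
    abort("mesh morphology undefined for a single-voxel mask",
          class = "edrisk_degenerate_morphology")
  }
  sp <- mask$spacing
  ms <- mesh_stats(mask)
  A <- ms$surface_area; V <- ms$volume
  v_vox <- sum(mask$values) * prod(sp)

  idx <- which(mask$values, arr.ind = TRUE)
  coords <- sweep(sweep(idx - 1, 2, sp, "*"), 2, mask$origin, "+")
  ctr <- colMeans(coords)
  cv <- stats::cov(coords)
  ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
             decreasing = TRUE)
  bv <- boundary_voxels(mask$values)
  bidx <- which(bv, arr.ind = TRUE)
  bcoords <- sweep(sweep(bidx - 1, 2, sp, "*"), 2, mask$origin, "+")
  diam <- max_diameter(bcoords)

  com_shift <- NA_real_
  if (!is.null(vol)) {
    check_same_grid(vol, mask)
    w <- vol$values[mask$values]
    if (sum(abs(w)) > 0) {
      wc <- colSums(coords * w) / sum(w)
      com_shift <- sqrt(sum((wc - ctr)^2))
    } else {
      com_shift <- 0
    }
  }

  s36 <- (36 * pi * V^2)^(1 / 3)
  c(morph.volume_mesh = V,
    morph.volume_voxel = v_vox,
    morph.surface_area = A,
    morph.surf_to_vol_ratio = A / V,
    morph.sphericity = s36 / A,
    morph.compactness1 = V / (sqrt(pi) * A^1.5),
    morph.compactness2 = 36 * pi * V^2 / A^3,
    morph.spherical_disproportion = A / s36,
    morph.asphericity = (A^3 / (36 * pi * V^2))^(1 / 3) - 1,
    morph.max_diameter_3d = diam,
    morph.major_axis_length = 4 * sqrt(ev[1]),
    morph.minor_axis_length = 4 * sqrt(ev[2]),
    morph.least_axis_length = 4 * sqrt(ev[3]),
    morph.elongation = sqrt(ev[2] / max(ev[1], 1e-12)),
    morph.flatness = sqrt(ev[3] / max(ev[1], 1e-12)),
    morph.com_shift = com_shift)
}
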