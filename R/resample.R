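#' Resample a volume/mask pair to an isotropic grid
#'
#' Tri-linear interpolation of the intensity volume onto a grid of cubic
#' voxels of side `target_mm`; the mask is interpolated the same way and
#' re-binarized at 0.5. Output grid centers are aligned with the physical
#' center of the input grid so the physical extent is preserved to within one
#' voxel. When the input is already on the target grid the values pass
#' through unchanged up to interpolation round-off.
#'
#' @param vol An [image_volume()].
#' @param mask An [roi_mask()] on the same grid.
#' @param target_mm Target isotropic voxel side in mm.
#' @return `list(volume, mask)` on the new grid.
#' @export
resample_isotropic <- function(vol, mask, target_mm = 1) {
  check_same_grid(vol, mask)
  check_nonempty_mask(mask)
  assert_scalar_pos(target_mm, "target_mm")
  d_in <- dim(vol$values)
  sp_in <- vol$spacing
  extent <- d_in * sp_in
  d_out <- pmax(2L, as.integer(round(extent / target_mm)))
  sp_out <- rep(target_mm, 3)
  # align grid centers: center of input = origin + (d-1)/2 * spacing
  center <- vol$origin + (d_in - 1) / 2 * sp_in
  origin_out <- center - (d_out - 1) / 2 * sp_out

  # output voxel centers in continuous input index space (1-based)
  idx <- lapply(1:3, function(a) {
    ((origin_out[a] + (seq_len(d_out[a]) - 1) * sp_out[a]) - vol$origin[a]) /
      sp_in[a] + 1
  })
  vals_out <- trilinear_sample(vol$values, idx, d_out)
  mask_num <- trilinear_sample(array(as.numeric(mask$values), d_in), idx, d_out)
  m_out <- mask_num > 0.5
  if (!any(m_out)) {
    abort("mask vanished during resampling", class = "edrisk_degenerate_mask")
  }
  list(volume = image_volume(vals_out, sp_out, origin_out),
       mask = roi_mask(array(m_out, d_out), sp_out, origin_out))
}

# Vectorized tri-linear sampling of array `a` at the tensor grid of continuous
# 1-based indices idx[[1]] x idx[[2]] x idx[[3]]; clamped at the faces.
trilinear_sample <- function(a, idx, d_out) {
  d <- dim(a)
  lo <- lapply(1:3, function(k) pmin(pmax(floor(idx[[k]]), 1), d[k] - 1L))
  fr <- lapply(1:3, function(k) pmin(pmax(idx[[k]] - lo[[k]], 0), 1))
  lo <- lapply(lo, as.integer)
  out <- array(0, d_out)
  X <- array(lo[[1]], d_out)
  Y <- array(rep(lo[[2]], each = d_out[1]), d_out)
  Z <- array(rep(lo[[3]], each = d_out[1] * d_out[2]), d_out)
  FX <- array(fr[[1]], d_out)
  FY <- array(rep(fr[[2]], each = d_out[1]), d_out)
  FZ <- array(rep(fr[[3]], each = d_out[1] * d_out[2]), d_out)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx == 1) FX else 1 - FX) *
         (if (dy == 1) FY else 1 - FY) *
         (if (dz == 1) FZ else 1 - FZ)
    lin <- (X + dx) + d[1] * ((Y + dy - 1L) + d[2] * (Z + dz - 1L))
    out <- out + w * a[lin]
  }
  out
}

#' Discretize in-mask intensities to a fixed number of bins
#'
#' Fixed-bin-number rebinning over the in-mask intensity range: bin
#' `b = floor(n_bins * (x - min) / (max - min)) + 1`, with the maximum mapped
#' into bin `n_bins`. A constant region maps every voxel to bin 1. Bin labels
#' are invariant to any affine shift of the whole in-mask distribution.
#'
#' @param vol An [image_volume()].
#' @param mask An [roi_mask()] on the same grid.
#' @param n_bins Number of grey-level bins (>= 2); 64 is the pipeline default.
#' @return An object of class `edr_discrete`: list with `bins` (integer array,
#'   0 outside the mask, 1..n_bins inside), `n_bins`, `edges`, `spacing`.
#' @export
discretize <- function(vol, mask, n_bins = 64) {
  check_same_grid(vol, mask)
  check_nonempty_mask(mask)
  if (n_bins < 2) abort("n_bins must be >= 2")
  x <- vol$values[mask$values]
  lo <- min(x); hi <- max(x)
  bins <- array(0L, dim(vol$values))
  if (hi - lo <= 0) {
    bins[mask$values] <- 1L
    edges <- c(lo, lo)
  } else {
    b <- floor(n_bins * (vol$values[mask$values] - lo) / (hi - lo)) + 1L
    bins[mask$values] <- pmin(as.integer(b), as.integer(n_bins))
    edges <- seq(lo, hi, length.out = n_bins + 1)
  }
  structure(list(bins = bins, n_bins = as.integer(n_bins), edges = edges,
                 spacing = vol$spacing, mask = mask$values),
            class = "edr_discrete")
}
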