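#' Image volume and ROI mask containers
#'
#' An `edr_volume` is a 3D scalar grid with voxel spacing and origin in mm;
#' an `edr_mask` is a logical grid on the same lattice marking the delineated
#' tumor region. Voxel indices are 1-based in R; the physical position of the
#' center of voxel `(i, j, k)` is `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param values 3D numeric array (volume) or array coercible to logical
#'   (mask).
#' @param spacing Voxel spacing in mm along the three array axes.
#' @param origin Physical position (mm) of the first voxel center.
#' @return An object of class `edr_volume` or `edr_mask`: a list with
#'   `values`, `spacing`, `origin`.
#' @examples
#' v <- image_volume(array(rnorm(8), c(2, 2, 2)), spacing = c(1, 1, 1))
#' m <- roi_mask(array(c(TRUE, FALSE), c(2, 2, 2)), spacing = c(1, 1, 1))
#' @export
image_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) abort("`values` must be a 3D array")
  if (!all(is.finite(values))) abort("volume values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive reals (mm)")
  }
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "edr_volume")
}

#' @rdname image_volume
#' @export
roi_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) abort("`values` must be a 3D array")
  storage.mode(values) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive reals (mm)")
  }
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "edr_mask")
}

#' @export
print.edr_volume <- function(x, ...) {
  cat("<edr_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.edr_mask <- function(x, ...) {
  cat("<edr_mask> ", paste(dim(x$values), collapse = " x "),
      " voxels, ", sum(x$values), " foreground, spacing ",
      paste(signif(x$spacing, 4), collapse = "/"), " mm\n", sep = "")
  invisible(x)
}

check_same_grid <- function(vol, mask) {
  if (!identical(dim(vol$values), dim(mask$values))) {
    abort("volume and mask grids differ in shape", class = "edrisk_alignment_error")
  }
  if (max(abs(vol$spacing - mask$spacing)) > 1e-6) {
    abort("volume and mask voxel spacings differ", class = "edrisk_alignment_error")
  }
  invisible(TRUE)
}

check_nonempty_mask <- function(mask) {
  if (!any(mask$values)) {
    abort("mask has no foreground voxels", class = "edrisk_degenerate_mask")
  }
  invisible(TRUE)
}

#' Write and read a volume/mask pair as NIfTI
#'
#' Thin wrappers over \pkg{RNifti} that carry voxel spacing through `pixdim`.
#' `load_pair()` binarizes the mask at 0.5 and validates grid compatibility.
#'
#' @param vol,mask `edr_volume` / `edr_mask` objects.
#' @param volume_path,mask_path Paths to `.nii` or `.nii.gz` files.
#' @return `load_pair()` returns `list(volume, mask)`.
#' @export
write_pair <- function(vol, mask, volume_path, mask_path) {
  check_same_grid(vol, mask)
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, volume_path)
  msk <- RNifti::asNifti(array(as.numeric(mask$values), dim(mask$values)))
  RNifti::pixdim(msk) <- mask$spacing
  RNifti::writeNifti(msk, mask_path)
  invisible(c(volume_path, mask_path))
}

#' @rdname write_pair
#' @export
load_pair <- function(volume_path, mask_path) {
  if (!file.exists(volume_path)) abort(paste("no such file:", volume_path))
  if (!file.exists(mask_path)) abort(paste("no such file:", mask_path))
  v <- RNifti::readNifti(volume_path)
  m <- RNifti::readNifti(mask_path)
  sv <- RNifti::pixdim(v)
  sm <- RNifti::pixdim(m)
  vol <- image_volume(array(as.numeric(v), dim(v)[1:3]), spacing = sv[1:3])
  mask <- roi_mask(array(as.numeric(m) > 0.5, dim(m)[1:3]), spacing = sm[1:3])
  check_same_grid(vol, mask)
  check_nonempty_mask(mask)
  list(volume = vol, mask = mask)
}
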