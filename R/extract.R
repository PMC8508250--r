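#' Extract the full radiomic feature vector for one case
#'
#' Runs the extraction workflow in its fixed order: isotropic resampling
#' (tri-linear, default 1 mm), then morphology on the resampled mask,
#' first-order statistics on the resampled in-mask intensities, and
#' histogram/texture features on the 64-bin fixed-bin-number discretization.
#' The catalogue is fixed: [feature_catalogue()] lists every feature name and
#' family; each non-degenerate ROI yields exactly that set.
#'
#' @param vol An [image_volume()].
#' @param mask An [roi_mask()] on the same grid.
#' @param spacing_mm Target isotropic voxel size (mm).
#' @param n_bins Number of grey-level bins.
#' @param id Optional case identifier stored in the `case` column.
#' @return A one-row tibble: `case` then one column per catalogue feature.
#' @examples
#' ph <- make_phantom(phantom_spec(radius_mm = 8, noise_sd = 5))
#' extract_all(ph$volume, ph$mask, id = "phantom1")
#' @export
extract_all <- function(vol, mask, spacing_mm = 1, n_bins = 64, id = "case1") {
  rs <- resample_isotropic(vol, mask, target_mm = spacing_mm)
  morph <- morphology_features(rs$mask, rs$volume)
  disc <- discretize(rs$volume, rs$mask, n_bins = n_bins)
  intens <- intensity_features(rs$volume, rs$mask, discrete = disc)
  tex <- texture_features(texture_matrices(disc))
  feats <- c(morph, intens, tex)
  out <- as_tibble(as.list(feats))
  out <- dplyr::bind_cols(tibble(case = id), out)
  attr(out, "extraction") <- list(spacing_mm = spacing_mm, n_bins = n_bins,
                                  n_features = length(feats),
                                  catalogue = "edrisk-1")
  out
}

#' Extract features for a list of cases
#'
#' @param cases Named list, each element `list(volume = , mask = )`.
#' @param spacing_mm,n_bins Passed to [extract_all()].
#' @return Tibble with one row per case.
#' @export
extract_cohort <- function(cases, spacing_mm = 1, n_bins = 64) {
  ids <- names(cases) %||% paste0("case", seq_along(cases))
  rows <- purrr::imap(cases, function(cs, id) {
    extract_all(cs$volume, cs$mask, spacing_mm = spacing_mm, n_bins = n_bins,
                id = id)
  })
  purrr::list_rbind(rows)
}

#' The fixed feature catalogue
#'
#' @return Tibble with columns `feature` and `family` enumerating every
#'   feature [extract_all()] produces, in output order.
#' @export
feature_catalogue <- function() {
  ph <- make_phantom(phantom_spec(radius_mm = 6, voxel_spacing_mm = 2,
                                  noise_sd = 2, seed = 7L))
  row <- extract_all(ph$volume, ph$mask, spacing_mm = 2, id = "cat")
  feats <- setdiff(names(row), "case")
  tibble(feature = feats,
         family = sub("\\..*$", "", feats))
}
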