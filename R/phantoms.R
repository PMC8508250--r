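#' Specify a synthetic tumor phantom
#'
#' A phantom is an analytic solid (sphere, ellipsoid, or a lobulated sphere
#' whose radius is perturbed by low-order spherical-harmonic-like terms),
#' voxelized on a regular grid, with a fixed intensity model: 80 inside the
#' tumor, 30 in an optional hypodense necrotic core, 0 background, plus
#' optional additive Gaussian noise. These intensities are arbitrary units on
#' a CT-like scale, held fixed so histogram features are predictable.
#'
#' @param shape_kind `"sphere"`, `"ellipsoid"` or `"lobulated"`.
#' @param radius_mm Reference radius in mm; must exceed twice the largest
#'   voxel spacing.
#' @param axis_ratios Three positive multipliers of `radius_mm` giving the
#'   semi-axes (ellipsoid); ignored for spheres.
#' @param lobulation_amplitude Fractional radial perturbation (>= 0) for
#'   lobulated shapes.
#' @param necrotic_core Logical; carve a concentric hypodense core?
#' @param core_fraction Core volume fraction in `[0, 1)`.
#' @param voxel_spacing_mm Voxel spacing (mm), length 3 (or 1, recycled).
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param seed Integer seed; identical specs and seeds give bit-identical
#'   phantoms.
#' @return A `phantom_spec` list.
#' @examples
#' spec <- phantom_spec(radius_mm = 10)
#' ph <- make_phantom(spec)
#' sum(ph$mask$values) # close to 4/3 * pi * 10^3
#' @export
phantom_spec <- function(shape_kind = c("sphere", "ellipsoid", "lobulated"),
                         radius_mm = 15,
                         axis_ratios = c(1, 1, 1),
                         lobulation_amplitude = 0,
                         necrotic_core = FALSE,
                         core_fraction = 0.15,
                         voxel_spacing_mm = c(1, 1, 1),
                         noise_sd = 0,
                         seed = 1L) {
  shape_kind <- match.arg(shape_kind)
  assert_scalar_pos(radius_mm, "radius_mm")
  if (length(voxel_spacing_mm) == 1L) voxel_spacing_mm <- rep(voxel_spacing_mm, 3)
  if (any(voxel_spacing_mm <= 0)) abort("voxel spacing must be positive")
  if (radius_mm <= 2 * max(voxel_spacing_mm)) {
    abort("radius_mm must exceed 2 * max(voxel_spacing_mm)",
          class = "edrisk_degenerate_shape")
  }
  if (core_fraction < 0 || core_fraction >= 1) {
    abort("core_fraction must lie in [0, 1)")
  }
  if (lobulation_amplitude < 0) abort("lobulation_amplitude must be >= 0")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  structure(list(shape_kind = shape_kind, radius_mm = radius_mm,
                 axis_ratios = as.numeric(axis_ratios),
                 lobulation_amplitude = lobulation_amplitude,
                 necrotic_core = isTRUE(necrotic_core),
                 core_fraction = core_fraction,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Radius multiplier of the lobulated shape as a function of direction.
# Low-order trigonometric surface modes, coefficients drawn once per seed and
# scaled so the maximum perturbation equals `amplitude`.
lobulation_field <- function(theta, phi, amplitude, seed) {
  set.seed(child_seed(seed, "lobulation"))
  a <- rnorm(3)
  raw <- a[1] * sin(2 * theta) * cos(2 * phi) +
    a[2] * cos(3 * theta) +
    a[3] * sin(3 * theta) * sin(3 * phi)
  scale <- max(abs(a[1]) + abs(a[2]) + abs(a[3]), 1e-9)
  1 + amplitude * raw / scale
}

#' Voxelize a phantom specification
#'
#' @param spec A [phantom_spec()].
#' @return `list(volume, mask)` of [image_volume()] / [roi_mask()] on a grid
#'   that pads the shape by three voxels per side.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$voxel_spacing_mm
  semi <- if (spec$shape_kind == "ellipsoid") {
    spec$radius_mm * spec$axis_ratios
  } else {
    rep(spec$radius_mm * (1 + spec$lobulation_amplitude), 3)
  }
  if (any(2 * semi < 2 * sp)) {
    abort("shape smaller than 2 voxels along an axis",
          class = "edrisk_degenerate_shape")
  }
  half_n <- ceiling(semi / sp) + 3L
  dims <- 2L * half_n + 1L
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1 - half_n[a]) * sp[a])
  x <- array(ax[[1]], dims)
  y <- array(rep(ax[[2]], each = dims[1]), dims)
  z <- array(rep(ax[[3]], each = dims[1] * dims[2]), dims)

  inside <- switch(spec$shape_kind,
    sphere = (x^2 + y^2 + z^2) <= spec$radius_mm^2,
    ellipsoid = {
      s <- spec$radius_mm * spec$axis_ratios
      (x / s[1])^2 + (y / s[2])^2 + (z / s[3])^2 <= 1
    },
    lobulated = {
      r <- sqrt(x^2 + y^2 + z^2)
      theta <- acos(ifelse(r > 0, z / pmax(r, 1e-12), 1))
      phi <- atan2(y, x)
      rloc <- spec$radius_mm *
        lobulation_field(theta, phi, spec$lobulation_amplitude, spec$seed)
      r <= rloc
    })
  dim(inside) <- dims
  if (!any(inside)) abort("empty phantom", class = "edrisk_degenerate_shape")

  vals <- array(0, dims)
  vals[inside] <- 80
  if (spec$necrotic_core && spec$core_fraction > 0) {
    shrink <- spec$core_fraction^(1 / 3)
    core <- switch(spec$shape_kind,
      sphere = (x^2 + y^2 + z^2) <= (shrink * spec$radius_mm)^2,
      ellipsoid = {
        s <- shrink * spec$radius_mm * spec$axis_ratios
        (x / s[1])^2 + (y / s[2])^2 + (z / s[3])^2 <= 1
      },
      lobulated = {
        r <- sqrt(x^2 + y^2 + z^2)
        theta <- acos(ifelse(r > 0, z / pmax(r, 1e-12), 1))
        phi <- atan2(y, x)
        rloc <- shrink * spec$radius_mm *
          lobulation_field(theta, phi, spec$lobulation_amplitude, spec$seed)
        r <= rloc
      })
    vals[core & inside] <- 30
  }
  if (spec$noise_sd > 0) {
    set.seed(child_seed(spec$seed, "noise"))
    vals <- vals + array(rnorm(length(vals), sd = spec$noise_sd), dims)
  }
  origin <- -(half_n) * sp
  list(volume = image_volume(vals, sp, origin),
       mask = roi_mask(inside, sp, origin))
}

# Separable Gaussian smoothing of a 3D array (sigma in voxels per axis).
gauss_smooth3 <- function(a, sigma_vox) {
  d <- dim(a)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-half:half) / s)^2)
    k <- k / sum(k)
    a <- apply_kernel_axis(a, k, axis)
  }
  a
}

apply_kernel_axis <- function(a, k, axis) {
  d <- dim(a)
  half <- (length(k) - 1L) / 2L
  out <- array(0, d)
  for (off in -half:half) {
    w <- k[off + half + 1L]
    idx_src <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
    out <- out + w * slice_index(a, idx_src, axis)
  }
  out
}

slice_index <- function(a, idx, axis) {
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

#' Emulate multi-reader delineation variability
#'
#' Produces `n_readers` contour variants of a mask with characteristic
#' boundary displacement `perturb_mm`: reader 1 keeps the original contour,
#' subsequent readers cycle through systematic dilation, systematic erosion,
#' and random boundary jitter, all realized by thresholding a Gaussian-smoothed
#' copy of the mask (plus, for jitter, a smooth random field).
#'
#' @param mask An [roi_mask()].
#' @param n_readers Number of variants (>= 2).
#' @param perturb_mm Characteristic contour displacement in mm; 0 returns
#'   exact copies.
#' @param seed Integer seed.
#' @return List of `n_readers` masks on the original grid.
#' @export
make_reader_variants <- function(mask, n_readers = 3, perturb_mm = 1, seed = 1L) {
  stopifnot(inherits(mask, "edr_mask"))
  if (n_readers < 2) abort("n_readers must be >= 2")
  check_nonempty_mask(mask)
  if (perturb_mm == 0) {
    return(replicate(n_readers, mask, simplify = FALSE))
  }
  sp <- mask$spacing
  m <- array(as.numeric(mask$values), dim(mask$values))
  sigma_vox <- pmax(perturb_mm / sp, 0.5)
  sm <- gauss_smooth3(m, sigma_vox)
  # A Gaussian-smoothed indicator crosses the boundary like pnorm(s / sigma)
  # in the signed distance s, so thresholding at 0.5 +/- delta with
  # delta = pnorm(1) - 0.5 displaces the contour by about one sigma, i.e. by
  # perturb_mm along the surface normal.
  delta <- pnorm(1) - 0.5
  modes <- rep(c("dilate", "erode", "jitter"), length.out = n_readers - 1)
  out <- vector("list", n_readers)
  out[[1]] <- mask
  for (r in seq_len(n_readers - 1)) {
    thr_field <- switch(modes[r],
      dilate = 0.5 - delta,
      erode = 0.5 + delta,
      jitter = {
        set.seed(child_seed(seed, "reader", r))
        noise <- gauss_smooth3(array(rnorm(length(m)), dim(m)),
                               pmax(2 * sigma_vox, 1))
        noise <- noise / max(sd(noise), 1e-12)
        0.5 - delta * noise
      })
    v <- sm > thr_field
    if (!any(v)) {
      abort("perturbation erased the mask", class = "edrisk_degenerate_mask")
    }
    out[[r + 1]] <- roi_mask(v, sp, mask$origin)
  }
  out
}

#' Dice overlap of two masks on the same grid
#'
#' @param a,b [roi_mask()] objects on identical grids.
#' @return Dice similarity coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a$values), dim(b$values)))
  2 * sum(a$values & b$values) / (sum(a$values) + sum(b$values))
}
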