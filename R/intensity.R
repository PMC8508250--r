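#' First-order intensity features of the tumor region
#'
#' Two feature families over the delineated voxels: `stat.*` are statistics of
#' the raw in-mask intensities; `ih.*` are computed on the fixed-bin-number
#' discretized grey levels (64 bins by default in the pipeline), including
#' histogram entropy/uniformity and the discrete histogram-gradient features.
#' Degenerate conventions: a constant region has variance 0, entropy 0 and
#' uniformity 1.
#'
#' @param vol An [image_volume()].
#' @param mask An [roi_mask()] on the same grid.
#' @param discrete Optionally a precomputed [discretize()] result (otherwise
#'   computed here with `n_bins`).
#' @param n_bins Bins for the histogram family when `discrete` is missing.
#' @return Named numeric vector of `stat.*` and `ih.*` features.
#' @export
intensity_features <- function(vol, mask, discrete = NULL, n_bins = 64) {
  check_same_grid(vol, mask)
  check_nonempty_mask(mask)
  x <- vol$values[mask$values]
  n <- length(x)
  mu <- mean(x)
  v <- mean((x - mu)^2)             # biased, IBSI convention
  sdv <- sqrt(v)
  skew <- if (sdv > 0) mean((x - mu)^3) / sdv^3 else 0
  kurt <- if (sdv > 0) mean((x - mu)^4) / sdv^4 - 3 else 0
  q <- unname(quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7))
  cm <- if (abs(mu) > 0) sdv / mu else 0
  qcod_den <- q[4] + q[2]
  stat <- c(stat.mean = mu, stat.variance = v, stat.skewness = skew,
            stat.kurtosis = kurt, stat.median = q[3], stat.min = min(x),
            stat.p10 = q[1], stat.p90 = q[5], stat.max = max(x),
            stat.iqr = q[4] - q[2], stat.range = max(x) - min(x),
            stat.mad = mean(abs(x - mu)),
            stat.medad = mean(abs(x - q[3])),
            stat.cov = cm,
            stat.qcod = if (abs(qcod_den) > 0) (q[4] - q[2]) / qcod_den else 0,
            stat.energy = sum(x^2),
            stat.rms = sqrt(mean(x^2)))

  if (is.null(discrete)) discrete <- discretize(vol, mask, n_bins = n_bins)
  g <- discrete$bins[discrete$bins > 0L]
  ng <- discrete$n_bins
  p <- tabulate(g, nbins = ng) / length(g)
  gl <- seq_len(ng)
  mu_h <- sum(gl * p)
  v_h <- sum((gl - mu_h)^2 * p)
  sd_h <- sqrt(v_h)
  skew_h <- if (sd_h > 0) sum((gl - mu_h)^3 * p) / sd_h^3 else 0
  kurt_h <- if (sd_h > 0) sum((gl - mu_h)^4 * p) / sd_h^4 - 3 else 0
  nz <- p > 0
  entropy <- -sum(p[nz] * log2(p[nz]))
  qh <- unname(quantile(g, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 1))
  mode_bin <- which.max(p)   # lowest bin on ties
  grad <- diff(p)            # histogram gradient over bins
  if (length(grad) == 0L) grad <- 0
  ih <- c(ih.mean = mu_h, ih.variance = v_h, ih.skewness = skew_h,
          ih.kurtosis = kurt_h, ih.median = qh[3],
          ih.min = min(g), ih.p10 = qh[1], ih.p90 = qh[5], ih.max = max(g),
          ih.mode = as.numeric(mode_bin), ih.iqr = qh[4] - qh[2],
          ih.range = max(g) - min(g),
          ih.mad = sum(p * abs(gl - mu_h)),
          ih.entropy = entropy,
          ih.uniformity = sum(p^2),
          ih.max_gradient = max(grad),
          ih.max_gradient_bin = as.numeric(which.max(grad) %g0% 1),
          ih.min_gradient = min(grad),
          ih.min_gradient_bin = as.numeric(which.min(grad) %g0% 1))
  c(stat, ih)
}
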