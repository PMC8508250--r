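# IBSI-style descriptors per texture family. Degenerate conventions (single
# occupied cell, zero variance, empty difference cells) take their defined
# limits: entropy 0, correlation 1, coarseness capped at 1e6, busyness 0.

glcm_features_one <- function(M) {
  s <- sum(M)
  if (s <= 0) {
    return(setNames(numeric(23), glcm_feature_names()))
  }
  P <- M / s
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  pij <- as.vector(P)
  iv <- as.vector(i); jv <- as.vector(j)
  mu_i <- sum(iv * pij)                  # symmetric: mu_i == mu_j
  var_i <- sum((iv - mu_i)^2 * pij)
  nz <- pij > 0
  joint_ent <- -sum(pij[nz] * log2(pij[nz]))
  dk <- abs(iv - jv)
  p_diff <- tapply(pij, factor(dk, levels = 0:(ng - 1)), sum)
  p_diff[is.na(p_diff)] <- 0
  kd <- 0:(ng - 1)
  diff_avg <- sum(kd * p_diff)
  diff_var <- sum((kd - diff_avg)^2 * p_diff)
  dnz <- p_diff > 0
  diff_ent <- -sum(p_diff[dnz] * log2(p_diff[dnz]))
  sk <- iv + jv
  p_sum <- tapply(pij, factor(sk, levels = 2:(2 * ng)), sum)
  p_sum[is.na(p_sum)] <- 0
  ks <- 2:(2 * ng)
  sum_avg <- sum(ks * p_sum)
  sum_var <- sum((ks - sum_avg)^2 * p_sum)
  snz <- p_sum > 0
  sum_ent <- -sum(p_sum[snz] * log2(p_sum[snz]))
  offd <- iv != jv
  inv_var <- 2 * sum(pij[offd] / dk[offd]^2)
  corr <- if (var_i > 0) {
    sum((iv - mu_i) * (jv - mu_i) * pij) / var_i
  } else 1
  cl <- iv + jv - 2 * mu_i
  setNames(c(
    max(pij),
    mu_i,
    var_i,
    joint_ent,
    diff_avg, diff_var, diff_ent,
    sum_avg, sum_var, sum_ent,
    sum(pij^2),                               # angular second moment
    sum(dk^2 * pij),                          # contrast
    sum(dk * pij),                            # dissimilarity
    sum(pij / (1 + dk)),                      # inverse difference
    sum(pij / (1 + dk / ng)),                 # inverse difference normalized
    sum(pij / (1 + dk^2)),                    # inverse difference moment
    sum(pij / (1 + dk^2 / ng^2)),             # idm normalized
    inv_var,
    corr,
    sum(iv * jv * pij),                       # autocorrelation
    sum(cl^2 * pij),                          # cluster tendency
    sum(cl^3 * pij),                          # cluster shade
    sum(cl^4 * pij)                           # cluster prominence
  ), glcm_feature_names())
}

glcm_feature_names <- function() {
  c("joint_max", "joint_avg", "joint_var", "joint_entropy",
    "diff_avg", "diff_var", "diff_entropy",
    "sum_avg", "sum_var", "sum_entropy",
    "energy", "contrast", "dissimilarity",
    "inv_diff", "inv_diff_norm", "inv_diff_moment", "inv_diff_moment_norm",
    "inv_variance", "correlation", "autocorrelation",
    "cluster_tendency", "cluster_shade", "cluster_prominence")
}

# shared emphasis-style features for run-length / size-zone / distance-zone
# matrices; `axis_name` labels the second margin (run length, zone size, zone
# distance); n_vox scales the "percentage" feature
rl_style_features <- function(R, n_vox, short, long, low, high, sl, sh, ll, lh,
                              gln, glnn, axn, axnn, pct, glv, axv, ent) {
  ns <- sum(R)
  out <- setNames(numeric(16), c(short, long, low, high, sl, sh, ll, lh,
                                 gln, glnn, axn, axnn, pct, glv, axv, ent))
  if (ns <= 0) return(out)
  ng <- nrow(R); nl <- ncol(R)
  i <- row(R); j <- col(R)
  r <- as.vector(R); iv <- as.vector(i); jv <- as.vector(j)
  ri <- rowSums(R); rj <- colSums(R)
  p <- r / ns
  nz <- p > 0
  mu_i <- sum(iv * p); mu_j <- sum(jv * p)
  out[short] <- sum(rj / (seq_len(nl))^2) / ns
  out[long] <- sum(rj * (seq_len(nl))^2) / ns
  out[low] <- sum(ri / (seq_len(ng))^2) / ns
  out[high] <- sum(ri * (seq_len(ng))^2) / ns
  out[sl] <- sum(r / (iv^2 * jv^2)) / ns
  out[sh] <- sum(r * iv^2 / jv^2) / ns
  out[ll] <- sum(r * jv^2 / iv^2) / ns
  out[lh] <- sum(r * iv^2 * jv^2) / ns
  out[gln] <- sum(ri^2) / ns
  out[glnn] <- sum(ri^2) / ns^2
  out[axn] <- sum(rj^2) / ns
  out[axnn] <- sum(rj^2) / ns^2
  out[pct] <- ns / n_vox
  out[glv] <- sum((iv - mu_i)^2 * p)
  out[axv] <- sum((jv - mu_j)^2 * p)
  out[ent] <- -sum(p[nz] * log2(p[nz]))
  out
}

glrlm_feature_names <- function() {
  c("sre", "lre", "lglre", "hglre", "srlgle", "srhgle", "lrlgle", "lrhgle",
    "gln", "glnn", "rln", "rlnn", "run_pct", "glv", "rlv", "run_entropy")
}

glrlm_features_one <- function(R, n_vox) {
  nm <- glrlm_feature_names()
  rl_style_features(R, n_vox, nm[1], nm[2], nm[3], nm[4], nm[5], nm[6], nm[7],
                    nm[8], nm[9], nm[10], nm[11], nm[12], nm[13], nm[14],
                    nm[15], nm[16])
}

ngtdm_features <- function(nt) {
  ni <- nt$n_i; si <- nt$s_i; nv <- nt$n_valid
  out <- setNames(numeric(5),
                  c("coarseness", "contrast", "busyness", "complexity",
                    "strength"))
  if (nv == 0) return(out)
  pi_ <- ni / nv
  act <- which(ni > 0)
  ngp <- length(act)
  denom_coarse <- sum(pi_ * si)
  out["coarseness"] <- if (denom_coarse > 0) min(1 / denom_coarse, 1e6) else 1e6
  if (ngp > 1) {
    pr <- expand.grid(i = act, j = act)
    out["contrast"] <- sum(pi_[pr$i] * pi_[pr$j] * (pr$i - pr$j)^2) /
      (ngp * (ngp - 1)) * sum(si) / nv
    den_busy <- sum(abs(pr$i * pi_[pr$i] - pr$j * pi_[pr$j]))
    out["busyness"] <- if (den_busy > 0) denom_coarse / den_busy else 0
    out["complexity"] <- sum(abs(pr$i - pr$j) *
      (pi_[pr$i] * si[pr$i] + pi_[pr$j] * si[pr$j]) /
      (pi_[pr$i] + pi_[pr$j])) / nv
    if (denom_coarse > 0) {
      out["strength"] <- sum((pi_[pr$i] + pi_[pr$j]) * (pr$i - pr$j)^2) /
        denom_coarse
    }
  }
  out
}

#' Texture features from a matrix set
#'
#' For the directional families (co-occurrence, run length) two aggregations
#' are produced, as in the extraction workflow this package implements:
#' `*_avg.*` computes each feature per direction and averages over the 13
#' directions, `*_comb.*` merges (sums) the directional matrices first and
#' computes features once.
#'
#' @param tm An `edr_texture_matrices` object from [texture_matrices()].
#' @return Named numeric vector of `glcm_avg.*`, `glcm_comb.*`,
#'   `glrlm_avg.*`, `glrlm_comb.*`, `glszm.*`, `ngtdm.*`, `gldzm.*` features.
#' @export
texture_features <- function(tm) {
  stopifnot(inherits(tm, "edr_texture_matrices"))
  nvox <- tm$n_voxels
  glcm_per_dir <- vapply(tm$glcm, glcm_features_one, numeric(23))
  glcm_avg <- rowMeans(glcm_per_dir)
  glcm_comb <- glcm_features_one(Reduce(`+`, tm$glcm))
  maxlen <- max(vapply(tm$glrlm, ncol, 1L))
  padR <- function(R) {
    if (ncol(R) < maxlen) {
      R <- cbind(R, matrix(0, nrow(R), maxlen - ncol(R)))
    }
    R
  }
  glrlm_per_dir <- vapply(tm$glrlm, function(R) glrlm_features_one(R, nvox),
                          numeric(16))
  glrlm_avg <- rowMeans(glrlm_per_dir)
  glrlm_comb <- glrlm_features_one(Reduce(`+`, lapply(tm$glrlm, padR)), nvox)

  nm_sz <- c("sae", "lae", "lglze", "hglze", "salgle", "sahgle", "lalgle",
             "lahgle", "gln", "glnn", "zsn", "zsnn", "zone_pct", "glv", "zsv",
             "zone_entropy")
  glszm <- rl_style_features(tm$glszm, nvox, nm_sz[1], nm_sz[2], nm_sz[3],
                             nm_sz[4], nm_sz[5], nm_sz[6], nm_sz[7], nm_sz[8],
                             nm_sz[9], nm_sz[10], nm_sz[11], nm_sz[12],
                             nm_sz[13], nm_sz[14], nm_sz[15], nm_sz[16])
  nm_dz <- c("sde", "lde", "lgle", "hgle", "sdlgle", "sdhgle", "ldlgle",
             "ldhgle", "gln", "glnn", "zdn", "zdnn", "zone_pct", "glv", "zdv",
             "zone_dist_entropy")
  gldzm <- rl_style_features(tm$gldzm, nvox, nm_dz[1], nm_dz[2], nm_dz[3],
                             nm_dz[4], nm_dz[5], nm_dz[6], nm_dz[7], nm_dz[8],
                             nm_dz[9], nm_dz[10], nm_dz[11], nm_dz[12],
                             nm_dz[13], nm_dz[14], nm_dz[15], nm_dz[16])
  ngtdm <- ngtdm_features(tm$ngtdm)
  c(setNames(glcm_avg, paste0("glcm_avg.", names(glcm_avg))),
    setNames(glcm_comb, paste0("glcm_comb.", names(glcm_comb))),
    setNames(glrlm_avg, paste0("glrlm_avg.", names(glrlm_avg))),
    setNames(glrlm_comb, paste0("glrlm_comb.", names(glrlm_comb))),
    setNames(glszm, paste0("glszm.", names(glszm))),
    setNames(ngtdm, paste0("ngtdm.", names(ngtdm))),
    setNames(gldzm, paste0("gldzm.", names(gldzm))))
}
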