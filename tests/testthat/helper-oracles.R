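# Independent brute-force oracles used to validate the package's vectorized
# implementations on small instances. These deliberately use naive loops and
# base-R model fits, not the package's own code paths.

oracle_glcm <- function(bins, d, ng) {
  D <- dim(bins)
  M <- matrix(0, ng, ng)
  for (x in seq_len(D[1])) for (y in seq_len(D[2])) for (z in seq_len(D[3])) {
    g1 <- bins[x, y, z]
    if (g1 == 0) next
    p <- c(x, y, z) + d
    if (any(p < 1) || any(p > D)) next
    g2 <- bins[p[1], p[2], p[3]]
    if (g2 == 0) next
    M[g1, g2] <- M[g1, g2] + 1
  }
  M + t(M)
}

oracle_glrlm <- function(bins, d, ng) {
  D <- dim(bins)
  R <- matrix(0, ng, sum(D))
  inside <- function(v) all(v >= 1) && all(v <= D)
  for (x in seq_len(D[1])) for (y in seq_len(D[2])) for (z in seq_len(D[3])) {
    g <- bins[x, y, z]
    if (g == 0) next
    prev <- c(x, y, z) - d
    if (inside(prev) && bins[prev[1], prev[2], prev[3]] == g) next
    len <- 1
    cur <- c(x, y, z) + d
    while (inside(cur) && bins[cur[1], cur[2], cur[3]] == g) {
      len <- len + 1
      cur <- cur + d
    }
    R[g, len] <- R[g, len] + 1
  }
  last <- max(which(colSums(R) > 0))
  R[, seq_len(last), drop = FALSE]
}

# ICC(2,1) through an independent route: two-way ANOVA mean squares from lm()
oracle_icc21 <- function(m) {
  df <- data.frame(y = as.vector(m),
                   case = factor(as.vector(row(m))),
                   rater = factor(as.vector(col(m))))
  a <- anova(lm(y ~ case + rater, data = df))
  msr <- a["case", "Mean Sq"]
  msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# exhaustive Youden scan: every possible dichotomy of the score vector
oracle_youden <- function(p, y) {
  thr <- c(-Inf, sort(unique(p)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  best <- NULL
  for (t in thr) {
    pred <- p > t
    sens <- sum(pred & y == 1) / n1
    spec <- sum(!pred & y == 0) / n0
    j <- sens + spec - 1
    if (is.null(best) || j > best$j || (j == best$j && spec > best$spec)) {
      best <- list(j = j, sens = sens, spec = spec, labels = pred)
    }
  }
  best
}

# two-group log-rank chi-square from the observed-vs-expected decomposition
oracle_logrank <- function(time, event, group) {
  g1 <- unique(group)[1]
  ev_times <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ev_times) {
    at1 <- sum(time >= t & group == g1)
    at0 <- sum(time >= t & group != g1)
    d1 <- sum(time == t & event == 1 & group == g1)
    d <- sum(time == t & event == 1)
    nall <- at1 + at0
    O1 <- O1 + d1
    E1 <- E1 + d * at1 / nall
    if (nall > 1) {
      V <- V + d * (at1 / nall) * (at0 / nall) * (nall - d) / (nall - 1)
    }
  }
  (O1 - E1)^2 / V
}

# hand product-limit estimator (no package code): S(t) at each event time
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ts, survival = out)
}

# small random discretized ROI for texture oracles
random_roi <- function(dims, ng, mask_prob = 0.8, seed = 1) {
  set.seed(seed)
  m <- array(runif(prod(dims)) < mask_prob, dims)
  if (!any(m)) m[1] <- TRUE
  b <- array(0L, dims)
  b[m] <- sample.int(ng, sum(m), replace = TRUE)
  structure(list(bins = b, n_bins = as.integer(ng),
                 edges = seq(0, 1, length.out = ng + 1),
                 spacing = c(1, 1, 1), mask = m),
            class = "edr_discrete")
}

dirs13 <- edrisk:::directions13
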