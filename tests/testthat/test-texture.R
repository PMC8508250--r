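test_that("co-occurrence matrices equal exhaustive pair enumeration", {
  for (seed in 1:4) {
    roi <- random_roi(c(4, 5, 3), ng = 4, seed = seed)
    for (r in seq_len(nrow(dirs13))) {
      M <- edrisk:::glcm_one(roi$bins, dirs13[r, ], 4)
      expect_equal(M, oracle_glcm(roi$bins, dirs13[r, ], 4),
                   ignore_attr = TRUE)
    }
  }
  # the documented 2x2x1 toy case
  toy <- array(0L, c(2, 2, 1))
  toy[, , 1] <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  M <- edrisk:::glcm_one(toy, c(1, 0, 0), 2)
  expect_equal(M, oracle_glcm(toy, c(1, 0, 0), 2), ignore_attr = TRUE)
  expect_equal(sum(M), 4)   # two pairs, symmetric
})

test_that("run-length matrices equal brute-force line walking", {
  for (seed in 5:8) {
    roi <- random_roi(c(5, 4, 4), ng = 3, seed = seed)
    for (r in seq_len(nrow(dirs13))) {
      R <- edrisk:::glrlm_one(as.integer(roi$bins),
                              arrayInd(seq_along(roi$bins), dim(roi$bins)),
                              dirs13[r, ], 3, dim(roi$bins))
      O <- oracle_glrlm(roi$bins, dirs13[r, ], 3)
      expect_equal(R[, seq_len(ncol(O)), drop = FALSE], O, ignore_attr = TRUE)
      if (ncol(R) > ncol(O)) {
        expect_true(all(R[, (ncol(O) + 1):ncol(R)] == 0))
      }
    }
  }
})

test_that("a constant ROI degenerates to one zone and full-length runs", {
  b <- array(1L, c(4, 4, 4))
  d <- structure(list(bins = b, n_bins = 2L, edges = c(0, 1),
                      spacing = c(1, 1, 1), mask = array(TRUE, c(4, 4, 4))),
                 class = "edr_discrete")
  tm <- texture_matrices(d)
  expect_equal(dim(tm$glszm), c(2, 64))
  expect_equal(tm$glszm[1, 64], 1)       # one zone of 64 voxels
  expect_equal(sum(tm$glszm), 1)
  # axis-aligned runs span the whole row
  R <- tm$glrlm[[1]]
  expect_equal(ncol(R), 4)
  expect_equal(R[1, 4], 16)
  f <- texture_features(tm)
  expect_equal(unname(f["glcm_comb.joint_entropy"]), 0)
  expect_equal(unname(f["glcm_comb.correlation"]), 1)
  expect_equal(unname(f["ngtdm.coarseness"]), 1e6)
})

test_that("probability-normalized co-occurrence matrices sum to one", {
  roi <- random_roi(c(6, 6, 4), ng = 5, seed = 12)
  tm <- texture_matrices(roi)
  for (M in tm$glcm) {
    if (sum(M) > 0) expect_equal(sum(M / sum(M)), 1)
  }
  merged <- Reduce(`+`, tm$glcm)
  expect_equal(sum(merged / sum(merged)), 1)
})

test_that("co-occurrence contrast matches a hand computation on a 3x3 slice", {
  sl <- matrix(c(1L, 2L, 3L,
                 2L, 2L, 1L,
                 3L, 1L, 1L), 3, 3, byrow = TRUE)
  b <- array(0L, c(3, 3, 1)); b[, , 1] <- sl
  M <- edrisk:::glcm_one(b, c(1, 0, 0), 3)
  P <- M / sum(M)
  hand_contrast <- sum((row(P) - col(P))^2 * P)
  f <- edrisk:::glcm_features_one(M)
  expect_equal(unname(f["contrast"]), hand_contrast)
  # and against the exhaustive oracle matrix
  expect_equal(M, oracle_glcm(b, c(1, 0, 0), 3), ignore_attr = TRUE)
})

test_that("averaged and merged texture features survive grid rotations", {
  ph <- make_phantom(phantom_spec(radius_mm = 8, necrotic_core = TRUE,
                                  core_fraction = 0.2, seed = 6L))
  d1 <- discretize(ph$volume, ph$mask, 16)
  rot <- function(a) aperm(a, c(2, 3, 1))
  d2 <- structure(list(bins = rot(d1$bins), n_bins = 16L, edges = d1$edges,
                       spacing = c(1, 1, 1), mask = rot(d1$mask)),
                  class = "edr_discrete")
  f1 <- texture_features(texture_matrices(d1))
  f2 <- texture_features(texture_matrices(d2))
  rotinv <- grep("^(glcm_avg|glcm_comb|glrlm_avg|glrlm_comb|glszm|ngtdm|gldzm)\\.",
                 names(f1), value = TRUE)
  expect_equal(f1[rotinv], f2[rotinv], tolerance = 1e-10)
})

test_that("extraction is deterministic and complete over the catalogue", {
  ph <- make_phantom(phantom_spec(radius_mm = 7, noise_sd = 4, seed = 8L))
  r1 <- extract_all(ph$volume, ph$mask, id = "a")
  r2 <- extract_all(ph$volume, ph$mask, id = "a")
  expect_equal(r1, r2, ignore_attr = TRUE)
  cat_n <- nrow(feature_catalogue())
  expect_equal(ncol(r1) - 1L, cat_n)
  expect_true(all(is.finite(as.numeric(r1[1, -1]))))
})
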