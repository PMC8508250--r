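test_that("a null linear predictor gives a 50% event rate", {
  spec <- cohort_sim_spec(n_patients = 2000, true_coefficients = c(necrosis = 0),
                          intercept = 0, seed = 31)
  co <- simulate_cohort(spec)
  expect_equal(mean(co$edr), 0.5, tolerance = 0.03)
})

test_that("event times respect the 12-month recurrence horizon", {
  spec <- cohort_sim_spec(n_patients = 500, seed = 32,
                          true_coefficients = c(ca199_u_ml = 0.000964,
                                                necrosis = 0.86465))
  co <- simulate_cohort(spec)
  expect_true(all(co$time_months[co$edr == 1] < 12))
  expect_true(all(co$event[co$edr == 1] == 1))
  expect_true(all(co$time_months[co$edr == 0] >= 12))
  expect_true(all(co$time_months <= spec$followup_max_months))
  expect_true(all(co$time_months > 0))
})

test_that("the calibrated marginal rate matches its target", {
  spec <- cohort_sim_spec(n_patients = 5000, seed = 33,
                          true_coefficients = c(ca199_u_ml = 0.000964,
                                                necrosis = 0.86465))
  co <- simulate_cohort(spec)
  # closed-form expectation over the covariate distribution = target rate;
  # binomial 3-sigma at n = 5000 is ~0.019 absolute
  expect_lt(abs(mean(co$edr) - 0.265), 0.02)
  expect_lt(abs(mean(co$p_edr) - 0.265), 0.01)
})

test_that("cohort simulation is deterministic and validates its inputs", {
  spec <- cohort_sim_spec(n_patients = 100, seed = 34,
                          true_coefficients = c(necrosis = 1))
  expect_identical(simulate_cohort(spec), simulate_cohort(spec))
  bad <- cohort_sim_spec(n_patients = 10,
                         true_coefficients = c(ghost_feature = 1), seed = 1)
  expect_error(simulate_cohort(bad), class = "edrisk_config_error")
})

test_that("fitting recovers the generative coefficients at n = 1000", {
  feats <- tibble::tibble(morph.surf_to_vol_ratio = runif(1000, 0.2, 0.5))
  spec <- cohort_sim_spec(n_patients = 1000, seed = 35)
  co <- simulate_cohort(spec, feature_values = feats)
  m <- fit_backward_logistic(co, "edr",
                             c("ca199_u_ml", "necrosis",
                               "morph.surf_to_vol_ratio"),
                             p_retain = 1)   # keep all three
  truth <- c(ca199_u_ml = 0.000964, necrosis = 0.86465,
             morph.surf_to_vol_ratio = -2.8972)
  for (v in names(truth)) {
    row <- m$terms[m$terms$term == v, ]
    expect_lt(row$coefficient - 2.5 * row$se, truth[[v]])
    expect_gt(row$coefficient + 2.5 * row$se, truth[[v]])
  }
})

test_that("CA19.9 follows the documented log-normal scale", {
  spec <- cohort_sim_spec(n_patients = 4000, seed = 36,
                          true_coefficients = c(necrosis = 0.86465))
  co <- simulate_cohort(spec)
  expect_equal(median(co$ca199_u_ml), exp(3.7), tolerance = 0.1)
  expect_equal(mean(co$necrosis), 0.18, tolerance = 0.25)
})
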