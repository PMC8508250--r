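test_that("KM estimates match closed forms and a hand-computed table", {
  # no censoring: events at 3, 6, 9 months
  d <- tibble::tibble(time_months = c(3, 6, 9), event = 1,
                      risk_group = "all")
  km <- km_estimate(d)
  expect_equal(km$steps$survival, c(2 / 3, 1 / 3, 0))

  # fully censored: survival stays at 1
  dc <- tibble::tibble(time_months = c(5, 8, 11), event = 0,
                       risk_group = "all")
  kmc <- km_estimate(dc)
  expect_true(all(kmc$steps$survival == 1))
  expect_equal(km_survival_at(kmc, 12)$survival, 1)

  # mixed censoring, 5 subjects, against the independent product-limit oracle
  dm <- tibble::tibble(time_months = c(2, 4, 4, 7, 9),
                       event = c(1, 0, 1, 1, 0), risk_group = "all")
  kmm <- km_estimate(dm)
  ora <- oracle_km(dm$time_months, dm$event)
  got <- kmm$steps[kmm$steps$n_event > 0, ]
  expect_equal(got$time, ora$time)
  expect_equal(got$survival, ora$survival)
  # hand values (censored subject at a tied time stays in the risk set):
  # S(2) = 4/5, S(4) = 4/5 * 3/4, S(7) = 4/5 * 3/4 * 1/2
  expect_equal(ora$survival, c(0.8, 0.6, 0.3))
})

test_that("log-rank matches the observed-vs-expected oracle on small data", {
  set.seed(23)
  for (i in 1:8) {
    n <- sample(8:20, 1)
    d <- tibble::tibble(
      time_months = sample(1:15, n, replace = TRUE),
      event = rbinom(n, 1, 0.7),
      risk_group = sample(c("high", "low"), n, replace = TRUE))
    if (length(unique(d$risk_group)) < 2 || sum(d$event) == 0) next
    lr <- log_rank(d)
    expect_equal(lr$statistic,
                 oracle_logrank(d$time_months, d$event, d$risk_group),
                 tolerance = 1e-8)
  }
})

test_that("identical event patterns give a null log-rank statistic", {
  d <- tibble::tibble(time_months = rep(c(3, 6, 9, 12), 2),
                      event = rep(c(1, 1, 0, 1), 2),
                      risk_group = rep(c("high", "low"), each = 4))
  lr <- log_rank(d)
  expect_lt(lr$statistic, 1e-8)
  expect_gt(lr$p_value, 0.99)
})

test_that("hazard ratios recover the generative rate ratio", {
  set.seed(24)
  n <- 2000
  d <- tibble::tibble(
    risk_group = rep(c("low", "high"), each = n / 2),
    time_months = c(rexp(n / 2, 0.05), rexp(n / 2, 0.05 * 3.5)),
    event = 1L)
  hr <- hazard_ratio(d)
  expect_equal(hr$hr, 3.5, tolerance = 0.05 * 3.5)
  # scale invariance: months -> days
  d2 <- dplyr::mutate(d, time_months = time_months * 30.4)
  hr2 <- hazard_ratio(d2)
  expect_equal(hr$hr, hr2$hr, tolerance = 1e-8)
})

test_that("identical groups give a hazard ratio near one", {
  set.seed(25)
  d <- tibble::tibble(risk_group = rep(c("low", "high"), each = 300),
                      time_months = rexp(600, 0.1), event = 1L)
  hr <- hazard_ratio(d)
  expect_gt(hr$ci_low, 0.6)
  expect_lt(hr$ci_high, 1.6)
  expect_true(hr$ci_low < 1 && 1 < hr$ci_high)
})

test_that("stratified evaluation separates a strong prognostic split", {
  set.seed(26)
  n <- 400
  d <- tibble::tibble(
    risk_group = rep(c("low", "high"), each = n / 2),
    time_months = c(rexp(n / 2, 0.04), rexp(n / 2, 0.12)),
    event = rbinom(n, 1, 0.9))
  st <- evaluate_stratification(d)
  expect_lt(st$log_rank$p_value, 0.001)
  expect_gt(st$hazard_ratio$hr, 1.5)
  s12 <- st$survival_at_horizon
  expect_lt(s12$survival[s12$group == "high"],
            s12$survival[s12$group == "low"])
  gl <- glance(st)
  expect_true(all(c("hr", "logrank_p") %in% names(gl)))
  expect_error(log_rank(dplyr::mutate(d, event = 0L)),
               class = "edrisk_degenerate_outcome")
})
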