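test_that("duplicate and anti-correlated columns collapse to one survivor", {
  set.seed(2)
  f1 <- rnorm(80)
  df <- tibble::tibble(f1 = f1, f2 = f1, f3 = -f1 + rnorm(80, sd = 1e-6),
                       f4 = rnorm(80))
  y <- rbinom(80, 1, plogis(f1))
  red <- redundancy_filter(df, y, threshold = 0.70)
  expect_equal(length(unique(red$cluster[red$feature %in% c("f1", "f2", "f3")])), 1)
  expect_equal(sum(red$selected[red$feature %in% c("f1", "f2", "f3")]), 1)
  expect_true(red$selected[red$feature == "f4"])
})

test_that("independent features stay singletons under the default threshold", {
  set.seed(4)
  df <- tibble::as_tibble(as.data.frame(matrix(rnorm(200 * 8), 200, 8)))
  y <- rbinom(200, 1, 0.3)
  red <- redundancy_filter(df, y, threshold = 0.70)
  expect_true(all(red$selected))
  expect_equal(dplyr::n_distinct(red$cluster), 8)
})

test_that("redundancy clustering is invariant to column order", {
  set.seed(6)
  base <- rnorm(100)
  df <- tibble::tibble(a = base + rnorm(100, sd = 0.1),
                       b = rnorm(100),
                       c = base + rnorm(100, sd = 0.1))
  y <- rbinom(100, 1, plogis(base))
  r1 <- redundancy_filter(df, y)
  r2 <- redundancy_filter(df[c("c", "b", "a")], y)
  sel1 <- sort(r1$feature[r1$selected])
  sel2 <- sort(r2$feature[r2$selected])
  expect_identical(sel1, sel2)
})

test_that("constant columns are excluded with an explicit reason", {
  df <- tibble::tibble(a = rnorm(50), k = rep(1, 50))
  y <- rep(c(0, 1), 25)
  red <- redundancy_filter(df, y)
  expect_false(red$selected[red$feature == "k"])
  expect_match(red$reason[red$feature == "k"], "constant")
})

test_that("null bootstrap hit rates match their conditional expectation", {
  # Conditional on the observed data, the per-resample z-statistic for a null
  # covariate fluctuates around the dataset's realized z (z* ~ z_obs + N(0,1)),
  # so the hit probability is pnorm(z-1.96) + pnorm(-z-1.96), which averages
  # ~0.166 over z ~ N(0,1) — not alpha. Simulation across independent null
  # datasets (the frozen oracle value) gives mean count/B = 0.16, sd = 0.14.
  set.seed(8)
  n <- 150; B <- 120
  fracs <- replicate(15, {
    df <- tibble::tibble(x = rnorm(n), edr = rbinom(n, 1, 0.3))
    bootstrap_rank(df, "edr", "x", B = B, seed = sample.int(1e6, 1))$frequency
  })
  expect_gt(mean(fracs), 0.05)              # conditional inflation is real
  expect_lt(abs(mean(fracs) - 0.166), 0.11) # 3 SE Monte-Carlo band
  # majority-vote selection of a null variable stays rare
  expect_lte(sum(fracs > 0.5), 3)
})

test_that("a strong planted effect is selected by majority vote", {
  set.seed(9)
  n <- 150
  x <- rnorm(n)
  df <- tibble::tibble(signal = x, noise = rnorm(n),
                       edr = rbinom(n, 1, plogis(-1 + 1.5 * x)))
  rk <- bootstrap_rank(df, "edr", c("signal", "noise"), B = 200, seed = 11)
  expect_true(rk$selected[rk$variable == "signal"])
  expect_false(rk$selected[rk$variable == "noise"])
  expect_equal(rk$variable[1], "signal")
})

test_that("bootstrap ranking is deterministic under a fixed seed", {
  set.seed(12)
  df <- tibble::tibble(x = rnorm(60), edr = rbinom(60, 1, 0.4))
  r1 <- bootstrap_rank(df, "edr", "x", B = 1, seed = 99)
  r2 <- bootstrap_rank(df, "edr", "x", B = 1, seed = 99)
  expect_identical(r1$count, r2$count)
  expect_true(r1$count %in% c(0L, 1L))
})

test_that("expected selection count grows with the true effect size", {
  set.seed(13)
  n <- 120; B <- 60; reps <- 20
  mean_counts <- vapply(c(0, 0.7, 1.6), function(beta) {
    mean(replicate(reps, {
      x <- rnorm(n)
      df <- tibble::tibble(x = x, edr = rbinom(n, 1, plogis(-1 + beta * x)))
      bootstrap_rank(df, "edr", "x", B = B,
                     seed = sample.int(1e6, 1))$count
    }))
  }, numeric(1))
  expect_true(all(diff(mean_counts) > 0))
})

test_that("unknown candidate names raise a configuration error", {
  df <- tibble::tibble(x = rnorm(30), edr = rbinom(30, 1, 0.5))
  expect_error(bootstrap_rank(df, "edr", c("x", "ghost"), B = 5, seed = 1),
               class = "edrisk_config_error")
})
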