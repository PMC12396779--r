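test_that("equal-mass bins split with larger bins first, stable on ties", {
  b <- adaptive_bins(seq(0.05, 0.95, length.out = 10), rep(TRUE, 10), 5)
  expect_equal(b$n, rep(2L, 5))

  b <- adaptive_bins(seq(0.1, 0.7, length.out = 7), rep(TRUE, 7), 3)
  expect_equal(b$n, c(3L, 2L, 2L))

  # all confidences tied: both bins share the same conf_mean, ties span
  # bins in stable input order
  conf <- rep(0.9, 4)
  outcomes <- c(TRUE, TRUE, FALSE, TRUE)
  b <- adaptive_bins(conf, outcomes, 2)
  expect_equal(b$conf_mean, c(0.9, 0.9))
  expect_equal(b$acc, c(1, 0.5))
  expect_equal(ace(conf, outcomes, 2), (0.1 + 0.4) / 2)

  expect_error(adaptive_bins(c(.1, .2), c(TRUE, TRUE), 3), "smaller n_bins")
  expect_error(adaptive_bins(c(.1, 1.2), c(TRUE, TRUE), 1), "\\[0, 1\\]")
})

test_that("ACE reproduces the hand-computed 6-record/2-bin example exactly", {
  conf <- c(0.9, 0.6, 0.95, 0.7, 1.0, 0.8)
  outcomes <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE) # sorted: 1,0,1 | 1,1,0
  expect_equal(ace(conf, outcomes, 2),
               (abs(2 / 3 - 0.7) + abs(2 / 3 - 0.95)) / 2)
  expect_equal(ace(conf, outcomes, 2), 0.15833333, tolerance = 1e-7)
})

test_that("ACE closed forms: perfect calibration and constant offset", {
  expect_equal(ace(rep(1, 8), rep(TRUE, 8), 4), 0)
  # all conf = 1, accuracy 0.6 -> ACE = 0.4 for any bin count
  conf <- rep(1, 10)
  outcomes <- c(rep(TRUE, 6), rep(FALSE, 4))
  for (nb in c(1, 2, 5)) {
    expect_equal(ace(conf, outcomes, nb), 0.4)
  }
})

test_that("ACE with a single bin equals |accuracy - mean confidence|", {
  set.seed(31)
  for (r in 1:100) {
    n <- sample(5:80, 1)
    conf <- runif(n)
    outcomes <- runif(n) < 0.5
    expect_equal(ace(conf, outcomes, 1),
                 abs(mean(outcomes) - mean(conf)), tolerance = 1e-12)
  }
})

test_that("Brier score matches closed forms and its analytic expectation", {
  expect_equal(brier_score(1, TRUE), 0)
  expect_equal(brier_score(0.7, FALSE), 0.49)
  set.seed(32)
  outcomes <- runif(10000) < 0.7
  expect_equal(brier_score(rep(0.7, 10000), outcomes), 0.7 * 0.3,
               tolerance = 0.01 / 0.21)
  expect_error(brier_score(numeric(), logical()), "undefined")
})

test_that("a constant Brier forecast is minimized at the base rate", {
  set.seed(33)
  outcomes <- runif(500) < 0.63
  grid <- seq(0, 1, by = 0.01)
  briers <- sapply(grid, function(p) {
    brier_score(rep(p, length(outcomes)), outcomes)
  })
  expect_lt(abs(grid[which.min(briers)] - mean(outcomes)), 0.011)
})

test_that("bootstrap intervals are deterministic given the seed", {
  conf <- c(0.9, 0.6, 0.95, 0.7, 1.0, 0.8)
  outcomes <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
  ace2 <- function(conf, out) ace(conf, out, 2)
  ci1 <- bootstrap_ci(ace2, conf, outcomes, reps = 1000, seed = 99)
  ci2 <- bootstrap_ci(ace2, conf, outcomes, reps = 1000, seed = 99)
  expect_identical(ci1, ci2)

  degenerate <- bootstrap_ci(function(c, o) mean(c), rep(1, 10),
                             rep(TRUE, 10), reps = 200, seed = 1)
  expect_equal(unname(degenerate), c(1, 1))
  expect_error(bootstrap_ci(ace2, conf, outcomes, reps = 50, seed = 1),
               "at least 200")
  expect_error(bootstrap_ci(ace2, conf, outcomes, reps = 200), "seed")
})

test_that("the nominal 95% Brier interval covers the truth in most replicates", {
  set.seed(34)
  q <- 0.6
  c0 <- 0.7
  true_brier <- c0^2 - 2 * c0 * q + q  # E[(c - Y)^2] for constant c
  covered <- replicate(200, {
    outcomes <- runif(300) < q
    conf <- rep(c0, 300)
    ci <- bootstrap_ci(brier_score, conf, outcomes, reps = 200,
                       seed = sample.int(1e6, 1))
    ci[1] <= true_brier && true_brier <= ci[2]
  })
  expect_gte(mean(covered), 0.90)
})

test_that("paired bootstrap p-values: identical data, large effects, smoothing floor", {
  set.seed(35)
  conf <- runif(400)
  outcomes <- runif(400) < conf
  expect_equal(
    bootstrap_paired_pvalue(brier_score, conf, conf, outcomes,
                            reps = 499, seed = 3),
    1
  )
  # A calibrated, B offset by +0.3: ACE strongly differs
  confB <- pmin(conf + 0.3, 1)
  ace10 <- function(conf, out) ace(conf, out, 10)
  p <- bootstrap_paired_pvalue(ace10, conf, confB, outcomes,
                               reps = 999, seed = 4)
  expect_lte(p, 0.01)
  expect_equal(p, 2 / 1000)  # add-one smoothing floor at reps = 999
})

test_that("calibration-curve points straddle reality as constructed", {
  set.seed(36)
  n <- 20000
  conf <- runif(n)
  outcomes <- runif(n) < conf
  bins <- adaptive_bins(conf, outcomes, 10)
  curve <- calibration_curve(bins)
  expect_equal(nrow(curve), 10)
  expect_true(!is.unsorted(curve$conf_mean))
  expect_lte(max(abs(curve$acc - curve$conf_mean)), 0.03)

  # single bin: the overall means
  one <- calibration_curve(adaptive_bins(conf, outcomes, 1))
  expect_equal(one$conf_mean, mean(conf))
  expect_equal(one$acc, mean(outcomes))

  # uniformly overconfident forecasts sit strictly below the identity
  true_p <- runif(n, 0.05, 0.8)
  reported <- pmin(true_p + 0.15, 1)
  outcomes2 <- runif(n) < true_p
  over <- calibration_curve(adaptive_bins(reported, outcomes2, 10))
  expect_true(all(over$acc < over$conf_mean))
})

test_that("calibration_report bundles ACE, Brier, bins and the poor-calibration flag", {
  set.seed(37)
  conf <- rep(0.95, 400)
  outcomes <- runif(400) < 0.6
  rep_ <- calibration_report(conf, outcomes, n_bins = 10, reps = 300,
                             seed = 5, metric = "expressed")
  expect_s3_class(rep_, "calibration_report")
  expect_equal(rep_$ace, abs(mean(outcomes) - 0.95), tolerance = 1e-10)
  expect_true(rep_$flag_poor)
  expect_equal(nrow(tidy(rep_)), 10)
  g <- glance(rep_)
  expect_equal(g$ace, rep_$ace)
  expect_true(g$flag_poor)
  expect_lte(g$ace_low, g$ace_high)
})
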