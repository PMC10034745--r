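maxd_series <- function(values, exposures = default_exposures()) {
  tibble::tibble(exposure = exposures, uptake = values)
}

test_that("constant maxD series give exact retention with zero slope", {
  tmax <- 4.0
  m1 <- estimate_backexchange(maxd_series(rep(tmax, 15)), tmax)
  expect_equal(m1$retention, 1)
  expect_equal(m1$slope, 0)
  expect_equal(m1$r_squared, 0)

  m2 <- estimate_backexchange(maxd_series(rep(tmax / 2, 15)), tmax)
  expect_equal(m2$retention, 0.5)
})

test_that("degenerate references are rejected, >1 retention flagged", {
  expect_error(estimate_backexchange(maxd_series(rep(1, 15)), 0), "positive")
  expect_error(
    estimate_backexchange(tibble::tibble(exposure = numeric(), uptake = numeric()), 1),
    "Empty"
  )
  expect_warning(estimate_backexchange(maxd_series(rep(1.2, 15)), 1), "exceeds 1")
  clipped <- suppressWarnings(
    estimate_backexchange(maxd_series(rep(1.2, 15)), 1, clip = TRUE)
  )
  expect_equal(clipped$retention, 1)
})

test_that("an injected retention drift is recovered by the regression", {
  # drift of 1e-4 per second over 300 s on a 0.9 baseline
  set.seed(42)
  exposures <- default_exposures()
  tmax <- 4.75
  truth_slope <- 1e-4
  ret <- 0.9 + truth_slope * exposures + rnorm(length(exposures), 0, 0.002)
  m <- estimate_backexchange(maxd_series(ret * tmax), tmax)
  ols <- oracle_ols(exposures, ret)
  expect_equal(m$slope, ols$slope, tolerance = 1e-10)
  expect_lt(abs(m$slope - truth_slope), 2 * ols$se)
})

test_that("correction divides by retention and flags overshoot", {
  tmax <- 4
  model <- estimate_backexchange(maxd_series(rep(2, 15)), tmax) # retention 0.5
  obs <- tibble::tibble(exposure = c(0.1, 1), uptake = c(2, 0.5))
  out <- expect_silent(correct_uptake(obs, model))
  expect_equal(out$uptake, c(4, 1))
  expect_false(any(out$above_max))

  ident <- estimate_backexchange(maxd_series(rep(tmax, 15)), tmax)
  expect_equal(correct_uptake(obs, ident)$uptake, obs$uptake)

  over <- tibble::tibble(exposure = 1, uptake = tmax * 0.6)
  expect_warning(correct_uptake(over, model), "exceed")
})

test_that("correction commutes with scaling and round-trips synthetic truth", {
  tmax <- 4
  model <- estimate_backexchange(maxd_series(rep(3, 15)), tmax)
  obs <- tibble::tibble(exposure = default_exposures(), uptake = seq(0.1, 2.9, length.out = 15))
  a <- 0.37
  scaled <- dplyr::mutate(obs, uptake = uptake * a)
  expect_equal(correct_uptake(scaled, model)$uptake,
               a * correct_uptake(obs, model)$uptake)

  # generate true uptake, apply retention + noise, correct with the
  # estimated model: truth recovered within replicate-noise tolerance
  set.seed(7)
  cond <- labeling_conditions()
  rates <- residue_intrinsic_rates("AEAWYNLGNAYYK", cond)
  truth <- intrinsic_uptake_curve(rates, default_exposures(), cond$d2o_fraction)
  r_true <- 0.85
  tmax_pep <- theoretical_max_uptake("AEAWYNLGNAYYK", cond$d2o_fraction)
  sd_noise <- 0.02
  maxd_obs <- maxd_series(r_true * tmax_pep + rnorm(45, 0, sd_noise),
                          rep(default_exposures(), 3))
  labeled <- tibble::tibble(
    exposure = rep(truth$exposure, 3),
    uptake = rep(truth$uptake, 3) * r_true + rnorm(45, 0, sd_noise)
  )
  est <- estimate_backexchange(maxd_obs, tmax_pep)
  corr <- suppressWarnings(correct_uptake(labeled, est))
  by_exp <- tapply(corr$uptake, corr$exposure, mean)
  expect_equal(as.vector(by_exp[as.character(truth$exposure)]),
               truth$uptake, tolerance = 0.05)
})

test_that("slope test holds its nominal type-I error on time-invariant data", {
  n_seeds <- 200
  tmax <- 4.75
  rejections <- vapply(seq_len(n_seeds), function(s) {
    set.seed(s)
    vals <- 0.9 * tmax + rnorm(15, 0, 0.05)
    m <- estimate_backexchange(maxd_series(vals), tmax)
    m$p_value < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.11)
})

test_that("percent normalization and the 1:20 D2O accounting", {
  tmax <- 4
  abs_tbl <- tibble::tibble(exposure = c(0.1, 1), uptake = c(0, tmax))
  pct <- normalize_percent(abs_tbl, tmax)
  expect_equal(pct$uptake, c(0, 100))
  expect_equal(pct$units, rep("percent", 2))
  expect_error(normalize_percent(abs_tbl, 0), "positive")

  expect_equal(d2o_fraction_after_mixing(20, 0.999), 20 * 0.999 / 21)
  expect_equal(round(100 * d2o_fraction_after_mixing(20, 0.999)), 95)
})
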