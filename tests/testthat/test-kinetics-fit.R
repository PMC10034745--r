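times15 <- default_exposures()

test_that("noiseless single-phase data are recovered to optimizer tolerance", {
  d <- data.frame(
    exposure = rep(times15, 2),
    uptake = rep(4 * (1 - exp(-2 * times15)), 2)
  )
  f <- fit_stretched_exponential(d, 1)
  expect_equal(f$status, "fitted")
  expect_equal(f$phases$q, 4, tolerance = 1e-6)
  expect_equal(f$phases$k, 2, tolerance = 1e-6)
  expect_equal(f$phases$beta, 1, tolerance = 1e-6)
  expect_gt(f$r_squared, 0.999999)
  # fitted curve is monotone non-decreasing
  grid <- 10^seq(-3, 3, length.out = 200)
  expect_true(all(diff(predict(f, grid)) >= -1e-12))
})

test_that("two-phase parameters are recovered within 10% over repeated sims", {
  ks <- t(vapply(1:10, function(s) {
    d <- simulate_series(two_phase_uptake, times15, n_rep = 3, cv = 0.01, seed = s)
    f <- fit_stretched_exponential(d, 2)
    c(f$phases$k, f$phases$q)
  }, numeric(4)))
  expect_equal(mean(ks[, 1]), 10, tolerance = 0.1)
  expect_equal(mean(ks[, 2]), 0.05, tolerance = 0.1)
  expect_equal(mean(ks[, 3]), 2, tolerance = 0.1)
  expect_equal(mean(ks[, 4]), 3, tolerance = 0.1)
})

test_that("insufficient data and degenerate series are handled", {
  few <- data.frame(exposure = c(0.1, 1, 10, 100), uptake = c(1, 2, 3, 3.2))
  expect_error(fit_stretched_exponential(few, 1), "at least")
  flat <- data.frame(exposure = rep(times15, 2), uptake = rep(0, 30))
  f <- fit_stretched_exponential(flat, 1)
  expect_equal(f$status, "uninformative")
  expect_equal(f$phases$q, 0)
  sel <- select_model(flat)
  expect_equal(sel$n_phases, 1L)
  expect_equal(sel$status, "uninformative")
})

test_that("model selection picks the minimal adequate phase count", {
  # pure single phase with noise: extra phases rejected in most seeds
  one_phase <- function(t) 4 * (1 - exp(-2 * t))
  picks1 <- vapply(1:20, function(s) {
    d <- simulate_series(one_phase, times15, n_rep = 3, cv = 0.01, seed = 100 + s)
    select_model(d)$n_phases
  }, integer(1))
  expect_gte(mean(picks1 == 1L), 0.8)

  # well-separated two-phase truth (rate ratio 200)
  picks2 <- vapply(1:10, function(s) {
    d <- simulate_series(two_phase_uptake, times15, n_rep = 3, cv = 0.01, seed = s)
    select_model(d)$n_phases
  }, integer(1))
  expect_gte(mean(picks2 == 2L), 0.9)
})

test_that("adding a phase never increases the residual sum of squares", {
  d <- simulate_series(two_phase_uptake, times15, n_rep = 3, cv = 0.01, seed = 3)
  f1 <- fit_stretched_exponential(d, 1)
  f2 <- fit_stretched_exponential(d, 2)
  f3 <- fit_stretched_exponential(d, 3)
  expect_lte(f2$rss, f1$rss + 1e-8)
  expect_lte(f3$rss, f2$rss + 1e-8)
})

test_that("protection factors: closed forms and phase-rank matching", {
  d <- data.frame(
    exposure = rep(times15, 2),
    uptake = rep(4 * (1 - exp(-2 * times15)), 2)
  )
  f_exp <- fit_stretched_exponential(d, 1)
  pf0 <- protection_factors(f_exp, f_exp)
  expect_equal(pf0$ln_pf, 0, tolerance = 1e-9)

  d_int <- data.frame(
    exposure = rep(times15, 2),
    uptake = rep(4 * (1 - exp(-20 * times15)), 2)
  )
  f_int <- fit_stretched_exponential(d_int, 1)
  d_slow <- data.frame(
    exposure = rep(times15, 2),
    uptake = rep(4 * (1 - exp(-2 * times15)), 2)
  )
  f_slow <- fit_stretched_exponential(d_slow, 1)
  pf <- protection_factors(f_slow, f_int)
  expect_equal(pf$ln_pf, log(10), tolerance = 1e-4)
  expect_equal(mean_ln_pf(f_slow, f_int), log(10), tolerance = 1e-4)

  # mismatched phase counts matched by amplitude rank with a warning
  d2 <- simulate_series(two_phase_uptake, times15, n_rep = 3, cv = 0.01, seed = 5)
  f2 <- fit_stretched_exponential(d2, 2)
  expect_warning(pf_m <- protection_factors(f2, f_int), "amplitude rank")
  expect_equal(nrow(pf_m), 1L)
})

test_that("uniform protection forward-simulated via intrinsic rates is recovered", {
  cond <- labeling_conditions()
  seqn <- "AEAWYNLGNAYYK"
  rates <- residue_intrinsic_rates(seqn, cond)
  k_in <- rates$k_int[rates$included]
  true_lnpf <- 2
  set.seed(9)
  exp_uptake <- function(t) {
    cond$d2o_fraction * vapply(t, function(x) sum(1 - exp(-k_in / exp(true_lnpf) * x)), numeric(1))
  }
  d_exp <- simulate_series(exp_uptake, times15, n_rep = 3, cv = 0.01, seed = 9)
  sel <- suppressWarnings(select_model(d_exp, q_max = theoretical_max_uptake(seqn, cond$d2o_fraction)))
  grid <- 10^seq(log10(0.025), log10(600), length.out = 60)
  int_curve <- intrinsic_uptake_curve(rates, grid, cond$d2o_fraction)
  f_int <- fit_stretched_exponential(int_curve, sel$n_phases)
  expect_equal(mean_ln_pf(sel, f_int), true_lnpf, tolerance = 0.3)
})

test_that("first-order decay fitting: exact recovery, degenerate flat signal", {
  tt <- c(0.04, 0.1, 0.2, 0.3, 0.4, 0.5)
  clean <- 1.7 * exp(-20.1 * tt)
  f <- fit_first_order_decay(tt, clean)
  expect_equal(f$k, 20.1, tolerance = 1e-6)
  expect_true(f$decaying)

  fc <- fit_first_order_decay(c(0.1, 0.2, 0.3, 0.4, 0.5), rep(2, 5))
  expect_equal(fc$k, 0)
  expect_false(fc$decaying)
  expect_lte(fc$conf_low, 0)
  expect_gte(fc$conf_high, 0)

  expect_error(fit_first_order_decay(c(1, 2, 3), c(3, 2, 1)), "4 points")
})

test_that("decay-rate CI covers the truth at nominal frequency", {
  hits <- vapply(1:150, function(s) {
    dn <- simulate_dnpa(20.1, noise_cv = 0.03, seed = s, n_replicates = 3)
    f <- fit_first_order_decay(dn$time, dn$signal)
    f$conf_low <= 20.1 && 20.1 <= f$conf_high
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("tidy and glance return well-formed summaries", {
  d <- simulate_series(two_phase_uptake, times15, n_rep = 3, cv = 0.01, seed = 2)
  f <- fit_stretched_exponential(d, 2)
  td <- tidy(f)
  expect_setequal(unique(td$term), c("q", "k", "beta"))
  expect_equal(nrow(td), 6L)
  gl <- glance(f)
  expect_equal(gl$n_phases, 2L)
  expect_true(gl$r.squared > 0.99)
})
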