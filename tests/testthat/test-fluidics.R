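test_that("Reynolds number is linear in flow and matches hand values", {
  expect_equal(reynolds_number(0), 0)
  # LV = F / (pi r^2), Re = LV d / kv, computed longhand
  f <- 1000
  lv <- f / (pi * (0.733 / 2)^2)
  expect_equal(reynolds_number(f), lv * 0.733 / 1)
  expect_equal(reynolds_number(2 * f), 2 * reynolds_number(f))
  expect_error(reynolds_number(10, diameter = 0), "diameter")
  expect_error(reynolds_number(10, kinematic_viscosity = -1), "viscosity")
  expect_error(reynolds_number(-5), "non-negative")
})

test_that("loop-volume dilution calibration", {
  expect_equal(loop_volume_from_dilution(24, 24, 1000), 1000)
  expect_equal(loop_volume_from_dilution(24, 0, 1000), 0)
  expect_equal(loop_volume_from_dilution(24, 12, 1000), 500)
  expect_error(loop_volume_from_dilution(24, 25, 1000), "impossible")
})

test_that("instrument config validates loop geometry", {
  cfg <- instrument_config()
  expect_length(cfg$loop_volumes, 6L)
  expect_equal(cfg$loop_volumes[1], 135)
  expect_error(instrument_config(loop_volumes = c(100, 90)), "ascending")
  expect_error(instrument_config(loop_volumes = c(100, 300)), "1.25")
  expect_warning(instrument_config(loop_volumes = c(100, 240, 576)), "design band")
  expect_error(instrument_config(min_total_flow = 3000), "min_total_flow")
})

test_that("planner floor, boundary feasibility and mode switching", {
  cfg <- instrument_config()
  floor_s <- 135 / 2700
  expect_error(plan_time_points(floor_s / 2, cfg), "floor")

  p_floor <- plan_time_points(floor_s, cfg)
  expect_equal(p_floor$mode, "continuous")
  expect_equal(p_floor$loop_index, 1L)
  expect_equal(p_floor$label_flow, 2700, tolerance = 1e-9)
  expect_equal(p_floor$achieved, 0.05)
  expect_equal(p_floor$re_label, 4696, tolerance = 0.005)

  # a time achievable exactly at minimum flow still meets the Re floor
  t_min_flow <- 135 / cfg$min_total_flow
  p_min <- plan_time_points(t_min_flow, cfg)
  expect_equal(p_min$label_flow, cfg$min_total_flow, tolerance = 1e-9)
  expect_gte(p_min$re_label, 2000)

  # far beyond continuous coverage: stop-flow at preset flows
  p_long <- plan_time_points(300, cfg)
  expect_equal(p_long$mode, "stop_flow")
  expect_equal(p_long$label_flow, 2400)
  expect_equal(p_long$quench_flow, 4800)
  expect_lt(abs(p_long$achieved - 300), 5e-4)
})

test_that("quench mixer sees doubled flow at a 1:1 quench ratio", {
  cfg <- instrument_config()
  p <- plan_time_points(0.05, cfg)
  expect_equal(p$quench_flow, 2 * p$label_flow)
  expect_equal(p$re_quench, 2 * p$re_label, tolerance = 1e-12)
})

test_that("config round-trips through YAML and JSON readers", {
  cfg_list <- list(
    tubing_diameter = 0.733,
    loop_volumes = c(135, 236.25, 413.4),
    min_total_flow = 1154,
    max_total_flow = 2700
  )
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_list, yml)
  cfg <- read_instrument_config(yml)
  expect_s3_class(cfg, "instrument_config")
  expect_equal(cfg$loop_volumes, c(135, 236.25, 413.4))

  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg_list, jsn, auto_unbox = TRUE, digits = NA)
  cfg2 <- read_instrument_config(jsn)
  expect_equal(cfg2$loop_volumes, cfg$loop_volumes)
  expect_error(
    read_instrument_config({
      bad <- tempfile(fileext = ".yaml")
      yaml::write_yaml(list(nonsense = 1), bad)
      bad
    }),
    "Unknown config key"
  )
})

test_that("DNPA simulation is exact without noise and reproducible by seed", {
  tt <- c(0.04, 0.1, 0.2, 0.5)
  d0 <- simulate_dnpa(20.1, times = tt, noise_cv = 0)
  expect_equal(d0$signal, exp(-20.1 * tt))
  d1 <- simulate_dnpa(20.1, times = tt, noise_cv = 0.03, seed = 5, n_replicates = 3)
  d2 <- simulate_dnpa(20.1, times = tt, noise_cv = 0.03, seed = 5, n_replicates = 3)
  expect_identical(d1, d2)
  expect_error(simulate_dnpa(-1), "positive")
})

test_that("pseudo-first-order conversion of the hydrolysis clock", {
  expect_equal(pseudo_first_order_rate(55, 0.44), 24.2)
  expect_error(pseudo_first_order_rate(0, 1), "positive")
  # simulated clock at the instrument's fitted rate refits close to truth
  dn <- simulate_dnpa(20.1, noise_cv = 0.03, seed = 17, n_replicates = 3)
  f <- fit_first_order_decay(dn$time, dn$signal)
  expect_equal(f$k, 20.1, tolerance = 0.15)
})
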