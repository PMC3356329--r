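test_that("generators are bit-reproducible given the same config and seed", {
  cfg <- beat_train_config(duration = 5, seed = 7)
  expect_identical(simulate_beat_trajectory(cfg)$force,
                   simulate_beat_trajectory(cfg)$force)
  expect_identical(simulate_thermal_noise(0.04, seed = 3, duration = 2)$deflection,
                   simulate_thermal_noise(0.04, seed = 3, duration = 2)$deflection)
  hc <- hertz_curve_config(E_true = 300, noise_sd_deflection = 0.5e-9,
                           n_points = 200, seed = 5)
  expect_identical(simulate_force_curve(hc)$deflection,
                   simulate_force_curve(hc)$deflection)
  dc <- dose_response_config(seed = 11)
  expect_identical(simulate_dose_response(dc)$force_N,
                   simulate_dose_response(dc)$force_N)
})

test_that("noiseless beat train reproduces the configured peaks exactly", {
  cfg <- beat_train_config(duration = 4, beat_rate_mean = 1, beat_rate_cv = 0,
                           amplitude_mean = 1e-9, amplitude_cv = 0,
                           fwhm_mean = 0.2, fwhm_cv = 0, noise_sd = 0,
                           peak_shape = "gaussian", seed = 1)
  tr <- simulate_beat_trajectory(cfg)
  gt <- tr$meta$ground_truth
  expect_equal(nrow(gt), 4L)
  # degenerate distributions: identical amplitudes, uniform intervals
  expect_true(all(gt$amplitude == 1e-9))
  expect_equal(diff(gt$t_peak), rep(1, 3), tolerance = 1e-12)
  # max over each one-beat window is the amplitude above the (zero) baseline
  for (tp in gt$t_peak) {
    win <- tr$force[abs(tr$time - tp) < 0.5]
    expect_equal(max(win), 1e-9, tolerance = 1e-6)
  }
})

test_that("beat-free trajectory noise matches the configured 20 pN scale", {
  tr <- noise_trajectory(duration = 120, noise_sd = 20e-12, seed = 42)
  expect_equal(sd(tr$force), 20e-12, tolerance = 0.05)
})

test_that("unresolvable peak widths are rejected", {
  expect_error(beat_train_config(sampling_rate = 20, fwhm_mean = 0.2),
               "resolvable")
})

test_that("thermal noise variance obeys equipartition", {
  kB <- 1.380649e-23
  th <- simulate_thermal_noise(0.04, 310, duration = 60, seed = 9)
  expect_equal(var(th$deflection), kB * 310 / 0.04, tolerance = 0.02)
  # doubling the spring constant halves the variance
  th2 <- simulate_thermal_noise(0.08, 310, duration = 60, seed = 9)
  expect_equal(var(th$deflection) / var(th2$deflection), 2, tolerance = 0.05)
  # zero temperature freezes the cantilever
  th0 <- simulate_thermal_noise(0.04, 0, duration = 1, seed = 1)
  expect_true(all(th0$deflection == 0))
  # equipartition holds on average across seeds
  v <- vapply(1:20, function(s) {
    var(simulate_thermal_noise(0.04, 310, duration = 10, seed = s)$deflection)
  }, numeric(1))
  expect_equal(mean(v), kB * 310 / 0.04, tolerance = 0.01)
})

test_that("noiseless cone curve follows the Sneddon force law exactly", {
  cfg <- hertz_curve_config(E_true = 300, geometry = "cone",
                            tip_half_angle = 35, contact_point = 1e-6,
                            max_indentation = 400e-9, n_points = 300, seed = 1)
  cv <- simulate_force_curve(cfg)
  post <- cv$z > 1e-6
  delta <- (cv$z[post] - 1e-6) - cv$deflection[post]
  f_model <- (2 / pi) * tan(35 * pi / 180) * 300 / (1 - 0.25) * delta^2
  expect_equal(cv$deflection[post] * cv$spring_constant, f_model,
               tolerance = 1e-9)
  # pre-contact deflection is exactly zero without noise
  expect_true(all(cv$deflection[!post] == 0))
})

test_that("sphere force law scales as delta^(3/2) and nu = 0.5 gives 4/3", {
  f1 <- hertz_force(200e-9, 1000, "sphere", 5e-6)
  f2 <- hertz_force(400e-9, 1000, "sphere", 5e-6)
  expect_equal(f2 / f1, 2^1.5, tolerance = 1e-12)
  expect_equal(hertz_force(1, 1, "cone", 45, nu = 0.5),
               (2 / pi) * (4 / 3), tolerance = 1e-12)
  expect_equal(hertz_force(-1e-9, 1000, "cone", 35), 0)
})

test_that("dwell map generator respects mask and mixture structure", {
  cfg <- dwell_map_config(n_rows = 5, n_cols = 5, dwell_duration = 4,
                          curve_n_points = 150, seed = 2)
  raw <- simulate_dwell_map(cfg)
  gt <- raw$ground_truth
  expect_equal(nrow(gt), 25L)
  expect_length(raw$points, 25L)
  # single-component mixture: every on-cell point uses component 1
  expect_true(all(gt$component[gt$on_cell] == 1L))
  # glass points carry the stiff glass modulus and no beats in ground truth
  expect_true(all(gt$E_true[!gt$on_cell] == cfg$glass_E))
  expect_true(all(gt$force_true[!gt$on_cell] == 0))
  # two well-separated components form two clusters in the joint plane
  cfg2 <- dwell_map_config(n_rows = 8, n_cols = 8, dwell_duration = 4,
                           curve_n_points = 150,
                           components = list(
                             list(weight = 0.5, force_mean = 2e-9,
                                  force_cv = 0.05, logE_mean = log(1000),
                                  logE_sd = 0.1),
                             list(weight = 0.5, force_mean = 0.2e-9,
                                  force_cv = 0.05, logE_mean = log(50),
                                  logE_sd = 0.1)),
                           seed = 3)
  gt2 <- simulate_dwell_map(cfg2)$ground_truth
  on <- gt2[gt2$on_cell, ]
  expect_true(all(on$force_true[on$component == 1] >
                    max(on$force_true[on$component == 2])))
  expect_true(all(on$E_true[on$component == 1] >
                    max(on$E_true[on$component == 2])))
  expect_error(dwell_map_config(cell_mask = matrix(FALSE, 15, 15)), "empty")
  expect_error(dwell_map_config(components = list(list(weight = 0.5,
    force_mean = 1e-9, force_cv = 0.1, logE_mean = 5, logE_sd = 0.1))),
    "sum to 1")
})

test_that("dose-response generator matches the Hill law", {
  cfg <- dose_response_config(doses = c(1e-8, 1e-7, 2.6e-7, 1e-6, 1e-5),
                              ec50_true = 2.6e-7, baseline_force = 0.2e-9,
                              max_force = 0.6e-9, noise_cv = 0,
                              beats_per_dose = 5, seed = 1)
  dr <- simulate_dose_response(cfg)
  # at dose = EC50 the response is the midpoint of the asymptotes
  at_ec50 <- dr$force_N[dr$dose_M == 2.6e-7]
  expect_equal(unique(at_ec50), 0.4e-9, tolerance = 1e-12)
  # asymptotes
  hill <- function(d) 0.2e-9 + 0.4e-9 * d / (d + 2.6e-7)
  for (d in unique(dr$dose_M)) {
    expect_equal(unique(dr$force_N[dr$dose_M == d]), hill(d),
                 tolerance = 1e-12)
  }
  expect_error(dose_response_config(doses = c(1e-6, 1e-7)), "increasing")
  expect_error(dose_response_config(baseline_force = 1e-9, max_force = 0.5e-9),
               "exceed")
})
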