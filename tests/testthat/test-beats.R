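test_that("baseline estimation: constant, beat-train and ramp inputs", {
  fs <- 2000
  tt <- (0:(10 * fs - 1)) / fs
  # constant trajectory: baseline is that constant everywhere
  const <- force_trajectory(tt, rep(0.5e-9, length(tt)), fs)
  expect_equal(estimate_baseline(const), rep(0.5e-9, length(tt)))
  # noiseless beat train on zero baseline: baseline within 1% of peak height
  cfg <- beat_train_config(duration = 30, beat_rate_mean = 1, beat_rate_cv = 0,
                           amplitude_mean = 1e-9, amplitude_cv = 0,
                           fwhm_mean = 0.2, fwhm_cv = 0, noise_sd = 0, seed = 1)
  tr <- simulate_beat_trajectory(cfg)
  expect_lt(max(abs(estimate_baseline(tr))), 0.01 * 1e-9)
  # linear ramp: matches a direct sliding-window percentile oracle
  ramp <- force_trajectory(tt[1:4000], seq(0, 1e-9, length.out = 4000), fs)
  got <- estimate_baseline(ramp, window = 0.5, percentile = 0.1)
  want <- rolling_percentile_direct(ramp$force, 1000, 0.1)
  interior <- 501:3500  # edge windows are truncated differently by design
  expect_lt(max(abs(got[interior] - want[interior])), 0.02 * 1e-9)
  # over-long window falls back to the global percentile with a warning
  expect_warning(b <- estimate_baseline(ramp, window = 60), "global")
  expect_equal(b, rep(quantile(ramp$force, 0.1, names = FALSE), 4000))
})

test_that("noiseless Gaussian beats are detected with exact metrics", {
  cfg <- beat_train_config(duration = 4, beat_rate_mean = 1, beat_rate_cv = 0,
                           amplitude_mean = 1e-9, amplitude_cv = 0,
                           fwhm_mean = 0.2, fwhm_cv = 0, noise_sd = 0,
                           peak_shape = "gaussian", seed = 1)
  ev <- detect_beats(simulate_beat_trajectory(cfg))
  expect_equal(nrow(ev), 4L)
  expect_equal(ev$force, rep(1e-9, 4), tolerance = 0.01)
  expect_equal(ev$rate_to_next[1:3], rep(1, 3), tolerance = 1e-3)
  # FWHM equals 2 sqrt(2 log 2) sigma within one sample period
  sigma <- 0.2 / (2 * sqrt(2 * log(2)))
  expect_lt(max(abs(ev$fwhm - 2.3548 * sigma)), 1 / 2000)
})

test_that("FWHM closed form holds without smoothing", {
  fs <- 2000
  tt <- (0:(6 * fs - 1)) / fs
  sigma <- 0.1
  f <- 1e-9 * exp(-(tt - 3)^2 / (2 * sigma^2))
  tr <- force_trajectory(tt, f, fs)
  ev <- detect_beats(tr, smooth_sigma = 0)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$fwhm - 2 * sqrt(2 * log(2)) * sigma), 1 / fs)
})

test_that("pure noise yields no detections at the auto threshold", {
  tr <- noise_trajectory(duration = 120, seed = 12)
  expect_equal(nrow(detect_beats(tr)), 0L)
})

test_that("detection is invariant to a constant force offset", {
  cfg <- beat_train_config(duration = 20, amplitude_mean = 0.5e-9, seed = 6)
  tr <- simulate_beat_trajectory(cfg)
  shifted <- force_trajectory(tr$time, tr$force + 3e-9, tr$sampling_rate)
  ev1 <- detect_beats(tr)
  ev2 <- detect_beats(shifted)
  expect_equal(ev1$t_peak, ev2$t_peak)
  expect_equal(ev1$force, ev2$force, tolerance = 1e-9)
  expect_equal(ev1$fwhm, ev2$fwhm, tolerance = 1e-9)
})

test_that("beat summaries report n-1 SDs, SEMs and CVs", {
  ev <- structure(data.frame(t_peak = 1:3, force = c(1e-9, 2e-9, 3e-9),
                             fwhm = c(0.2, 0.2, 0.2),
                             fwhm_flagged = c(FALSE, FALSE, FALSE),
                             rate_to_next = c(1, 1, NA)),
                  class = c("beat_events", "data.frame"))
  s <- summarize_beats(ev)
  expect_equal(s$n_beats, 3L)
  expect_equal(s$force$mean, 2e-9)
  expect_equal(s$force$sd, 1e-9)
  expect_equal(s$force$cv, 0.5)
  expect_equal(s$force$sem, 1e-9 / sqrt(3))
  # single beat: dispersion undefined
  s1 <- summarize_beats(ev[1, ])
  expect_true(is.na(s1$force$sd) && is.na(s1$force$cv))
  # empty input
  s0 <- summarize_beats(ev[0, ])
  expect_equal(s0$n_beats, 0L)
  expect_true(is.na(s0$force$mean))
})

test_that("recovered force CV reflects the generating amplitude CV", {
  cfg <- beat_train_config(duration = 100, beat_rate_mean = 1,
                           amplitude_mean = 1e-9, amplitude_cv = 0.05,
                           seed = 31)
  s <- summarize_beats(detect_beats(simulate_beat_trajectory(cfg)))
  expect_gte(s$force$cv, 0.03)
  expect_lte(s$force$cv, 0.07)
})

test_that("fraction of beats above a rate cutoff", {
  ev <- data.frame(rate_to_next = c(1.0, 1.8, 2.0, 1.5))
  expect_equal(fraction_above_rate(ev, 1.7), 0.5)
  expect_equal(fraction_above_rate(ev, 0.5), 1.0)
  expect_equal(fraction_above_rate(ev, 2.5), 0.0)
  expect_error(fraction_above_rate(data.frame(rate_to_next = NA_real_), 1),
               "no beats")
})

test_that("smoothed histogram is a proper density", {
  set.seed(8)
  v <- rnorm(10000)
  d <- smoothed_histogram(v)
  # integrates to 1
  expect_equal(sum(d$density) * diff(d$x[1:2]), 1, tolerance = 1e-3)
  # density at 0 near the standard normal value
  expect_equal(d$density[which.min(abs(d$x))], 1 / sqrt(2 * pi),
               tolerance = 0.05)
  # shift equivariance
  d2 <- smoothed_histogram(v + 5, bandwidth = bw.nrd0(v))
  expect_equal(d2$density[which.min(abs(d2$x - 5))],
               d$density[which.min(abs(d$x))], tolerance = 1e-6)
  expect_error(smoothed_histogram(rep(1, 5)), "degenerate")
  expect_error(smoothed_histogram(1), "at least 2")
})

test_that("condition comparison: fold change and p-values", {
  mk <- function(forces) data.frame(force = forces,
                                    rate_to_next = rep(1, length(forces)))
  pre <- mk(rep(0.1e-9, 10) + seq(-1e-12, 1e-12, length.out = 10))
  post <- mk(rep(0.26e-9, 10) + seq(-1e-12, 1e-12, length.out = 10))
  cmp <- compare_conditions(pre, post)
  expect_equal(cmp$force_fold_change, 2.6, tolerance = 1e-6)
  expect_lt(cmp$force_p, 1e-10)
  # identical samples: fold change 1, p = 1
  same <- compare_conditions(pre, pre)
  expect_equal(same$force_fold_change, 1)
  expect_gt(same$force_p, 0.99)
  expect_error(compare_conditions(mk(1e-9), post), "at least 2")
})

test_that("Welch p agrees with the permutation p on small synthetic samples", {
  set.seed(41)
  pre <- data.frame(force = rnorm(5, 1e-9, 1e-10), rate_to_next = NA_real_)
  post <- data.frame(force = rnorm(5, 1.5e-9, 1e-10), rate_to_next = NA_real_)
  cmp <- compare_conditions(pre, post, n_perm = 5000, seed = 2)
  expect_lt(abs(cmp$force_p - cmp$force_p_perm), 0.05)
})

test_that("beat metrics are recovered from a noisy train", {
  cfg <- beat_train_config(duration = 120, beat_rate_mean = 1.2,
                           amplitude_mean = 0.5e-9, amplitude_cv = 0.1,
                           fwhm_mean = 0.2, fwhm_cv = 0.05, seed = 77)
  tr <- simulate_beat_trajectory(cfg)
  ev <- detect_beats(tr)
  gt <- tr$meta$ground_truth
  expect_equal(nrow(ev), nrow(gt))
  expect_lt(abs(mean(ev$force) - mean(gt$amplitude)),
            max(0.05 * mean(gt$amplitude), 40e-12))
  expect_lt(abs(mean(ev$rate_to_next, na.rm = TRUE) -
                  mean(1 / diff(gt$t_peak))) / mean(1 / diff(gt$t_peak)), 0.01)
  expect_lt(abs(mean(ev$fwhm[!ev$fwhm_flagged], na.rm = TRUE) - mean(gt$fwhm)),
            2 / 2000)
})
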