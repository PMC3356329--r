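test_that("bootstrap CI: degenerate, geometric-mean and shrinkage behaviour", {
  b <- bootstrap_ci(rep(5, 20), B = 1000, seed = 1)
  expect_equal(c(b$ci_low, b$estimate, b$ci_high), c(5, 5, 5))
  # log transform reports the geometric mean
  bl <- bootstrap_ci(c(10, 1000), B = 1000, seed = 1, transform = "log")
  expect_equal(bl$estimate, 100, tolerance = 1e-9)
  expect_error(bootstrap_ci(c(-1, 2, 3), transform = "log"), "positive")
  expect_error(bootstrap_ci(1:10, B = 50), "B")
  # CI width shrinks with sample size on nested samples
  set.seed(10)
  v <- rnorm(400)
  w100 <- with(bootstrap_ci(v[1:100], B = 2000, seed = 2),
               ci_high - ci_low)
  w400 <- with(bootstrap_ci(v, B = 2000, seed = 2), ci_high - ci_low)
  expect_lt(w400, w100)
  # estimate lies inside its own CI
  bb <- bootstrap_ci(rnorm(50), B = 2000, seed = 3)
  expect_lte(bb$ci_low, bb$estimate)
  expect_gte(bb$ci_high, bb$estimate)
})

test_that("bootstrap CI covers the true mean at the nominal rate", {
  set.seed(20)
  cover <- vapply(1:200, function(i) {
    v <- rnorm(200)
    b <- bootstrap_ci(v, B = 1000, seed = i)
    b$ci_low <= 0 && b$ci_high >= 0
  }, logical(1))
  # binomial 95% band around 0.95 with n = 200
  expect_gt(mean(cover), 0.95 - 1.96 * sqrt(0.95 * 0.05 / 200) - 0.01)
})

test_that("Mann-Whitney: exact small-sample behaviour", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-12)
  expect_equal(mw$method, "exact")
  # identical multisets: p = 1 (tied data fall back to the approximation)
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  # normal approximation close to exact at n = 8 + 8
  set.seed(5)
  x <- rnorm(8); y <- rnorm(8, 0.5)
  p_exact <- mann_whitney(x, y)$p
  p_apx <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE)$p.value)
  expect_lt(abs(p_exact - p_apx), 0.05)
})

test_that("Mann-Whitney exact p matches full enumeration for n1+n2 <= 10", {
  set.seed(6)
  for (n1 in 1:5) {
    for (n2 in n1:(10 - n1)) {
      for (rep in 1:2) {
        v <- sample(seq_len(50), n1 + n2)  # distinct values, no ties
        x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
        expect_equal(mann_whitney(x, y)$p, mann_whitney_enum(x, y),
                     tolerance = 1e-12,
                     info = sprintf("n1=%d n2=%d rep=%d", n1, n2, rep))
      }
    }
  }
})

test_that("2D KS statistic: limits and brute-force agreement", {
  set.seed(7)
  a <- cbind(runif(20), runif(20))
  expect_equal(ks2d_statistic(a, a), 0)
  b <- cbind(runif(20) + 10, runif(20) + 10)
  expect_equal(ks2d_statistic(a, b), 1)
  for (i in 1:25) {
    x <- cbind(rnorm(10), rnorm(10))
    y <- cbind(rnorm(10, 0.5), rnorm(10))
    expect_equal(ks2d_statistic(x, y), ks2d_brute(x, y), tolerance = 1e-12)
  }
  expect_error(ks2d_statistic(a[1:2, ], b), "3 points")
})

test_that("2D KS statistic is invariant to monotone axis-wise rescaling", {
  set.seed(9)
  a <- cbind(rexp(15), rnorm(15))
  b <- cbind(rexp(15, 0.5), rnorm(15, 1))
  d0 <- ks2d_statistic(a, b)
  tr <- function(m) cbind(log(m[, 1] + 1), m[, 2]^3)
  expect_equal(ks2d_statistic(tr(a), tr(b)), d0, tolerance = 1e-12)
})

test_that("2D KS test: permutation and asymptotic p-values", {
  set.seed(11)
  a <- cbind(rnorm(20), rnorm(20))
  b <- cbind(rnorm(20) + 8, rnorm(20) + 8)
  kt <- ks2d_test(a, b, n_perm = 2000, seed = 1)
  expect_equal(kt$D, 1)
  expect_lte(kt$p, 1 / 1000)
  expect_equal(kt$H, 1L)
  # H is 1 exactly when p < alpha
  kt2 <- ks2d_test(a, rbind(a[-1, ], a[1, ] + 0.01), n_perm = 200, seed = 2)
  expect_equal(kt2$H, as.integer(kt2$p < 0.05))
  expect_error(ks2d_test(a, b, n_perm = 50), "n_perm")
  # asymptotic method resolves far smaller p than permutation can
  kta <- ks2d_test(a, b, method = "asymptotic")
  expect_lt(kta$p, 1e-6)
})

test_that("Hill fit recovers EC50", {
  dr <- simulate_dose_response(dose_response_config(noise_cv = 0, seed = 1))
  fit <- fit_hill(dr, boot_B = 0)
  expect_lt(abs(fit$ec50 - 260e-9) / 260e-9, 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-4)
  # response at dose = EC50 is the midpoint of the asymptotes
  mid <- fit$baseline + (fit$max_force - fit$baseline) / 2
  pred <- fit$baseline + (fit$max_force - fit$baseline) /
    (1 + (fit$ec50 / fit$ec50)^fit$hill)
  expect_equal(pred, mid)
  # doubling all doses doubles the fitted EC50
  dr2 <- dr; dr2$dose_M <- dr2$dose_M * 2
  fit2 <- fit_hill(dr2, boot_B = 0)
  expect_equal(fit2$ec50 / fit$ec50, 2, tolerance = 1e-6)
})

test_that("Hill fit errors on unusable designs", {
  dr <- simulate_dose_response(dose_response_config(noise_cv = 0.05, seed = 2))
  few <- dr[dr$dose_M %in% unique(dr$dose_M)[1:3], ]
  expect_error(fit_hill(few), "4 distinct")
  narrow <- dr[dr$dose_M >= 0.9e-7 & dr$dose_M <= 3.3e-6, ]
  expect_error(fit_hill(narrow), "decades")
  flat_cfg <- dose_response_config(baseline_force = 0.49999e-9,
                                   max_force = 0.5e-9, noise_cv = 0.2,
                                   seed = 3)
  expect_error(fit_hill(simulate_dose_response(flat_cfg)), "unidentifiable")
})

test_that("Hill fit bootstrap CI brackets the estimate", {
  dr <- simulate_dose_response(dose_response_config(noise_cv = 0.1,
                                                    beats_per_dose = 20,
                                                    seed = 4))
  fit <- fit_hill(dr, boot_B = 200)
  expect_false(is.null(fit$ec50_ci))
  expect_lte(fit$ec50_ci[1], fit$ec50)
  expect_gte(fit$ec50_ci[2], fit$ec50)
})
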