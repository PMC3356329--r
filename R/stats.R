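#' Nonparametric bootstrap confidence interval for a mean
#'
#' Percentile bootstrap CI of the sample mean, with an optional log
#' transform: `transform = "log"` computes the mean of the log-values and
#' back-transforms both the point estimate and the CI, i.e. it reports the
#' geometric mean — the convention used for right-skewed Young's moduli.
#'
#' @param values numeric vector, n >= 2 (strictly positive when
#'   `transform = "log"`).
#' @param statistic only `"mean"` is supported.
#' @param B number of bootstrap resamples (>= 1000).
#' @param seed integer RNG seed.
#' @param transform `"identity"` or `"log"`.
#' @param conf confidence level (default 0.95).
#' @return A `bootstrap_result` list: `estimate`, `ci_low`, `ci_high`, `B`,
#'   `transform`, `n`, `seed`.
#' @export
bootstrap_ci <- function(values, statistic = "mean", B = 10000, seed = 1L,
                         transform = c("identity", "log"), conf = 0.95) {
  transform <- match.arg(transform)
  statistic <- match.arg(statistic, "mean")
  if (length(values) < 2L) stop("need at least 2 values")
  if (B < 1000L) stop("B must be >= 1000 for stable percentile CIs")
  v <- if (transform == "log") {
    if (any(values <= 0)) stop("log transform requires strictly positive values")
    log(values)
  } else {
    as.numeric(values)
  }
  n <- length(v)
  est <- mean(v)
  boots <- with_seed(seed, {
    idx <- sample.int(n, n * B, replace = TRUE)
    colMeans(matrix(v[idx], nrow = n, ncol = B))
  })
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  if (transform == "log") {
    est <- exp(est); ci <- exp(ci)
  }
  structure(list(estimate = est, ci_low = ci[1], ci_high = ci[2], B = B,
                 transform = transform, n = n, seed = seed, conf = conf),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %s mean = %.4g (%.0f%% CI %.4g .. %.4g, B = %d, n = %d)\n",
              if (x$transform == "log") "geometric" else "arithmetic",
              x$estimate, 100 * x$conf, x$ci_low, x$ci_high, x$B, x$n))
  invisible(x)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided by default. For small samples (n1 + n2 <= 16) without ties the
#' p-value is exact (full enumeration of the rank-sum distribution); with
#' ties or larger samples a normal approximation with midranks and
#' tie-corrected variance is used. Implemented on top of
#' [stats::wilcox.test()], which provides exactly this behaviour.
#'
#' @param x,y numeric samples, both non-empty.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A list: `U` (the Mann-Whitney U statistic for `x` vs `y`), `p`,
#'   `method` (`"exact"` or `"normal_approx"`), `n1`, `n2`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  has_ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 16L) && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal_approx",
       n1 = length(x), n2 = length(y))
}

# Quadrant fractions of `pts` (2-col matrix) around each origin row; strict
# inequalities, so points on either dividing line count in no quadrant.
# Returns a 4 x n_origins matrix of fractions (UR, UL, LL, LR).
.quadrant_fraction_matrix <- function(pts, origins) {
  gx <- outer(pts[, 1], origins[, 1], ">")
  gy <- outer(pts[, 2], origins[, 2], ">")
  lx <- outer(pts[, 1], origins[, 1], "<")
  ly <- outer(pts[, 2], origins[, 2], "<")
  n <- nrow(pts)
  rbind(colSums(gx & gy), colSums(lx & gy),
        colSums(lx & ly), colSums(gx & ly)) / n
}

# max over the four quadrants of |f_a - f_b| over all origins in `origins`
.ks2d_max_diff <- function(a, b, origins) {
  fa <- .quadrant_fraction_matrix(a, origins)
  fb <- .quadrant_fraction_matrix(b, origins)
  max(abs(fa - fb))
}

#' Two-sample two-dimensional Kolmogorov-Smirnov statistic
#'
#' The Fasano-Franceschini statistic for comparing two bivariate point
#' clouds: every data point of each sample in turn is taken as the origin of
#' four quadrants; the statistic of one sample is the maximum over origins
#' and quadrants of the absolute difference between the two samples'
#' quadrant fractions, and D is the average of the two per-sample maxima.
#' Points lying exactly on a dividing line belong to no quadrant.
#'
#' @param a,b two-column numeric matrices (or [mechano_point_set()]s, from
#'   which the (beat force, Young's modulus) columns are taken), each with at
#'   least 3 points.
#' @return The statistic D, between 0 and 1.
#' @export
ks2d_statistic <- function(a, b) {
  a <- .as_xy_matrix(a); b <- .as_xy_matrix(b)
  if (nrow(a) < 3L || nrow(b) < 3L) stop("need at least 3 points per sample")
  d1 <- .ks2d_max_diff(a, b, a)
  d2 <- .ks2d_max_diff(a, b, b)
  (d1 + d2) / 2
}

.as_xy_matrix <- function(x) {
  if (inherits(x, "mechano_point_set")) {
    return(cbind(x$beat_force_N, x$E_Pa))
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("expected 2-column observations")
  storage.mode(x) <- "double"
  x
}

# complementary CDF of the Kolmogorov distribution, Q_KS(lambda)
.q_ks <- function(lambda) {
  if (lambda < 1e-3) return(1)
  j <- seq_len(100)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, .Machine$double.xmin), 1)
}

#' Two-sample 2D Kolmogorov-Smirnov test
#'
#' Tests whether two bivariate samples (e.g. the (beat force, modulus) point
#' clouds of two dwell maps) come from the same continuous distribution,
#' using the statistic of [ks2d_statistic()].
#'
#' Two p-values are available. `"permutation"` (default) pools the
#' observations, reshuffles the labels `n_perm` times and reports
#' `(1 + #\{D* >= D_obs\}) / (1 + n_perm)` — defensible at any sample size but
#' bounded below by `1/(1 + n_perm)`. `"asymptotic"` uses the
#' correlation-corrected Kolmogorov tail formula of Press et al., which can
#' resolve arbitrarily small p-values but is approximate at small n.
#'
#' @param a,b point sets as in [ks2d_statistic()].
#' @param method `"permutation"` or `"asymptotic"`.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed for the permutation test.
#' @param alpha significance level for the reject indicator.
#' @return A `ks2d_result` list: `D`, `p`, `H` (1 if `p < alpha`), `method`,
#'   `n1`, `n2`, `n_perm`, `seed`.
#' @export
ks2d_test <- function(a, b, method = c("permutation", "asymptotic"),
                      n_perm = 10000, seed = 1L, alpha = 0.05) {
  method <- match.arg(method)
  a <- .as_xy_matrix(a); b <- .as_xy_matrix(b)
  D <- ks2d_statistic(a, b)
  n1 <- nrow(a); n2 <- nrow(b)
  if (method == "permutation") {
    if (n_perm < 100) stop("n_perm must be >= 100")
    pool <- rbind(a, b)
    n_tot <- n1 + n2
    p <- with_seed(seed, {
      exceed <- 0L
      for (i in seq_len(n_perm)) {
        idx <- sample.int(n_tot, n1)
        d_star <- ks2d_statistic(pool[idx, , drop = FALSE],
                                 pool[-idx, , drop = FALSE])
        if (d_star >= D - 1e-12) exceed <- exceed + 1L
      }
      (1 + exceed) / (1 + n_perm)
    })
  } else {
    # Press et al. correlation-corrected 2D KS tail probability
    r1 <- stats::cor(a[, 1], a[, 2])
    r2 <- stats::cor(b[, 1], b[, 2])
    if (!is.finite(r1)) r1 <- 0
    if (!is.finite(r2)) r2 <- 0
    rr <- sqrt(1 - 0.5 * (r1^2 + r2^2))
    n_eff <- n1 * n2 / (n1 + n2)
    lambda <- sqrt(n_eff) * D / (1 + rr * (0.25 - 0.75 / sqrt(n_eff)))
    p <- .q_ks(lambda)
  }
  structure(list(D = D, p = p, H = as.integer(p < alpha), method = method,
                 n1 = n1, n2 = n2,
                 n_perm = if (method == "permutation") n_perm else NA_integer_,
                 seed = seed, alpha = alpha),
            class = "ks2d_result")
}

#' @export
print.ks2d_result <- function(x, ...) {
  cat(sprintf("<ks2d_result> D = %.4f, p = %.3g (%s), H = %d (n = %d + %d)\n",
              x$D, x$p, x$method, x$H, x$n1, x$n2))
  invisible(x)
}

#' Fit a Hill dose-response curve and estimate EC50
#'
#' Least-squares fit of
#' `F(dose) = baseline + (max - baseline) / (1 + (EC50/dose)^h)`
#' to per-beat forces across an agonist dose ladder, parameterised in
#' log(EC50) for stability. Optionally the Hill coefficient is fixed. The
#' EC50 confidence interval comes from a case-resampling bootstrap
#' stratified by dose.
#'
#' @param series data.frame with columns `dose_M` (mol/L) and `force_N` (N),
#'   e.g. from [simulate_dose_response()]; needs at least 4 distinct doses
#'   spanning at least 2 decades.
#' @param fix_hill optional fixed Hill coefficient (e.g. 1).
#' @param boot_B bootstrap resamples for the EC50 CI (0 skips the CI).
#' @param seed RNG seed for the bootstrap.
#' @return A `hill_fit` list: `ec50` (mol/L), `hill`, `baseline` (N),
#'   `max_force` (N), `residual_rms`, `ec50_ci` (or NULL), `n`.
#' @export
fit_hill <- function(series, fix_hill = NULL, boot_B = 1000, seed = 1L) {
  stopifnot(is.data.frame(series), all(c("dose_M", "force_N") %in% names(series)))
  dose <- series$dose_M; f <- series$force_N
  ud <- sort(unique(dose))
  if (length(ud) < 4L) stop("need at least 4 distinct doses")
  if (log10(max(ud) / min(ud)) < 2) stop("doses must span at least 2 decades")
  mu_by_dose <- tapply(f, dose, mean)
  base0 <- mu_by_dose[[1]]
  max0 <- mu_by_dose[[length(mu_by_dose)]]
  # identifiability screen: response swing must exceed twice the noise scale
  sd_by_dose <- tapply(f, dose, stats::sd)
  noise <- stats::median(sd_by_dose, na.rm = TRUE)
  if (is.finite(noise) && noise > 0 && abs(max0 - base0) < 2 * noise) {
    stop("unidentifiable EC50: response range indistinguishable from noise")
  }
  mid <- (base0 + max0) / 2
  ec50_0 <- ud[which.min(abs(mu_by_dose - mid))]

  .fit_once <- function(dose, f) {
    dat <- data.frame(dose = dose, f = f)
    ctrl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                       maxiter = 500)
    if (is.null(fix_hill)) {
      fit <- minpack.lm::nlsLM(
        f ~ base + (fmax - base) / (1 + exp(h * (lec - log(dose)))),
        data = dat,
        start = list(base = base0, fmax = max0, lec = log(ec50_0), h = 1),
        control = ctrl)
    } else {
      h_fixed <- fix_hill
      fit <- minpack.lm::nlsLM(
        f ~ base + (fmax - base) / (1 + exp(h_fixed * (lec - log(dose)))),
        data = dat,
        start = list(base = base0, fmax = max0, lec = log(ec50_0)),
        control = ctrl)
    }
    cf <- stats::coef(fit)
    list(ec50 = exp(unname(cf["lec"])),
         hill = if (is.null(fix_hill)) unname(cf["h"]) else fix_hill,
         baseline = unname(cf["base"]), max_force = unname(cf["fmax"]),
         residual_rms = sqrt(mean(stats::resid(fit)^2)))
  }
  est <- .fit_once(dose, f)
  if (est$max_force <= est$baseline) {
    warning("fitted maximum does not exceed baseline; EC50 unreliable")
  }
  ec50_ci <- NULL
  if (boot_B > 0) {
    by_dose <- split(seq_along(dose), dose)
    boots <- with_seed(seed, vapply(seq_len(boot_B), function(b) {
      idx <- unlist(lapply(by_dose, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]),
        use.names = FALSE)
      out <- tryCatch(.fit_once(dose[idx], f[idx])$ec50,
                      error = function(e) NA_real_)
      out
    }, numeric(1)))
    boots <- boots[is.finite(boots)]
    if (length(boots) >= 100) {
      ec50_ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
    }
  }
  structure(c(est, list(ec50_ci = ec50_ci, n = length(f))),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> EC50 = %.4g mol/L (h = %.3g), response %.3g -> %.3g nN\n",
              x$ec50, x$hill, x$baseline * 1e9, x$max_force * 1e9))
  if (!is.null(x$ec50_ci)) {
    cat(sprintf("  EC50 95%% CI: %.4g .. %.4g mol/L\n", x$ec50_ci[1], x$ec50_ci[2]))
  }
  invisible(x)
}
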