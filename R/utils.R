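# Internal helpers shared across modules.

# Boltzmann constant, J/K (2019 SI exact value).
.kB <- 1.380649e-23

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. Generators must be bit-reproducible given (config, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_if_not_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (if (strict) x <= 0 else x < 0)) {
    stop(sprintf("`%s` must be a single finite %s number, got %s",
                 name, if (strict) "positive" else "non-negative",
                 deparse(substitute(x))), call. = FALSE)
  }
  invisible(x)
}

# Gaussian smoothing by direct FIR convolution (kernel truncated at 4 sigma).
# sigma_samples = 0 returns the input unchanged. Edges use renormalised
# partial kernels so the baseline is not dragged toward zero.
gaussian_smooth <- function(x, sigma_samples) {
  if (sigma_samples <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_samples))
  k <- stats::dnorm(seq(-half, half), sd = sigma_samples)
  k <- k / sum(k)
  n <- length(x)
  # filter() leaves NA at the edges; fill them with renormalised kernels
  y <- stats::filter(x, k, method = "convolution", sides = 2)
  y <- as.numeric(y)
  idx <- which(is.na(y))
  for (i in idx) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    kk <- k[(lo - i + half + 1L):(hi - i + half + 1L)]
    y[i] <- sum(x[lo:hi] * kk) / sum(kk)
  }
  y
}

# Noise attenuation factor of the smoothing kernel: sd(smoothed white noise)
# = factor * sd(raw noise). Equals sqrt(sum(w^2)) for normalised weights w.
gaussian_smooth_noise_factor <- function(sigma_samples) {
  if (sigma_samples <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma_samples))
  k <- stats::dnorm(seq(-half, half), sd = sigma_samples)
  k <- k / sum(k)
  sqrt(sum(k^2))
}

# Rolling lower-percentile estimate via overlapping blocks + linear
# interpolation. Exact sliding windows are O(n * w); block centres every
# window/4 samples give the same envelope to well within the tolerance of
# any downstream use while staying O(n).
rolling_percentile <- function(x, window_samples, prob) {
  n <- length(x)
  w <- min(as.integer(window_samples), n)
  if (w >= n) return(rep(stats::quantile(x, prob, names = FALSE), n))
  stride <- max(1L, w %/% 4L)
  starts <- seq(1L, n - w + 1L, by = stride)
  if (starts[length(starts)] < n - w + 1L) starts <- c(starts, n - w + 1L)
  centers <- starts + (w - 1) / 2
  q <- vapply(starts, function(s) {
    stats::quantile(x[s:(s + w - 1L)], prob, names = FALSE)
  }, numeric(1))
  stats::approx(centers, q, xout = seq_len(n), rule = 2)$y
}

# full width at half maximum of a Gaussian with unit sd
.fwhm_gauss <- 2 * sqrt(2 * log(2))
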