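# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use the most direct (and slowest)
# formulation of each definition.

# Two-sample 2D KS statistic, direct definition: explicit loops over every
# origin and quadrant.
ks2d_brute <- function(a, b) {
  quad_frac <- function(pts, x0, y0) {
    f <- c(0, 0, 0, 0)
    for (i in seq_len(nrow(pts))) {
      x <- pts[i, 1]; y <- pts[i, 2]
      if (x > x0 && y > y0) f[1] <- f[1] + 1
      else if (x < x0 && y > y0) f[2] <- f[2] + 1
      else if (x < x0 && y < y0) f[3] <- f[3] + 1
      else if (x > x0 && y < y0) f[4] <- f[4] + 1
    }
    f / nrow(pts)
  }
  max_over <- function(origins) {
    d <- 0
    for (i in seq_len(nrow(origins))) {
      fa <- quad_frac(a, origins[i, 1], origins[i, 2])
      fb <- quad_frac(b, origins[i, 1], origins[i, 2])
      d <- max(d, max(abs(fa - fb)))
    }
    d
  }
  (max_over(a) + max_over(b)) / 2
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(n1+n2, n1) group labelings (no ties allowed).
mann_whitney_enum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  stopifnot(!anyDuplicated(pool))
  u_stat <- function(xi, yi) sum(outer(xi, yi, ">"))
  u_obs <- u_stat(x, y)
  labelings <- utils::combn(n1 + n2, n1)
  u_all <- apply(labelings, 2, function(idx) u_stat(pool[idx], pool[-idx]))
  m <- n1 * n2 / 2
  if (u_obs <= m) {
    p <- 2 * mean(u_all <= u_obs)
  } else {
    p <- 2 * mean(u_all >= u_obs)
  }
  min(p, 1)
}

# Direct O(n * w) sliding-window percentile (centred windows, truncated at
# the edges).
rolling_percentile_direct <- function(x, w, prob) {
  n <- length(x)
  half <- (w - 1) / 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, ceiling(i - half)); hi <- min(n, floor(i + half))
    stats::quantile(x[lo:hi], prob, names = FALSE)
  }, numeric(1))
}

# Pure-noise force trajectory (no beats) at the instrument's nominal scales.
noise_trajectory <- function(duration = 120, fs = 2000, noise_sd = 20e-12,
                             seed = 1) {
  n <- duration * fs
  set.seed(seed)
  force_trajectory((seq_len(n) - 1) / fs, rnorm(n, 0, noise_sd), fs)
}

# Study conditions for beat-train parameter-recovery sweeps: amplitudes and
# rates span the ranges reported for stem-cell-derived cardiomyocytes, and
# the beat duration is capped at 30% of the cycle length (contraction
# occupies a minority of the beat cycle).
draw_beat_conditions <- function(n, seed) {
  set.seed(seed)
  data.frame(
    amplitude = runif(n, 0.1e-9, 2.5e-9),
    rate = rate <- runif(n, 0.5, 2),
    fwhm = vapply(rate, function(r) runif(1, 0.15, min(0.3, 0.3 / r)),
                  numeric(1)),
    seed = sample.int(1e6, n)
  )
}
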