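#' Configuration for a simulated beat train
#'
#' Describes a spontaneously beating cardiomyocyte as seen by a stationary
#' AFM cantilever: a train of contraction peaks riding on a flat (optionally
#' drifting) baseline with additive Gaussian instrument noise. Defaults follow
#' typical instrument settings for this kind of recording: 2 kHz acquisition
#' and about 20 pN of force noise.
#'
#' Peaks are asymmetric by default — a fast upstroke and slower relaxation —
#' modelled as a two-sided Gaussian whose rise and decay standard deviations
#' are 0.35 and 0.65 of twice the FWHM-equivalent sigma, so the nominal FWHM
#' is preserved. `peak_shape = "gaussian"` gives the symmetric closed form
#' used in analytic tests.
#'
#' @param duration recording length, s.
#' @param sampling_rate acquisition rate, Hz.
#' @param beat_rate_mean mean beat rate, beats/s.
#' @param beat_rate_cv coefficient of variation of inter-beat intervals.
#' @param amplitude_mean mean peak force above baseline, N.
#' @param amplitude_cv coefficient of variation of peak amplitudes.
#' @param fwhm_mean mean beat duration (full width at half maximum), s.
#' @param fwhm_cv coefficient of variation of FWHM.
#' @param peak_shape `"asymmetric"` (default) or `"gaussian"`.
#' @param noise_sd additive Gaussian force noise SD, N.
#' @param baseline_drift_amplitude amplitude of a slow sinusoid-plus-ramp
#'   baseline drift, N (default 0: equilibrated cantilever).
#' @param baseline_force constant resting force offset, N.
#' @param seed integer RNG seed.
#' @return A `beat_train_config` list.
#' @export
beat_train_config <- function(duration = 120, sampling_rate = 2000,
                              beat_rate_mean = 1, beat_rate_cv = 0.05,
                              amplitude_mean = 1e-9, amplitude_cv = 0.1,
                              fwhm_mean = 0.2, fwhm_cv = 0.05,
                              peak_shape = c("asymmetric", "gaussian"),
                              noise_sd = 20e-12,
                              baseline_drift_amplitude = 0,
                              baseline_force = 0,
                              seed = 1L) {
  peak_shape <- match.arg(peak_shape)
  stop_if_not_scalar_pos(duration, "duration")
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  stop_if_not_scalar_pos(beat_rate_mean, "beat_rate_mean")
  stop_if_not_scalar_pos(amplitude_mean, "amplitude_mean")
  stop_if_not_scalar_pos(fwhm_mean, "fwhm_mean")
  stop_if_not_scalar_pos(noise_sd, "noise_sd", strict = FALSE)
  if (beat_rate_cv < 0 || amplitude_cv < 0 || fwhm_cv < 0) {
    stop("coefficients of variation must be >= 0")
  }
  if (sampling_rate * fwhm_mean < 10) {
    stop("peaks not resolvable: sampling_rate * fwhm_mean must be >= 10 samples")
  }
  structure(list(duration = duration, sampling_rate = sampling_rate,
                 beat_rate_mean = beat_rate_mean, beat_rate_cv = beat_rate_cv,
                 amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv,
                 fwhm_mean = fwhm_mean, fwhm_cv = fwhm_cv,
                 peak_shape = peak_shape, noise_sd = noise_sd,
                 baseline_drift_amplitude = baseline_drift_amplitude,
                 baseline_force = baseline_force, seed = seed),
            class = "beat_train_config")
}

# Evaluate one beat peak (unit amplitude) at times t relative to the peak.
# Asymmetric: half-Gaussians with sd sigma_rise (t < 0) and sigma_decay
# (t >= 0); both halves reach 1 at t = 0, so FWHM = (s_r + s_d)*sqrt(2 log 2).
.peak_shape_eval <- function(t, fwhm, shape) {
  if (shape == "gaussian") {
    s <- fwhm / .fwhm_gauss
    exp(-t^2 / (2 * s^2))
  } else {
    s_eq <- fwhm / .fwhm_gauss
    s_r <- 2 * 0.35 * s_eq
    s_d <- 2 * 0.65 * s_eq
    ifelse(t < 0, exp(-t^2 / (2 * s_r^2)), exp(-t^2 / (2 * s_d^2)))
  }
}

#' Simulate a cardiomyocyte beat trajectory
#'
#' Generates a force-vs-time series with beats drawn from the configured
#' amplitude / interval / width distributions, plus additive Gaussian noise
#' and optional baseline drift. Ground-truth beat times, amplitudes and widths
#' are attached as `meta$ground_truth` so downstream detection can be checked
#' by parameter recovery.
#'
#' Inter-beat intervals are normal with mean `1/beat_rate_mean` and CV
#' `beat_rate_cv`, truncated at 40% of the mean to keep them positive;
#' amplitudes and widths are likewise truncated normals.
#'
#' @param config a [beat_train_config()].
#' @return A [force_trajectory()] whose `meta` holds the generating config and
#'   a `ground_truth` data.frame (`t_peak`, `amplitude`, `fwhm`).
#' @export
simulate_beat_trajectory <- function(config) {
  stopifnot(inherits(config, "beat_train_config"))
  n <- round(config$duration * config$sampling_rate)
  dt <- 1 / config$sampling_rate
  time <- (seq_len(n) - 1L) * dt
  with_seed(config$seed, {
    mu_int <- 1 / config$beat_rate_mean
    # draw more intervals than can fit, then truncate to the duration
    n_max <- ceiling(config$duration / mu_int * 2) + 10L
    ints <- stats::rnorm(n_max, mu_int, config$beat_rate_cv * mu_int)
    ints <- pmax(ints, 0.4 * mu_int)
    t_peaks <- 0.5 * mu_int + cumsum(c(0, ints))
    t_peaks <- t_peaks[t_peaks < config$duration - 0.5 * config$fwhm_mean]
    nb <- length(t_peaks)
    amps <- pmax(stats::rnorm(nb, config$amplitude_mean,
                              config$amplitude_cv * config$amplitude_mean),
                 0.05 * config$amplitude_mean)
    fwhms <- pmax(stats::rnorm(nb, config$fwhm_mean,
                               config$fwhm_cv * config$fwhm_mean),
                  0.3 * config$fwhm_mean)
    force <- rep(config$baseline_force, n)
    for (i in seq_len(nb)) {
      # evaluate each peak only on a +-4 FWHM support window
      halfwin <- 4 * fwhms[i]
      lo <- max(1L, floor((t_peaks[i] - halfwin) / dt) + 1L)
      hi <- min(n, ceiling((t_peaks[i] + halfwin) / dt) + 1L)
      idx <- lo:hi
      force[idx] <- force[idx] +
        amps[i] * .peak_shape_eval(time[idx] - t_peaks[i], fwhms[i],
                                   config$peak_shape)
    }
    if (config$baseline_drift_amplitude != 0) {
      a <- config$baseline_drift_amplitude
      force <- force + a * sin(2 * pi * time / max(30, config$duration / 2)) +
        a * time / config$duration
    }
    if (config$noise_sd > 0) force <- force + stats::rnorm(n, 0, config$noise_sd)
    gt <- data.frame(t_peak = t_peaks, amplitude = amps, fwhm = fwhms)
    force_trajectory(time, force, config$sampling_rate,
                     meta = list(config = config, ground_truth = gt))
  })
}

#' Simulate thermal fluctuations of a free cantilever
#'
#' White Gaussian deflection noise whose variance obeys the equipartition
#' theorem, var(d) = kB * T / k. This is the series a thermal-noise spring
#' constant calibration consumes.
#'
#' @param spring_constant cantilever spring constant, N/m.
#' @param temperature bath temperature, K. `0` yields an all-zero series.
#' @param duration length of the series, s.
#' @param sampling_rate sampling rate, Hz.
#' @param seed integer RNG seed.
#' @return A [deflection_trajectory()] in metres.
#' @export
simulate_thermal_noise <- function(spring_constant, temperature = 310,
                                   duration = 60, sampling_rate = 2000,
                                   seed = 1L) {
  stop_if_not_scalar_pos(spring_constant, "spring_constant")
  stop_if_not_scalar_pos(temperature, "temperature", strict = FALSE)
  n <- round(duration * sampling_rate)
  time <- (seq_len(n) - 1L) / sampling_rate
  sd_d <- sqrt(.kB * temperature / spring_constant)
  d <- if (sd_d > 0) with_seed(seed, stats::rnorm(n, 0, sd_d)) else numeric(n)
  deflection_trajectory(time, d, sampling_rate,
                        meta = list(spring_constant = spring_constant,
                                    temperature = temperature, seed = seed))
}

#' Configuration for a simulated Hertzian approach curve
#'
#' @param E_true Young's modulus of the sample, Pa.
#' @param nu Poisson's ratio (0.5 for an incompressible cell).
#' @param geometry indenter geometry: `"cone"`, `"sphere"` or `"pyramid"`.
#' @param tip_half_angle half-opening angle in degrees (cone / pyramid).
#' @param tip_radius tip radius in metres (sphere).
#' @param contact_point z position of tip-sample contact, m.
#' @param max_indentation deepest indentation sampled, m.
#' @param spring_constant cantilever spring constant, N/m.
#' @param noise_sd_deflection additive deflection noise SD, m.
#' @param n_points samples along the approach; the default matches a 2 kHz
#'   acquisition over a ~1 s approach sweep.
#' @param pre_contact_fraction fraction of the z range before contact.
#' @param seed integer RNG seed.
#' @return A `hertz_curve_config` list.
#' @export
hertz_curve_config <- function(E_true = 300, nu = 0.5,
                               geometry = c("cone", "sphere", "pyramid"),
                               tip_half_angle = 35, tip_radius = NULL,
                               contact_point = 1e-6, max_indentation = 400e-9,
                               spring_constant = 0.04,
                               noise_sd_deflection = 0, n_points = 2000,
                               pre_contact_fraction = 0.3, seed = 1L) {
  geometry <- match.arg(geometry)
  stop_if_not_scalar_pos(E_true, "E_true")
  if (nu < 0 || nu > 0.5) stop("nu must lie in [0, 0.5]")
  stop_if_not_scalar_pos(max_indentation, "max_indentation")
  stop_if_not_scalar_pos(spring_constant, "spring_constant")
  if (geometry == "sphere") {
    if (is.null(tip_radius)) stop("sphere geometry requires tip_radius")
    tip_param <- tip_radius
  } else {
    if (is.null(tip_half_angle)) stop(geometry, " geometry requires tip_half_angle")
    tip_param <- tip_half_angle
  }
  if (pre_contact_fraction < 0.05 || pre_contact_fraction > 0.9) {
    stop("pre_contact_fraction must lie in [0.05, 0.9]")
  }
  structure(list(E_true = E_true, nu = nu, geometry = geometry,
                 tip_param = tip_param, contact_point = contact_point,
                 max_indentation = max_indentation,
                 spring_constant = spring_constant,
                 noise_sd_deflection = noise_sd_deflection,
                 n_points = as.integer(n_points),
                 pre_contact_fraction = pre_contact_fraction, seed = seed),
            class = "hertz_curve_config")
}

#' Simulate an AFM approach (indentation) curve
#'
#' Before the contact point the deflection is flat (noise only); beyond it,
#' force follows the geometry's Hertz law of the true indentation
#' `delta = (z - z_c) - d`, where the deflection `d = F/k` is solved
#' self-consistently at every z so that the generated curve is exactly what a
#' soft cantilever records on a Hertzian sample.
#'
#' @param config a [hertz_curve_config()].
#' @return A [force_curve()] with ground truth in `meta`.
#' @export
simulate_force_curve <- function(config) {
  stopifnot(inherits(config, "hertz_curve_config"))
  k <- config$spring_constant
  # z travel past contact = indentation + deflection at max indentation
  F_max <- hertz_force(config$max_indentation, config$E_true, config$geometry,
                       config$tip_param, config$nu)
  z_post <- config$max_indentation + F_max / k
  z_pre <- z_post * config$pre_contact_fraction / (1 - config$pre_contact_fraction)
  z <- seq(config$contact_point - z_pre, config$contact_point + z_post,
           length.out = config$n_points)
  d <- numeric(config$n_points)
  post <- z > config$contact_point
  if (any(post)) {
    u <- z[post] - config$contact_point
    C <- hertz_prefactor(config$E_true, config$geometry, config$tip_param,
                         config$nu)
    if (config$geometry == "sphere") {
      # solve k d = C (u - d)^{3/2} by vectorised Newton iteration; g is
      # convex in d, so iterates from d = 0 converge monotonically
      di <- numeric(length(u))
      for (it in seq_len(60)) {
        g <- k * di - C * (u - di)^1.5
        gp <- k + 1.5 * C * sqrt(u - di)
        step <- g / gp
        di <- pmin(pmax(di - step, 0), u)
        if (max(abs(step)) < 1e-18) break
      }
      d[post] <- di
    } else {
      # k d = C (u - d)^2 is quadratic in d; the smaller root lies in [0, u]
      b <- 2 * C * u + k
      d[post] <- (b - sqrt(b^2 - 4 * C^2 * u^2)) / (2 * C)
    }
  }
  if (config$noise_sd_deflection > 0) {
    d <- d + with_seed(config$seed,
                       stats::rnorm(length(d), 0, config$noise_sd_deflection))
  }
  force_curve(z, d, k, meta = list(config = config,
                                   contact_point_true = config$contact_point,
                                   E_true = config$E_true))
}

#' Configuration for a simulated dwell map
#'
#' A grid scan over a cell: each point carries one approach curve and one
#' dwell trajectory. On-cell points draw their generating (beat force, Young's
#' modulus) from a mixture of components — one component emulates a healthy
#' cell's single population, two well-separated components emulate the bimodal
#' pattern seen in dilated-cardiomyopathy cells. Off-cell (glass) points are
#' stiff and beat-free.
#'
#' Each mixture component is a list with elements `weight`, `force_mean` (N),
#' `force_cv`, `logE_mean` (mean of log(E/Pa)), `logE_sd`.
#'
#' @param n_rows,n_cols grid size (10-30 each is typical).
#' @param spacing grid pitch, m.
#' @param cell_mask logical `n_rows x n_cols` matrix, `TRUE` on the cell;
#'   `NULL` for the default inscribed ellipse covering ~55% of the grid.
#' @param components list of mixture components (see Details).
#' @param beat_rate_mean,beat_rate_cv beat rate distribution at beating points.
#' @param fwhm_mean mean beat FWHM, s.
#' @param dwell_duration dwell length per point, s.
#' @param sampling_rate Hz.
#' @param noise_sd force noise during dwells, N.
#' @param glass_E Young's modulus reported on glass points, Pa (effectively
#'   rigid compared with the cell).
#' @param spring_constant N/m.
#' @param geometry,tip_half_angle indenter model used for curve generation.
#' @param height_cell,height_sd cell height field mean and SD, m.
#' @param curve_n_points samples per approach curve.
#' @param curve_noise_sd_deflection deflection noise on curves, m.
#' @param seed integer RNG seed.
#' @return A `dwell_map_config` list.
#' @export
dwell_map_config <- function(n_rows = 15, n_cols = 15, spacing = 2e-6,
                             cell_mask = NULL,
                             components = list(list(weight = 1,
                                                    force_mean = 1.35e-9,
                                                    force_cv = 0.25,
                                                    logE_mean = log(296),
                                                    logE_sd = 0.5)),
                             beat_rate_mean = 1, beat_rate_cv = 0.05,
                             fwhm_mean = 0.2, dwell_duration = 10,
                             sampling_rate = 2000, noise_sd = 20e-12,
                             glass_E = 5e4, spring_constant = 0.04,
                             geometry = "cone", tip_half_angle = 35,
                             height_cell = 4e-6, height_sd = 0.5e-6,
                             curve_n_points = 400,
                             curve_noise_sd_deflection = 0.2e-9,
                             seed = 1L) {
  if (n_rows < 2 || n_cols < 2) stop("grid must be at least 2 x 2")
  if (is.null(cell_mask)) {
    r <- (seq_len(n_rows) - (n_rows + 1) / 2) / (n_rows / 2)
    c_ <- (seq_len(n_cols) - (n_cols + 1) / 2) / (n_cols / 2)
    cell_mask <- outer(r, c_, function(a, b) a^2 + b^2 <= 0.85^2)
  }
  if (!is.matrix(cell_mask) || !identical(dim(cell_mask), c(as.integer(n_rows), as.integer(n_cols)))) {
    stop("cell_mask must be an n_rows x n_cols logical matrix")
  }
  if (!any(cell_mask)) stop("cell_mask is empty: no on-cell points")
  w <- vapply(components, `[[`, numeric(1), "weight")
  if (any(w < 0)) stop("mixture weights must be >= 0")
  if (abs(sum(w) - 1) > 1e-8) stop("mixture weights must sum to 1")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 spacing = spacing, cell_mask = cell_mask,
                 components = components, beat_rate_mean = beat_rate_mean,
                 beat_rate_cv = beat_rate_cv, fwhm_mean = fwhm_mean,
                 dwell_duration = dwell_duration,
                 sampling_rate = sampling_rate, noise_sd = noise_sd,
                 glass_E = glass_E, spring_constant = spring_constant,
                 geometry = geometry, tip_half_angle = tip_half_angle,
                 height_cell = height_cell, height_sd = height_sd,
                 curve_n_points = as.integer(curve_n_points),
                 curve_noise_sd_deflection = curve_noise_sd_deflection,
                 seed = seed),
            class = "dwell_map_config")
}

#' Preset dwell-map configurations: healthy-like and DCM-like cells
#'
#' `dwell_map_config_healthy()` is a single-population cell at the scale of a
#' healthy control (mean beat force ~1.35 nN, geometric-mean modulus ~296 Pa).
#' `dwell_map_config_dcm()` mixes a near-normal component with a low-force /
#' low-modulus component, reproducing the bimodal joint distribution typical
#' of dilated-cardiomyopathy cardiomyocytes.
#'
#' @param ... overrides passed on to [dwell_map_config()].
#' @return A `dwell_map_config`.
#' @export
dwell_map_config_healthy <- function(...) {
  dwell_map_config(components = list(list(weight = 1, force_mean = 1.35e-9,
                                          force_cv = 0.25,
                                          logE_mean = log(296),
                                          logE_sd = 0.5)), ...)
}

#' @rdname dwell_map_config_healthy
#' @export
dwell_map_config_dcm <- function(...) {
  dwell_map_config(components = list(
    list(weight = 0.5, force_mean = 0.85e-9, force_cv = 0.2,
         logE_mean = log(280), logE_sd = 0.4),
    list(weight = 0.5, force_mean = 0.25e-9, force_cv = 0.2,
         logE_mean = log(90), logE_sd = 0.4)), ...)
}

#' Simulate a raw dwell map
#'
#' Generates, for every grid point, one approach curve and one dwell
#' trajectory. On-cell points draw a mixture component, a per-point modulus
#' (log-normal) and a per-point mean beat force; glass points get stiff
#' curves, zero height and beat-free dwells. Ground truth (component label,
#' true E, true mean force, height) is returned alongside.
#'
#' @param config a [dwell_map_config()].
#' @return A `dwell_map_raw` list: `points` (list of lists with `row`, `col`,
#'   `x`, `y`, `curve`, `dwell`), `ground_truth` data.frame, `config`.
#' @export
simulate_dwell_map <- function(config) {
  stopifnot(inherits(config, "dwell_map_config"))
  nr <- config$n_rows; nc <- config$n_cols
  grid <- expand.grid(row = seq_len(nr) - 1L, col = seq_len(nc) - 1L)
  grid <- grid[order(grid$row, grid$col), ]
  npts <- nrow(grid)
  w <- vapply(config$components, `[[`, numeric(1), "weight")
  with_seed(config$seed, {
    # per-point sub-seeds keep each point reproducible yet distinct
    sub_seeds <- sample.int(.Machine$integer.max, 2L * npts)
    points <- vector("list", npts)
    gt <- data.frame(row = grid$row, col = grid$col,
                     on_cell = FALSE, component = NA_integer_,
                     E_true = NA_real_, force_true = NA_real_,
                     height_true = NA_real_)
    for (i in seq_len(npts)) {
      r <- grid$row[i]; c_ <- grid$col[i]
      on_cell <- config$cell_mask[r + 1L, c_ + 1L]
      if (on_cell) {
        comp_i <- sample.int(length(w), 1L, prob = w)
        comp <- config$components[[comp_i]]
        E_i <- exp(stats::rnorm(1, comp$logE_mean, comp$logE_sd))
        f_i <- pmax(stats::rnorm(1, comp$force_mean,
                                 comp$force_cv * comp$force_mean),
                    0.1 * comp$force_mean)
        h_i <- pmax(stats::rnorm(1, config$height_cell, config$height_sd),
                    0.5e-6)
        n_beats_cfg <- beat_train_config(
          duration = config$dwell_duration,
          sampling_rate = config$sampling_rate,
          beat_rate_mean = config$beat_rate_mean,
          beat_rate_cv = config$beat_rate_cv,
          amplitude_mean = f_i, amplitude_cv = 0.05,
          fwhm_mean = config$fwhm_mean, fwhm_cv = 0.05,
          noise_sd = config$noise_sd, seed = sub_seeds[2L * i - 1L])
        dwell <- simulate_beat_trajectory(n_beats_cfg)
      } else {
        comp_i <- NA_integer_
        E_i <- config$glass_E
        f_i <- 0
        h_i <- 0
        n <- round(config$dwell_duration * config$sampling_rate)
        tvec <- (seq_len(n) - 1L) / config$sampling_rate
        noise <- with_seed(sub_seeds[2L * i - 1L],
                           stats::rnorm(n, 0, config$noise_sd))
        dwell <- force_trajectory(tvec, noise, config$sampling_rate)
      }
      # contact point encodes local height: taller cell -> earlier contact
      zc_i <- 2e-6 + (config$height_cell + 2e-6 - h_i)
      # approach until the 100 pN force trigger: indentation depth adapts to
      # the local stiffness, exactly as the instrument's trigger does
      delta_trig <- (100e-12 / hertz_prefactor(E_i, config$geometry,
                                               config$tip_half_angle))^
        (1 / hertz_exponent(config$geometry))
      curve <- simulate_force_curve(hertz_curve_config(
        E_true = E_i, geometry = config$geometry,
        tip_half_angle = config$tip_half_angle,
        contact_point = zc_i,
        max_indentation = delta_trig,
        spring_constant = config$spring_constant,
        noise_sd_deflection = config$curve_noise_sd_deflection,
        n_points = config$curve_n_points, seed = sub_seeds[2L * i]))
      points[[i]] <- list(row = r, col = c_,
                          x = c_ * config$spacing, y = r * config$spacing,
                          curve = curve, dwell = dwell)
      gt$on_cell[i] <- on_cell
      gt$component[i] <- comp_i
      gt$E_true[i] <- E_i
      gt$force_true[i] <- f_i
      gt$height_true[i] <- h_i
    }
    structure(list(points = points, ground_truth = gt, config = config),
              class = "dwell_map_raw")
  })
}

#' Configuration for a simulated dose-response series
#'
#' Beat forces under increasing agonist dose following a Hill curve:
#' `F(dose) = baseline + (max - baseline) * dose^h / (dose^h + EC50^h)`,
#' with multiplicative Gaussian noise per beat. The default ladder spans
#' 10 nmol/L to 32 umol/L in half-decade steps.
#'
#' @param doses vector of doses, mol/L, strictly positive and increasing.
#' @param ec50_true half-maximal dose, mol/L.
#' @param hill_coefficient Hill slope.
#' @param baseline_force beat force at zero dose, N.
#' @param max_force saturating beat force, N.
#' @param noise_cv multiplicative noise CV per beat.
#' @param beats_per_dose beats measured at each dose.
#' @param seed integer RNG seed.
#' @return A `dose_response_config` list.
#' @export
dose_response_config <- function(doses = 10^seq(-8, log10(3.2e-5), by = 0.5),
                                 ec50_true = 260e-9, hill_coefficient = 1,
                                 baseline_force = 0.18e-9,
                                 max_force = 0.48e-9, noise_cv = 0.1,
                                 beats_per_dose = 30, seed = 1L) {
  if (any(doses <= 0) || is.unsorted(doses, strictly = TRUE)) {
    stop("doses must be strictly positive and strictly increasing")
  }
  stop_if_not_scalar_pos(ec50_true, "ec50_true")
  if (max_force <= baseline_force) stop("max_force must exceed baseline_force")
  structure(list(doses = doses, ec50_true = ec50_true,
                 hill_coefficient = hill_coefficient,
                 baseline_force = baseline_force, max_force = max_force,
                 noise_cv = noise_cv, beats_per_dose = as.integer(beats_per_dose),
                 seed = seed),
            class = "dose_response_config")
}

#' Simulate a dose-response series of beat forces
#'
#' @param config a [dose_response_config()].
#' @return A data.frame (`dose_M`, `force_N`) of class `dose_response_series`,
#'   with the generating config as attribute `config`.
#' @export
simulate_dose_response <- function(config) {
  stopifnot(inherits(config, "dose_response_config"))
  with_seed(config$seed, {
    out <- do.call(rbind, lapply(config$doses, function(dose) {
      h <- config$hill_coefficient
      mu <- config$baseline_force + (config$max_force - config$baseline_force) *
        dose^h / (dose^h + config$ec50_true^h)
      f <- mu * (1 + if (config$noise_cv > 0)
        stats::rnorm(config$beats_per_dose, 0, config$noise_cv) else
          numeric(config$beats_per_dose))
      data.frame(dose_M = dose, force_N = f)
    }))
    attr(out, "config") <- config
    class(out) <- c("dose_response_series", "data.frame")
    out
  })
}
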