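#' Force and deflection trajectory containers
#'
#' A `force_trajectory` holds a uniformly sampled force-vs-time series from
#' one cantilever dwell; a `deflection_trajectory` holds raw deflection in
#' metres (before conversion by the spring constant). Both are lists with a
#' numeric `time` (s), the signal vector, a `sampling_rate` (Hz) and free-form
#' `meta` (calibration, seeds, ground truth from the simulator).
#'
#' @param time numeric vector of times in seconds, uniform grid.
#' @param force numeric vector of forces in newtons.
#' @param sampling_rate sampling rate in Hz; inferred from `time` if `NULL`.
#' @param meta named list of metadata (spring constant, seed, ground truth...).
#' @return An object of class `force_trajectory`.
#' @export
force_trajectory <- function(time, force, sampling_rate = NULL, meta = list()) {
  if (length(time) != length(force)) stop("time and force lengths differ")
  if (length(time) < 2L) stop("a trajectory needs at least 2 samples")
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (diff(range(dt)) > 1e-9 * mean(dt)) {
    stop("time grid is not uniform (relative tolerance 1e-9)")
  }
  if (is.null(sampling_rate)) sampling_rate <- 1 / mean(dt)
  structure(list(time = as.numeric(time), force = as.numeric(force),
                 sampling_rate = sampling_rate, meta = meta),
            class = "force_trajectory")
}

#' @rdname force_trajectory
#' @param deflection numeric vector of cantilever deflections in metres.
#' @export
deflection_trajectory <- function(time, deflection, sampling_rate = NULL,
                                  meta = list()) {
  tr <- force_trajectory(time, deflection, sampling_rate, meta)
  names(tr)[names(tr) == "force"] <- "deflection"
  class(tr) <- "deflection_trajectory"
  tr
}

#' @export
print.force_trajectory <- function(x, ...) {
  cat(sprintf("<force_trajectory> %d samples, %.3f s at %.6g Hz\n",
              length(x$force), x$time[length(x$time)] - x$time[1],
              x$sampling_rate))
  cat(sprintf("  force range: %.4g .. %.4g nN\n",
              min(x$force) * 1e9, max(x$force) * 1e9))
  invisible(x)
}

#' @export
print.deflection_trajectory <- function(x, ...) {
  cat(sprintf("<deflection_trajectory> %d samples, %.3f s at %.6g Hz\n",
              length(x$deflection), x$time[length(x$time)] - x$time[1],
              x$sampling_rate))
  invisible(x)
}

#' AFM force curve (approach segment)
#'
#' Stores the approach segment of an indentation curve: z-piezo extension
#' (metres, increasing toward the sample) and cantilever deflection (metres),
#' with the spring constant needed to express force F = k * d.
#'
#' @param z numeric vector, piezo extension in metres (monotone increasing on
#'   the approach).
#' @param deflection numeric vector, deflection in metres.
#' @param spring_constant cantilever spring constant in N/m.
#' @param meta named list of metadata.
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(z, deflection, spring_constant, meta = list()) {
  if (length(z) != length(deflection)) stop("z and deflection lengths differ")
  if (length(z) < 2L) stop("a force curve needs at least 2 samples")
  if (any(diff(z) <= 0)) stop("approach segment requires strictly increasing z")
  stop_if_not_scalar_pos(spring_constant, "spring_constant")
  structure(list(z = as.numeric(z), deflection = as.numeric(deflection),
                 spring_constant = spring_constant, meta = meta),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %d points, z %.3f .. %.3f um, k = %.4g N/m\n",
              length(x$z), min(x$z) * 1e6, max(x$z) * 1e6, x$spring_constant))
  invisible(x)
}

#' Paired (beat force, Young's modulus) observations
#'
#' The joint point cloud fed to the two-dimensional Kolmogorov-Smirnov test
#' and the bootstrap comparisons: one row per beating dwell-map point with a
#' successful Hertz fit. Glass points and non-beating points are excluded.
#'
#' @param beat_force numeric vector, mean beat peak force per point (N), > 0.
#' @param modulus numeric vector, fitted Young's modulus per point (Pa), > 0.
#' @param label single string naming the condition (e.g. "healthy", "DCM").
#' @return A `mechano_point_set`: a data.frame with columns `beat_force_N`,
#'   `E_Pa` and `log10_E`, with attribute `label`.
#' @export
mechano_point_set <- function(beat_force, modulus, label = "unnamed") {
  if (length(beat_force) != length(modulus)) stop("length mismatch")
  if (anyNA(beat_force) || anyNA(modulus)) stop("point set cannot hold NA")
  if (length(beat_force) && (any(beat_force <= 0) || any(modulus <= 0))) {
    stop("beat_force and modulus must be positive")
  }
  out <- data.frame(beat_force_N = as.numeric(beat_force),
                    E_Pa = as.numeric(modulus),
                    log10_E = log10(as.numeric(modulus)))
  attr(out, "label") <- label
  class(out) <- c("mechano_point_set", "data.frame")
  out
}

#' @export
print.mechano_point_set <- function(x, ...) {
  cat(sprintf("<mechano_point_set> '%s': %d beating points\n",
              attr(x, "label"), nrow(x)))
  if (nrow(x)) {
    cat(sprintf("  mean beat force %.3g nN, geometric-mean E %.4g Pa\n",
                mean(x$beat_force_N) * 1e9, exp(mean(log(x$E_Pa)))))
  }
  invisible(x)
}
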