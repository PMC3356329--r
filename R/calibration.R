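#' Thermal-noise calibration of the cantilever spring constant
#'
#' Estimates the spring constant from the thermal fluctuations of the free
#' cantilever via the equipartition theorem: `k = kB * T / var(d)`, where the
#' deflection variance is computed after mean removal. The optional
#' `"equipartition_mode1_corrected"` method multiplies by beta1 = 0.971, the
#' standard correction for the fraction of thermal energy carried by the
#' first flexural mode of a rectangular cantilever.
#'
#' @param deflection_series a [deflection_trajectory()] of the free cantilever
#'   (metres), at least 1000 samples.
#' @param temperature bath temperature, K. Default 309.15 K (36 C).
#' @param method `"equipartition"` (default) or
#'   `"equipartition_mode1_corrected"`.
#' @return A `cantilever_calibration` list: `spring_constant` (N/m),
#'   `temperature`, `method`, `variance_used` (m^2), `n_samples`.
#' @export
calibrate_spring_constant <- function(deflection_series,
                                      temperature = 309.15,
                                      method = c("equipartition",
                                                 "equipartition_mode1_corrected")) {
  method <- match.arg(method)
  stopifnot(inherits(deflection_series, "deflection_trajectory"))
  stop_if_not_scalar_pos(temperature, "temperature")
  d <- deflection_series$deflection
  if (length(d) < 1000L) stop("need >= 1000 samples for thermal calibration")
  v <- mean((d - mean(d))^2)
  if (v <= .Machine$double.eps * max(abs(d), 1e-30)^2 || v == 0) {
    stop("degenerate input: deflection variance is zero or near zero")
  }
  beta1 <- if (method == "equipartition_mode1_corrected") 0.971 else 1
  k <- beta1 * .kB * temperature / v
  structure(list(spring_constant = k, temperature = temperature,
                 method = method, variance_used = v,
                 n_samples = length(d)),
            class = "cantilever_calibration")
}

#' @export
print.cantilever_calibration <- function(x, ...) {
  cat(sprintf("<cantilever_calibration> k = %.5g N/m (%s, T = %.2f K, n = %d)\n",
              x$spring_constant, x$method, x$temperature, x$n_samples))
  invisible(x)
}

#' Convert deflection to force
#'
#' Applies Hooke's law F = k * d elementwise. Accepts a bare numeric vector
#' or a [deflection_trajectory()]; the latter is returned as a
#' [force_trajectory()] carrying the spring constant in its metadata.
#'
#' @param deflection numeric vector (m) or a `deflection_trajectory`.
#' @param spring_constant spring constant in N/m, or a
#'   `cantilever_calibration`.
#' @return Forces in newtons (numeric, or a `force_trajectory`).
#' @examples
#' deflection_to_force(2.5e-9, 0.04)  # the 100 pN contact trigger
#' @export
deflection_to_force <- function(deflection, spring_constant) {
  if (inherits(spring_constant, "cantilever_calibration")) {
    spring_constant <- spring_constant$spring_constant
  }
  if (is.null(spring_constant)) stop("missing calibration: spring_constant is NULL")
  stop_if_not_scalar_pos(spring_constant, "spring_constant")
  if (inherits(deflection, "deflection_trajectory")) {
    meta <- deflection$meta
    meta$spring_constant <- spring_constant
    return(force_trajectory(deflection$time,
                            deflection$deflection * spring_constant,
                            deflection$sampling_rate, meta = meta))
  }
  deflection * spring_constant
}

#' @rdname deflection_to_force
#' @param force numeric forces in newtons.
#' @export
force_to_deflection <- function(force, spring_constant) {
  stop_if_not_scalar_pos(spring_constant, "spring_constant")
  force / spring_constant
}
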