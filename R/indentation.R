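#' Hertz-family contact force laws
#'
#' Force as a function of indentation depth for the three supported indenter
#' geometries (Poisson ratio `nu`, modulus `E` in Pa, depth `delta` in m):
#'
#' * cone (Sneddon): `F = (2/pi) * tan(alpha) * E / (1 - nu^2) * delta^2`
#' * sphere (Hertz): `F = (4/3) * sqrt(R) * E / (1 - nu^2) * delta^(3/2)`
#' * pyramid (Bilodeau): `F = 0.7453 * tan(alpha) * E / (1 - nu^2) * delta^2`
#'
#' @param delta indentation depth(s), m (negative values give 0 force).
#' @param E Young's modulus, Pa.
#' @param geometry `"cone"`, `"sphere"` or `"pyramid"`.
#' @param tip_param half-angle in degrees (cone/pyramid) or radius in m
#'   (sphere).
#' @param nu Poisson's ratio; 0.5 for an incompressible cell.
#' @return Force(s) in newtons.
#' @export
hertz_force <- function(delta, E, geometry = c("cone", "sphere", "pyramid"),
                        tip_param, nu = 0.5) {
  geometry <- match.arg(geometry)
  delta <- pmax(delta, 0)
  pref <- hertz_prefactor(E, geometry, tip_param, nu)
  pref * delta^hertz_exponent(geometry)
}

# modulus-dependent prefactor C such that F = C * delta^m
hertz_prefactor <- function(E, geometry, tip_param, nu = 0.5) {
  switch(geometry,
         cone = (2 / pi) * tan(tip_param * pi / 180) * E / (1 - nu^2),
         sphere = (4 / 3) * sqrt(tip_param) * E / (1 - nu^2),
         pyramid = 0.7453 * tan(tip_param * pi / 180) * E / (1 - nu^2))
}

hertz_exponent <- function(geometry) {
  if (geometry == "sphere") 1.5 else 2
}

#' Locate the tip-sample contact point of an approach curve
#'
#' Fits a piecewise model — flat deflection `d0` before the candidate contact
#' point, a Hertz law of the corrected indentation beyond it — over a grid of
#' candidate contact points and returns the least-squares minimum, refined by
#' golden-section search between the best grid neighbours. Because the model
#' is linear in E at fixed contact point, each candidate is scored in closed
#' form.
#'
#' @param curve a [force_curve()].
#' @param geometry,tip_param,nu indenter model (see [hertz_force()]).
#' @param coarse_step spacing of the candidate grid in samples; `NULL` scales
#'   it with the curve length (~100 candidates) before the continuous
#'   refinement.
#' @return A list: `z_c` (contact z, m), `d0` (pre-contact deflection offset,
#'   m), `rss` (residual sum of squares in N^2).
#' @export
find_contact_point <- function(curve, geometry = "cone", tip_param = 35,
                               nu = 0.5, coarse_step = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  z <- curve$z; d <- curve$deflection; k <- curve$spring_constant
  n <- length(z)
  if (n < 50L) stop("approach segment needs at least 50 points")
  m <- hertz_exponent(geometry)

  # no-contact screen: the deflection at the end of the approach must rise
  # significantly above the early-curve baseline (test on block means, so a
  # soft sample whose force stays near the noise floor still registers)
  n0 <- max(10L, floor(0.2 * n))
  d_pre <- d[seq_len(n0)]
  noise <- stats::sd(d_pre)
  n_tail <- max(10L, floor(0.05 * n))
  rise <- mean(d[(n - n_tail + 1L):n]) - mean(d_pre)
  if (rise < max(4 * noise * sqrt(1 / n_tail + 1 / n0), 1e-12)) {
    stop("no contact detected: deflection never rises above the baseline")
  }

  F_all <- k * d
  score <- function(zc) {
    pre <- z <= zc
    n_pre <- sum(pre)
    if (n_pre < 5L || n_pre > n - 10L) return(Inf)
    d0 <- mean(d[pre])
    F0 <- k * d0
    delta <- pmax((z - zc) - (d - d0), 0)
    phi <- delta^m
    Fc <- F_all - F0
    ss_phi <- sum(phi^2)
    coef <- if (ss_phi > 0) sum(Fc * phi) / ss_phi else 0
    coef <- max(coef, 0)
    sum((Fc - coef * phi)^2)
  }

  lo <- max(5L, floor(0.05 * n))
  hi <- n - 10L
  if (is.null(coarse_step)) coarse_step <- max(4L, (hi - lo) %/% 100L)
  cand_idx <- seq(lo, hi, by = as.integer(coarse_step))
  rss <- vapply(z[cand_idx], score, numeric(1))
  best <- cand_idx[which.min(rss)]
  z_lo <- z[max(lo, best - coarse_step)]
  z_hi <- z[min(hi, best + coarse_step)]
  opt <- stats::optimize(score, c(z_lo, z_hi), tol = diff(range(z)) * 1e-7)
  z_c <- opt$minimum
  d0 <- mean(d[z <= z_c])
  list(z_c = z_c, d0 = d0, rss = opt$objective)
}

#' Fit the Hertz model to an approach curve
#'
#' With the contact point and deflection offset fixed (from
#' [find_contact_point()] unless supplied), the Young's modulus is the exact
#' least-squares solution of the regression of force on `delta^m` — the Hertz
#' laws are linear in E, so no iterative optimiser is needed. Indentations
#' beyond `fit_range` are excluded.
#'
#' @param curve a [force_curve()].
#' @param geometry,tip_param,nu indenter model (see [hertz_force()]).
#' @param fit_range maximum indentation depth included in the fit, m
#'   (`Inf` = use the full curve up to the trigger depth).
#' @param contact optional list `(z_c, d0)` to reuse a previous contact fit.
#' @return A `hertz_fit` list: `E` (Pa), `z_c`, `d0`, `geometry`,
#'   `tip_param`, `nu`, `residual_rms` (N), `n_fit`, `ok` (FALSE when the
#'   fitted E is non-positive or the contact search failed).
#' @export
fit_hertz <- function(curve, geometry = c("cone", "sphere", "pyramid"),
                      tip_param = 35, nu = 0.5, fit_range = Inf,
                      contact = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(contact)) {
    contact <- tryCatch(
      find_contact_point(curve, geometry, tip_param, nu),
      error = function(e) NULL)
    if (is.null(contact)) {
      return(structure(list(E = NA_real_, z_c = NA_real_, d0 = NA_real_,
                            geometry = geometry, tip_param = tip_param,
                            nu = nu, residual_rms = NA_real_, n_fit = 0L,
                            ok = FALSE),
                       class = "hertz_fit"))
    }
  }
  k <- curve$spring_constant
  m <- hertz_exponent(geometry)
  delta <- (curve$z - contact$z_c) - (curve$deflection - contact$d0)
  post <- curve$z > contact$z_c & delta > 0 & delta <= fit_range
  if (sum(post) < 20L) {
    return(structure(list(E = NA_real_, z_c = contact$z_c, d0 = contact$d0,
                          geometry = geometry, tip_param = tip_param, nu = nu,
                          residual_rms = NA_real_, n_fit = sum(post),
                          ok = FALSE),
                     class = "hertz_fit"))
  }
  FF <- k * (curve$deflection[post] - contact$d0)
  phi <- delta[post]^m
  pref_unit <- hertz_prefactor(1, geometry, tip_param, nu)
  coef <- sum(FF * phi) / sum(phi^2)
  E <- coef / pref_unit
  res <- FF - coef * phi
  structure(list(E = E, z_c = contact$z_c, d0 = contact$d0,
                 geometry = geometry, tip_param = tip_param, nu = nu,
                 residual_rms = sqrt(mean(res^2)), n_fit = sum(post),
                 ok = is.finite(E) && E > 0),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("<hertz_fit> E = %.4g Pa (%s, z_c = %.4g um, rms %.3g pN, n = %d)\n",
                x$E, x$geometry, x$z_c * 1e6, x$residual_rms * 1e12, x$n_fit))
  } else {
    cat("<hertz_fit> FAILED\n")
  }
  invisible(x)
}

#' Indentation depth at a given trigger force
#'
#' Inverts the fitted Hertz law: the depth at which the model force equals
#' the trigger, `delta = (F / C)^(1/m)`.
#'
#' @param fit a `hertz_fit` (or any list with `E`, `geometry`, `tip_param`,
#'   `nu`).
#' @param trigger trigger force, N (e.g. 100e-12 for a 100 pN trigger).
#' @param max_indentation optional cap; exceeding it raises an error (the
#'   trigger lies beyond the measured curve).
#' @return Indentation depth in metres.
#' @export
indentation_at_trigger <- function(fit, trigger, max_indentation = Inf) {
  if (trigger < 0) stop("trigger must be >= 0")
  if (trigger == 0) return(0)
  if (!isTRUE(fit$ok) && !is.finite(fit$E)) stop("Hertz fit unavailable")
  pref <- hertz_prefactor(fit$E, fit$geometry, fit$tip_param, fit$nu)
  delta <- (trigger / pref)^(1 / hertz_exponent(fit$geometry))
  if (delta > max_indentation) {
    stop("trigger force exceeds the maximum force of the fitted range")
  }
  delta
}

#' Local cell height from paired contact points
#'
#' The cell height at a grid point is the difference between the z-piezo
#' extension needed to touch the glass substrate and the (smaller) extension
#' needed to touch the cell: `height = z_c(substrate) - z_c(cell)`. Both
#' contact points must be expressed in the same z frame.
#'
#' @param cell_z_c contact point measured on the cell, m.
#' @param substrate_z_c contact point measured on the bare substrate, m.
#' @return Height in metres; negative values are returned with a warning
#'   (probable mis-ordered reference).
#' @export
cell_height <- function(cell_z_c, substrate_z_c) {
  h <- substrate_z_c - cell_z_c
  if (any(h < 0, na.rm = TRUE)) {
    warning("negative cell height: contact points may be mis-ordered")
  }
  h
}
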