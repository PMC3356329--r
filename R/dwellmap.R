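#' Analysis parameters for a dwell-map point
#'
#' Bundles the indenter model and beat-detection settings shared by every
#' point of a map.
#'
#' @param geometry,tip_param,nu indenter model (see [hertz_force()]).
#' @param min_beats minimum detected beats for a point to count as beating.
#' @param min_separation,smooth_sigma,min_height passed to [detect_beats()].
#' @param substrate_z_c optional substrate contact point (m) for height
#'   computation; `NA` defers height to [assemble_dwell_map()], which uses
#'   the latest (deepest) contact point among non-beating points as the
#'   substrate reference when available.
#' @return A `dwell_point_params` list.
#' @export
dwell_point_params <- function(geometry = "cone", tip_param = 35, nu = 0.5,
                               min_beats = 2L, min_separation = 0.25,
                               smooth_sigma = 0.010, min_height = "auto",
                               substrate_z_c = NA_real_) {
  structure(list(geometry = geometry, tip_param = tip_param, nu = nu,
                 min_beats = as.integer(min_beats),
                 min_separation = min_separation,
                 smooth_sigma = smooth_sigma, min_height = min_height,
                 substrate_z_c = substrate_z_c),
            class = "dwell_point_params")
}

#' Analyze one dwell-map grid point
#'
#' Runs the indentation pipeline (contact point + Hertz fit) on the point's
#' approach curve and the beat pipeline (baseline + detection + summary) on
#' its dwell trajectory. Neither a failed Hertz fit nor an absence of beats
#' is fatal — both are recorded, since glass points legitimately show no
#' beats.
#'
#' @param curve the point's [force_curve()].
#' @param dwell the point's [force_trajectory()] recorded during the dwell.
#' @param params a [dwell_point_params()].
#' @param row,col 0-based grid indices.
#' @param x,y physical position, m.
#' @return A `dwell_point` list: grid position, `z_c`, `height` (NA unless a
#'   substrate reference is set), `E` (NA on fit failure), `beats`
#'   (`beat_events`), `n_beats`, `beat_force` (mean detected peak force, NA
#'   if below `min_beats`), `is_beating`, `low_confidence` (TRUE when the
#'   dwell is shorter than two detected beat periods).
#' @export
analyze_dwell_point <- function(curve, dwell, params = dwell_point_params(),
                                row = NA_integer_, col = NA_integer_,
                                x = NA_real_, y = NA_real_) {
  fit <- fit_hertz(curve, geometry = params$geometry,
                   tip_param = params$tip_param, nu = params$nu)
  beats <- detect_beats(dwell, min_height = params$min_height,
                        min_separation = params$min_separation,
                        smooth_sigma = params$smooth_sigma)
  n_beats <- nrow(beats)
  is_beating <- n_beats >= params$min_beats
  dwell_len <- dwell$time[length(dwell$time)] - dwell$time[1]
  low_conf <- FALSE
  if (is_beating && n_beats >= 2L) {
    period <- mean(diff(beats$t_peak))
    low_conf <- dwell_len < 2 * period
  }
  height <- if (is.finite(params$substrate_z_c) && fit$ok) {
    cell_height(fit$z_c, params$substrate_z_c)
  } else {
    NA_real_
  }
  structure(list(row = row, col = col, x = x, y = y,
                 z_c = if (fit$ok) fit$z_c else NA_real_,
                 height = height,
                 E = if (fit$ok) fit$E else NA_real_,
                 hertz_ok = fit$ok,
                 beats = beats, n_beats = n_beats,
                 beat_force = if (is_beating) mean(beats$force) else NA_real_,
                 is_beating = is_beating, low_confidence = low_conf),
            class = "dwell_point")
}

#' Assemble analyzed points into a dwell map
#'
#' Orders points row-major, checks the grid is complete without duplicates,
#' and exposes the height / modulus / beat-force fields as matrices with NA
#' for missing values (failed fits, non-beating points). If no substrate
#' reference was given per point, heights are computed relative to the
#' deepest contact point among non-beating (glass) points when at least one
#' exists.
#'
#' @param points list of `dwell_point`s covering an `n_rows x n_cols` grid.
#' @param n_rows,n_cols grid dimensions; inferred from the indices if `NULL`.
#' @return A `dwell_map` list: `n_rows`, `n_cols`, `points` (row-major),
#'   `height`, `E`, `beat_force` matrices, and `counts`
#'   (beating / non_beating / hertz_failed).
#' @export
assemble_dwell_map <- function(points, n_rows = NULL, n_cols = NULL) {
  stopifnot(length(points) > 0L)
  rows <- vapply(points, `[[`, numeric(1), "row")
  cols <- vapply(points, `[[`, numeric(1), "col")
  if (anyNA(rows) || anyNA(cols)) stop("all points need grid indices")
  if (is.null(n_rows)) n_rows <- max(rows) + 1L
  if (is.null(n_cols)) n_cols <- max(cols) + 1L
  key <- rows * n_cols + cols
  if (anyDuplicated(key)) stop("duplicate grid cells in point list")
  if (length(points) != n_rows * n_cols ||
      !setequal(key, seq_len(n_rows * n_cols) - 1L)) {
    stop("incomplete grid: expected one point per cell")
  }
  points <- points[order(key)]

  get_field <- function(name) {
    m <- matrix(NA_real_, n_rows, n_cols)
    for (p in points) m[p$row + 1L, p$col + 1L] <- p[[name]]
    m
  }
  # substrate reference: deepest contact among non-beating points
  if (all(vapply(points, function(p) is.na(p$height), logical(1)))) {
    glass_zc <- vapply(points, function(p) {
      if (!p$is_beating && p$hertz_ok) p$z_c else NA_real_
    }, numeric(1))
    if (any(is.finite(glass_zc))) {
      sub_zc <- max(glass_zc, na.rm = TRUE)
      for (i in seq_along(points)) {
        if (points[[i]]$hertz_ok) {
          # direct difference: contact-point jitter makes small negative
          # heights unremarkable at glass-level points
          points[[i]]$height <- sub_zc - points[[i]]$z_c
        }
      }
    }
  }
  beating <- vapply(points, `[[`, logical(1), "is_beating")
  hertz_ok <- vapply(points, `[[`, logical(1), "hertz_ok")
  out <- structure(list(n_rows = n_rows, n_cols = n_cols, points = points,
                        height = get_field("height"), E = get_field("E"),
                        beat_force = get_field("beat_force"),
                        counts = c(beating = sum(beating),
                                   non_beating = sum(!beating),
                                   hertz_failed = sum(!hertz_ok))),
                   class = "dwell_map")
  if (!any(beating)) warning("dwell map contains no beating points")
  out
}

#' @export
print.dwell_map <- function(x, ...) {
  cat(sprintf("<dwell_map> %d x %d grid: %d beating, %d non-beating, %d failed fits\n",
              x$n_rows, x$n_cols, x$counts["beating"], x$counts["non_beating"],
              x$counts["hertz_failed"]))
  invisible(x)
}

#' Extract the joint (beat force, modulus) point set from a dwell map
#'
#' Keeps beating points with successful Hertz fits; glass and non-beating
#' points never enter the set.
#'
#' @param map a `dwell_map` from [assemble_dwell_map()].
#' @param label condition name attached to the set.
#' @return A [mechano_point_set()]; zero rows (with a warning) when no point
#'   qualifies.
#' @export
extract_point_set <- function(map, label = "unnamed") {
  stopifnot(inherits(map, "dwell_map"))
  keep <- vapply(map$points, function(p) {
    p$is_beating && p$hertz_ok && is.finite(p$beat_force) && p$beat_force > 0
  }, logical(1))
  if (!any(keep)) {
    warning("no beating points with successful fits; returning empty set")
    return(mechano_point_set(numeric(0), numeric(0), label))
  }
  pts <- map$points[keep]
  mechano_point_set(vapply(pts, `[[`, numeric(1), "beat_force"),
                    vapply(pts, `[[`, numeric(1), "E"), label)
}

#' Run the full pipeline on a simulated dwell map
#'
#' Convenience wrapper: analyzes every point of a `dwell_map_raw` (from
#' [simulate_dwell_map()]) and assembles the result.
#'
#' @param raw a `dwell_map_raw`.
#' @param params a [dwell_point_params()].
#' @return A `dwell_map`.
#' @export
analyze_dwell_map <- function(raw, params = dwell_point_params()) {
  stopifnot(inherits(raw, "dwell_map_raw"))
  pts <- lapply(raw$points, function(p) {
    analyze_dwell_point(p$curve, p$dwell, params,
                        row = p$row, col = p$col, x = p$x, y = p$y)
  })
  assemble_dwell_map(pts, raw$config$n_rows, raw$config$n_cols)
}
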