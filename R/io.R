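# Plain-text tabular dialects. All files are CSV/TSV with SI units encoded
# in the column names and '#'-prefixed key=value metadata lines, so they are
# diff-able and self-describing.

.read_meta_lines <- function(path, n_max = 50L) {
  head_lines <- readLines(path, n = n_max)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- trimws(substr(kv, 1, eq - 1))
      val <- trimws(substr(kv, eq + 1, nchar(kv)))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

.write_meta_lines <- function(meta, con) {
  for (key in names(meta)) {
    v <- meta[[key]]
    if (is.numeric(v)) v <- format(v, digits = 17)
    writeLines(sprintf("# %s=%s", key, v), con)
  }
}

#' Write / read a trajectory file
#'
#' The trajectory dialect is a CSV with a `time_s` column followed by exactly
#' one of `force_N` or `deflection_m`, preceded by `#` metadata lines
#' (`sampling_rate_hz`, `spring_constant_N_per_m`, ...). Deflection files are
#' converted to force on read, which requires a spring constant from the
#' metadata or the `spring_constant` argument. The time grid is validated to
#' be uniform.
#'
#' @param traj a [force_trajectory()] or [deflection_trajectory()].
#' @param path file path.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns a [force_trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- list(sampling_rate_hz = traj$sampling_rate)
  if (!is.null(traj$meta$spring_constant)) {
    meta$spring_constant_N_per_m <- traj$meta$spring_constant
  }
  if (!is.null(traj$meta$seed)) meta$seed <- traj$meta$seed
  .write_meta_lines(meta, con)
  if (inherits(traj, "deflection_trajectory")) {
    df <- data.frame(time_s = traj$time, deflection_m = traj$deflection)
  } else {
    df <- data.frame(time_s = traj$time, force_N = traj$force)
  }
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param spring_constant spring constant in N/m, required for deflection
#'   files lacking `spring_constant_N_per_m` metadata.
#' @export
read_trajectory <- function(path, spring_constant = NULL) {
  meta <- .read_meta_lines(path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!"time_s" %in% names(df)) stop("missing required column: time_s")
  dt <- diff(df$time_s)
  bad <- which(dt <= 0)
  if (length(bad)) {
    stop(sprintf("non-monotone time grid at row %d", bad[1] + 1L))
  }
  rel <- abs(dt - mean(dt)) / mean(dt)
  if (any(rel > 1e-6)) {
    stop(sprintf("non-uniform time grid at row %d (relative deviation %.3g)",
                 which.max(rel) + 1L, max(rel)))
  }
  k <- spring_constant %||% meta$spring_constant_N_per_m
  if ("force_N" %in% names(df)) {
    tr_meta <- meta
    if (!is.null(k)) tr_meta$spring_constant <- k
    force_trajectory(df$time_s, df$force_N,
                     sampling_rate = meta$sampling_rate_hz, meta = tr_meta)
  } else if ("deflection_m" %in% names(df)) {
    if (is.null(k)) {
      stop("deflection file requires a spring constant (metadata spring_constant_N_per_m or argument)")
    }
    d <- deflection_trajectory(df$time_s, df$deflection_m,
                               sampling_rate = meta$sampling_rate_hz,
                               meta = meta)
    deflection_to_force(d, k)
  } else {
    stop("missing required column: force_N or deflection_m")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a force-curve file
#'
#' Approach curves are CSVs with columns `z_m` and `deflection_m` and `#`
#' metadata (at least `spring_constant_N_per_m`). On read, z must be
#' strictly increasing: a decreasing z column is rejected as a retract
#' segment.
#'
#' @param curve a [force_curve()].
#' @param path file path.
#' @return `write_force_curve()` returns `path` invisibly;
#'   `read_force_curve()` a [force_curve()].
#' @export
write_force_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  .write_meta_lines(list(spring_constant_N_per_m = curve$spring_constant,
                         direction = "approach"), con)
  df <- data.frame(z_m = curve$z, deflection_m = curve$deflection)
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_force_curve
#' @param spring_constant spring constant override, N/m.
#' @export
read_force_curve <- function(path, spring_constant = NULL) {
  meta <- .read_meta_lines(path)
  df <- utils::read.csv(path, comment.char = "#")
  for (col in c("z_m", "deflection_m")) {
    if (!col %in% names(df)) stop("missing required column: ", col)
  }
  k <- spring_constant %||% meta$spring_constant_N_per_m
  if (is.null(k)) stop("missing spring constant for force curve")
  if (all(diff(df$z_m) < 0)) {
    stop("approach segment missing: z is decreasing (retract-only curve?)")
  }
  if (any(diff(df$z_m) <= 0)) {
    stop("z must be strictly increasing on the approach segment")
  }
  force_curve(df$z_m, df$deflection_m, k, meta = meta)
}

#' Write / read a simulated dwell map as a file collection
#'
#' A dwell map on disk is a directory holding one curve CSV and one dwell
#' trajectory CSV per grid point plus a TSV index
#' (`row, col, x_m, y_m, curve_file, dwell_file`). Ground truth, when
#' present, is written to `ground_truth.tsv` alongside.
#'
#' @param raw a `dwell_map_raw` from [simulate_dwell_map()].
#' @param dir output directory (created if needed).
#' @return `write_dwell_map_files()` returns the index path invisibly;
#'   `read_dwell_map_files()` returns a `dwell_map_raw` (without ground
#'   truth unless the sidecar exists).
#' @export
write_dwell_map_files <- function(raw, dir) {
  stopifnot(inherits(raw, "dwell_map_raw"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- do.call(rbind, lapply(raw$points, function(p) {
    cf <- sprintf("curve_r%02d_c%02d.csv", p$row, p$col)
    df <- sprintf("dwell_r%02d_c%02d.csv", p$row, p$col)
    write_force_curve(p$curve, file.path(dir, cf))
    write_trajectory(p$dwell, file.path(dir, df))
    data.frame(row = p$row, col = p$col, x_m = p$x, y_m = p$y,
               curve_file = cf, dwell_file = df)
  }))
  index_path <- file.path(dir, "index.tsv")
  utils::write.table(idx, index_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(raw$ground_truth)) {
    utils::write.table(raw$ground_truth, file.path(dir, "ground_truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(index_path)
}

#' @rdname write_dwell_map_files
#' @param index_path path to the `index.tsv` of a dwell-map directory.
#' @export
read_dwell_map_files <- function(index_path) {
  idx <- utils::read.delim(index_path)
  need <- c("row", "col", "x_m", "y_m", "curve_file", "dwell_file")
  for (col in need) if (!col %in% names(idx)) stop("index missing column: ", col)
  dir <- dirname(index_path)
  points <- lapply(seq_len(nrow(idx)), function(i) {
    list(row = idx$row[i], col = idx$col[i], x = idx$x_m[i], y = idx$y_m[i],
         curve = read_force_curve(file.path(dir, idx$curve_file[i])),
         dwell = read_trajectory(file.path(dir, idx$dwell_file[i])))
  })
  gt_path <- file.path(dir, "ground_truth.tsv")
  gt <- if (file.exists(gt_path)) utils::read.delim(gt_path) else NULL
  structure(list(points = points, ground_truth = gt,
                 config = list(n_rows = max(idx$row) + 1L,
                               n_cols = max(idx$col) + 1L)),
            class = "dwell_map_raw")
}

#' Write / read a (beat force, modulus) point set as TSV
#'
#' @param ps a [mechano_point_set()].
#' @param path file path.
#' @return `write_point_set()` returns `path` invisibly; `read_point_set()`
#'   a [mechano_point_set()].
#' @export
write_point_set <- function(ps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  .write_meta_lines(list(label = attr(ps, "label")), con)
  utils::write.table(data.frame(beat_force_N = ps$beat_force_N,
                                E_Pa = ps$E_Pa),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_point_set
#' @export
read_point_set <- function(path) {
  meta <- .read_meta_lines(path)
  df <- utils::read.delim(path, comment.char = "#")
  for (col in c("beat_force_N", "E_Pa")) {
    if (!col %in% names(df)) stop("missing required column: ", col)
  }
  mechano_point_set(df$beat_force_N, df$E_Pa,
                    label = meta$label %||% "unnamed")
}

#' Export a dwell map as long-format and matrix TSVs
#'
#' Writes `map_long.tsv` (`row, col, x_m, y_m, height_m, E_Pa, beat_force_N,
#' n_beats, is_beating`) plus one matrix TSV per field.
#'
#' @param map a `dwell_map`.
#' @param dir output directory.
#' @return The long-format path, invisibly.
#' @export
write_dwell_map_tables <- function(map, dir) {
  stopifnot(inherits(map, "dwell_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- do.call(rbind, lapply(map$points, function(p) {
    data.frame(row = p$row, col = p$col, x_m = p$x, y_m = p$y,
               height_m = p$height, E_Pa = p$E, beat_force_N = p$beat_force,
               n_beats = p$n_beats, is_beating = p$is_beating)
  }))
  long_path <- file.path(dir, "map_long.tsv")
  utils::write.table(long, long_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  for (field in c("height", "E", "beat_force")) {
    utils::write.table(map[[field]],
                       file.path(dir, paste0("map_", field, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(long_path)
}

#' Write a calibration result as a plain-text sidecar
#'
#' @param cal a `cantilever_calibration`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "cantilever_calibration"))
  con <- file(path, "w")
  on.exit(close(con))
  .write_meta_lines(list(spring_constant_N_per_m = cal$spring_constant,
                         temperature_K = cal$temperature,
                         method = cal$method,
                         variance_m2 = cal$variance_used,
                         n_samples = cal$n_samples), con)
  invisible(path)
}

# Recognised run-configuration keys, nested as section.key.
.run_config_schema <- list(
  seed = "integer",
  detection = c("min_separation", "smooth_sigma", "min_height_floor",
                "baseline_window", "baseline_percentile", "min_beats"),
  hertz = c("geometry", "tip_param", "nu", "fit_range"),
  calibration = c("temperature", "method"),
  stats = c("n_perm", "bootstrap_B", "alpha")
)

#' Read a run configuration file
#'
#' Run configurations are YAML with a fixed schema (`seed` plus the
#' `detection`, `hertz`, `calibration` and `stats` sections); unknown keys
#' are rejected by name so typos cannot silently fall back to defaults.
#'
#' @param path path to a YAML file.
#' @return A nested list of validated settings.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading run configurations requires the 'yaml' package")
  }
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("run config must be a key-value mapping")
  for (key in names(cfg)) {
    if (!key %in% names(.run_config_schema)) {
      stop("unknown config key: ", key)
    }
    if (key == "seed") next
    sub <- cfg[[key]]
    for (subkey in names(sub)) {
      if (!subkey %in% .run_config_schema[[key]]) {
        stop("unknown config key: ", key, ".", subkey)
      }
    }
  }
  cfg
}
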