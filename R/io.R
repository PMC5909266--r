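SCAN_COLUMNS <- c("time_s", "marker1_ap_mm", "marker2_ap_mm", "marker3_ap_mm",
                  "target_lr_mm", "target_si_mm", "target_ap_mm")

sidecar_path <- function(path) sub("\\.csv$", ".yaml", path)

#' Write a scan to CSV with a YAML metadata sidecar
#'
#' One row per sample with the fixed column order
#' `time_s, marker1_ap_mm, ..., target_ap_mm` (6 decimal places) and a
#' sidecar `<name>.yaml` holding `scan_id`, `acquired_at` (ISO-8601, UTC)
#' and `dt`.
#'
#' @param scan An `rm_scan`.
#' @param path Output CSV path (the sidecar replaces `.csv` with `.yaml`).
#' @return The CSV path, invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "rm_scan"))
  sm <- surrogate_matrix(scan)
  tm <- target_matrix(scan)
  df <- data.frame(
    time_s = round((seq_len(scan$n_samples) - 1) * scan$dt, 6),
    marker1_ap_mm = round(sm[, 1], 6), marker2_ap_mm = round(sm[, 2], 6),
    marker3_ap_mm = round(sm[, 3], 6),
    target_lr_mm = round(tm[, "LR"], 6), target_si_mm = round(tm[, "SI"], 6),
    target_ap_mm = round(tm[, "AP"], 6)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    scan_id = scan$scan_id,
    acquired_at = format(as.POSIXct(scan$acquired_at, origin = "1970-01-01", tz = "UTC"),
                         "%Y-%m-%dT%H:%M:%OS1Z"),
    dt = scan$dt
  )
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a scan from CSV (plus optional YAML sidecar)
#'
#' Validates the schema: all seven columns present, no missing/NaN values
#' (the offending row and column are named), timestamps uniform to 1e-6 s.
#' Metadata defaults (`scan_id` from the file name, `acquired_at = 0`) are
#' applied when no sidecar exists.
#'
#' @param path CSV path as written by [write_scan()].
#' @return An `rm_scan`.
#' @export
read_scan <- function(path) {
  if (!file.exists(path)) err_parse(sprintf("scan file '%s' does not exist", path))
  df <- read.csv(path)
  missing_cols <- setdiff(SCAN_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    err_parse(sprintf("scan file '%s' is missing column(s): %s",
                      path, paste(missing_cols, collapse = ", ")))
  }
  for (col in SCAN_COLUMNS) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0) {
      err_parse(sprintf("scan file '%s': missing or non-finite value in column '%s', row %d",
                        path, col, bad[1]))
    }
  }
  if (nrow(df) < 4) err_parse(sprintf("scan file '%s' has too few rows", path))
  dts <- diff(df$time_s)
  if (max(dts) - min(dts) > 1e-6) {
    err_parse(sprintf("scan file '%s': non-uniform timestamps (spread %.2g s)",
                      path, max(dts) - min(dts)))
  }
  meta <- list(scan_id = sub("\\.csv$", "", basename(path)), acquired_at = 0,
               dt = mean(dts))
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- modifyList(meta, yaml::read_yaml(sp))
    if (is.character(meta$acquired_at)) {
      meta$acquired_at <- as.numeric(as.POSIXct(meta$acquired_at,
                                                format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"))
    }
  }
  surr <- lapply(1:3, function(i) {
    new_surrogate_trace(i, df[[paste0("marker", i, "_ap_mm")]], meta$dt)
  })
  targ <- new_target_trace(cbind(df$target_lr_mm, df$target_si_mm, df$target_ap_mm), meta$dt)
  new_scan(meta$scan_id, surr, targ, acquired_at = meta$acquired_at)
}

#' Serialize an estimation model to YAML
#'
#' Quadratic models store the nine `(a, b, c, d, e)` quintuples, `T_M` and
#' the source scan id; phase-linear models store the eight phase averages,
#' per-branch slopes/intercepts and the centroid.
#'
#' @param model An `rm_quadratic_model` or `rm_phase_linear_model`.
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- if (inherits(model, "rm_quadratic_model")) {
    list(
      kind = "quadratic", t_m_s = model$T_M, dt_s = model$dt,
      source_scan_id = model$source_scan_id,
      coefficients = setNames(lapply(1:3, function(i) {
        setNames(lapply(DIRECTIONS, function(d) as.list(setNames(model$coeffs[i, d, ], COEF_NAMES))),
                 DIRECTIONS)
      }), paste0("marker", 1:3))
    )
  } else if (inherits(model, "rm_phase_linear_model")) {
    list(
      kind = "phase_linear", source_scan_id = model$source_scan_id,
      w_ave_mm = as.list(model$w_ave),
      p_4dcbct_mm = setNames(lapply(DIRECTIONS, function(d) as.list(model$p_4dcbct[, d])), DIRECTIONS),
      slopes = setNames(lapply(DIRECTIONS, function(d) as.list(unname(model$slopes[, d]))), DIRECTIONS),
      intercepts_mm = setNames(lapply(DIRECTIONS, function(d) as.list(unname(model$intercepts[, d]))), DIRECTIONS),
      centroid_mm = as.list(model$centroid)
    )
  } else {
    err_invalid("unknown model kind")
  }
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read an estimation model from YAML
#'
#' @param path YAML path as written by [write_model()].
#' @return The model object.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) err_parse(sprintf("model file '%s' does not exist", path))
  obj <- yaml::read_yaml(path)
  if (identical(obj$kind, "quadratic")) {
    coeffs <- array(NA_real_, dim = c(3, 3, 5),
                    dimnames = list(paste0("marker", 1:3), DIRECTIONS, COEF_NAMES))
    for (i in 1:3) for (d in DIRECTIONS) {
      coeffs[i, d, ] <- unlist(obj$coefficients[[paste0("marker", i)]][[d]])[COEF_NAMES]
    }
    structure(list(coeffs = coeffs, T_M = obj$t_m_s, source_scan_id = obj$source_scan_id,
                   dt = obj$dt_s),
              class = "rm_quadratic_model")
  } else if (identical(obj$kind, "phase_linear")) {
    p <- vapply(DIRECTIONS, function(d) unlist(obj$p_4dcbct_mm[[d]]), numeric(8))
    fit_phase_linear(unlist(obj$w_ave_mm), p, source_scan_id = obj$source_scan_id)
  } else {
    err_parse(sprintf("model file '%s' has unknown kind '%s'", path, obj$kind))
  }
}

#' Write a drift-correction report to YAML
#'
#' @param correction An `rm_drift_correction`.
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_drift_correction <- function(correction, path) {
  stopifnot(inherits(correction, "rm_drift_correction"))
  obj <- list(
    t_c_s = correction$T_C, anchor = correction$anchor,
    model_kind = correction$model_kind,
    scan_a = correction$scan_a_id, scan_b = correction$scan_b_id,
    bd_ir_mm = as.list(correction$bd_ir),
    bd_target_mm = if (is.matrix(correction$bd_target)) {
      setNames(lapply(1:3, function(i) as.list(correction$bd_target[i, ])), paste0("marker", 1:3))
    } else {
      as.list(correction$bd_target)
    }
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Default run configuration
#'
#' The grids and switches of the evaluation pipeline, with the standard
#' defaults: `T_M` in \{5, 10, 15, 25, 35\} s, `T_C` in \{5, 10, 15\} s
#' (applied only where `T_C <= T_M`), `dt = 0.2` s, verbatim target-drift
#' anchor and the printed velocity-sign convention.
#'
#' @return Named list of configuration values.
#' @export
default_run_config <- function() {
  list(
    dt_s = 0.2,
    duration_s = 70,
    t_m_set_s = c(5, 10, 15, 25, 35),
    t_c_set_s = c(5, 10, 15),
    model_kinds = "quadratic",
    anchor = "scan_a",
    invert_breathing_sign = FALSE,
    per_marker_target_drift = FALSE,
    extrema = list(min_prominence_mm = NULL, min_separation_s = 1, smooth_width = 0),
    simulator = default_cohort_ranges(),
    n_patients = 20,
    seed = 1
  )
}

#' Read (and validate) a run configuration
#'
#' Reads a YAML configuration, fills unset keys from
#' [default_run_config()], applies overrides (e.g. command-line flags) and
#' validates the grids: all periods must be positive multiples of `dt` and
#' every `T_C` must be feasible for at least the largest `T_M`.
#'
#' @param path YAML configuration path, or `NULL` for pure defaults.
#' @param overrides Named list taking precedence over the file.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) err_parse(sprintf("config file '%s' does not exist", path))
    cfg <- modifyList(cfg, yaml::read_yaml(path))
  }
  cfg <- modifyList(cfg, overrides)
  for (T in c(cfg$t_m_set_s, cfg$t_c_set_s)) period_steps(T, cfg$dt_s)
  if (any(cfg$t_c_set_s > max(cfg$t_m_set_s))) {
    err_invalid("every T_C must be <= the largest T_M in the grid")
  }
  if (!cfg$anchor %in% c("scan_a", "scan_b")) err_invalid("anchor must be scan_a or scan_b")
  if (!all(cfg$model_kinds %in% c("quadratic", "phase_linear"))) {
    err_invalid("model_kinds must be a subset of {quadratic, phase_linear}")
  }
  cfg
}
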