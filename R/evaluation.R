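#' Root-mean-square error in one direction
#'
#' @param estimated,actual Numeric vectors of equal length (mm).
#' @return RMSE in mm.
#' @export
rmse <- function(estimated, actual) {
  if (length(estimated) != length(actual) || length(estimated) < 1) {
    err_invalid("estimated and actual must have equal length >= 1")
  }
  sqrt(mean((estimated - actual)^2))
}

#' 3D root-mean-square error
#'
#' The sample-wise Euclidean error aggregated as
#' `sqrt(mean(||e_k||^2))`; algebraically this equals
#' `sqrt(rmse_LR^2 + rmse_SI^2 + rmse_AP^2)`.
#'
#' @param estimated,actual Numeric `n x 3` matrices (mm).
#' @return 3D RMSE in mm.
#' @export
rmse_3d <- function(estimated, actual) {
  estimated <- as.matrix(estimated); actual <- as.matrix(actual)
  if (!all(dim(estimated) == dim(actual)) || ncol(estimated) != 3 || nrow(estimated) < 1) {
    err_invalid("estimated and actual must be n x 3 matrices of equal size")
  }
  sqrt(mean(rowSums((estimated - actual)^2)))
}

#' Assemble an RMSE report for one estimation run
#'
#' Computes per-direction and 3D RMSEs and asserts the decomposition
#' identity `rmse_3d^2 == sum(rmse_dir^2)` (to 1e-9 relative) at
#' construction.
#'
#' @param estimated,actual Numeric `n x 3` matrices (mm), columns LR/SI/AP.
#' @param scenario `"intra"` or `"inter"`.
#' @param model_kind `"quadratic"` or `"phase_linear"`.
#' @param T_M Modeling period label (seconds, or `"4D-CBCT"`).
#' @param T_C Correction period in seconds, or `NA` when uncorrected.
#' @param corrected Logical drift-correction flag.
#' @param anchor Drift anchor used (`NA` when uncorrected).
#' @param scan_a,scan_b Scan ids.
#' @param elapsed_min Elapsed time between scans in minutes (`NA` intra).
#' @return An object of class `rm_rmse_report`.
#' @export
rmse_report <- function(estimated, actual, scenario, model_kind, T_M,
                        T_C = NA_real_, corrected = FALSE, anchor = NA_character_,
                        scan_a = NA_character_, scan_b = NA_character_,
                        elapsed_min = NA_real_) {
  per_dir <- vapply(1:3, function(j) rmse(estimated[, j], actual[, j]), numeric(1))
  names(per_dir) <- DIRECTIONS
  r3d <- rmse_3d(estimated, actual)
  if (abs(r3d^2 - sum(per_dir^2)) > 1e-9 * max(1, r3d^2)) {
    err_invalid("RMSE decomposition identity violated")  # unreachable unless NA/Inf
  }
  structure(
    list(rmse = per_dir, rmse_3d = r3d, scenario = scenario,
         model_kind = model_kind, T_M = T_M, T_C = T_C, corrected = corrected,
         anchor = anchor, scan_a = scan_a, scan_b = scan_b,
         elapsed_min = elapsed_min, n = nrow(estimated)),
    class = "rm_rmse_report"
  )
}

#' @export
print.rm_rmse_report <- function(x, ...) {
  cat(sprintf("<rm_rmse_report>  %s, %s model, T_M = %s%s%s\n",
              x$scenario, x$model_kind, as.character(x$T_M),
              if (!is.na(x$T_C)) sprintf(", T_C = %g s", x$T_C) else "",
              if (isTRUE(x$corrected)) " (drift-corrected)" else ""))
  cat(sprintf("  RMSE LR/SI/AP (mm): %s;  3D: %.3f mm over %d samples\n",
              paste(sprintf("%.3f", x$rmse), collapse = ", "), x$rmse_3d, x$n))
  invisible(x)
}

#' @export
as.data.frame.rm_rmse_report <- function(x, ...) {
  data.frame(
    scenario = x$scenario, model_kind = x$model_kind,
    T_M_s = as.character(x$T_M),
    T_C_s = x$T_C, corrected = x$corrected, anchor = x$anchor,
    scan_a = x$scan_a, scan_b = x$scan_b,
    rmse_lr_mm = unname(x$rmse["LR"]), rmse_si_mm = unname(x$rmse["SI"]),
    rmse_ap_mm = unname(x$rmse["AP"]), rmse_3d_mm = x$rmse_3d,
    elapsed_min = x$elapsed_min, n = x$n,
    stringsAsFactors = FALSE
  )
}

# Fit whichever model kind over whichever T_M on a source scan.
fit_model_for <- function(scan, model_kind, T_M, ...) {
  if (model_kind == "quadratic") {
    fit_quadratic_model(scan, T_M)
  } else {
    pa <- simulate_phase_averages(scan, ...)
    fit_phase_linear(pa$w_ave, pa$p_4dcbct, source_scan_id = scan$scan_id)
  }
}

#' Intra-scan estimation
#'
#' Trains the model on the modeling session of a scan (the last `T_M`
#' seconds; `T_M = 70` trains on the whole scan, a deliberately leaky
#' comparator) and evaluates on the validating session of the same scan.
#' For the phase-linear comparator the phase averages come from the whole
#' scan (also leaky, as in the reference workflow) and `T_M` is ignored.
#'
#' @param scan An `rm_scan`.
#' @param model_kind `"quadratic"` or `"phase_linear"`.
#' @param T_M Modeling period in seconds (quadratic model).
#' @param invert_breathing_sign Passed to phase-linear prediction.
#' @param ... Passed to [detect_extrema()] for phase averaging.
#' @return An `rm_rmse_report`.
#' @export
intra_scan <- function(scan, model_kind = c("quadratic", "phase_linear"), T_M = 10,
                       invert_breathing_sign = FALSE, ...) {
  model_kind <- match.arg(model_kind)
  split <- split_sessions(scan)
  model <- fit_model_for(scan, model_kind, T_M, ...)
  est <- predict_scan(model, scan, split$validating,
                      invert_breathing_sign = invert_breathing_sign)
  actual <- target_matrix(scan)[split$validating, , drop = FALSE]
  rmse_report(est, actual, scenario = "intra", model_kind = model_kind,
              T_M = if (model_kind == "quadratic") T_M else "4D-CBCT",
              scan_a = scan$scan_id, scan_b = scan$scan_id)
}

#' Inter-scan estimation
#'
#' Trains the model on scan A's modeling session and evaluates on scan B's
#' validating session, optionally after median baseline-drift correction
#' of surrogate and target with correction period `T_C` (which must not
#' exceed `T_M` for the quadratic model).
#'
#' @param scan_a Model source scan.
#' @param scan_b Estimation target scan.
#' @inheritParams intra_scan
#' @param T_C Correction period in seconds (required when `corrected`).
#' @param corrected Apply baseline-drift correction.
#' @param anchor Target-drift anchor, `"scan_a"` (verbatim definition) or
#'   `"scan_b"` (removes a genuine target baseline shift).
#' @param per_marker_target_drift Compute target drift per marker before
#'   averaging (quadratic model only).
#' @return An `rm_rmse_report`.
#' @export
inter_scan <- function(scan_a, scan_b, model_kind = c("quadratic", "phase_linear"),
                       T_M = 10, T_C = NULL, corrected = FALSE,
                       anchor = c("scan_a", "scan_b"),
                       per_marker_target_drift = FALSE,
                       invert_breathing_sign = FALSE, ...) {
  model_kind <- match.arg(model_kind)
  anchor <- match.arg(anchor)
  model <- fit_model_for(scan_a, model_kind, T_M, ...)
  split_b <- split_sessions(scan_b)
  if (corrected) {
    if (is.null(T_C)) err_invalid("corrected estimation requires T_C")
    corr <- compute_drift_correction(model, scan_a, scan_b, T_C, anchor = anchor,
                                     per_marker_target_drift = per_marker_target_drift,
                                     invert_breathing_sign = invert_breathing_sign)
    est <- apply_corrected(model, scan_b, corr, split_b$validating,
                           invert_breathing_sign = invert_breathing_sign)
  } else {
    est <- predict_scan(model, scan_b, split_b$validating,
                        invert_breathing_sign = invert_breathing_sign)
  }
  actual <- target_matrix(scan_b)[split_b$validating, , drop = FALSE]
  rmse_report(est, actual, scenario = "inter", model_kind = model_kind,
              T_M = if (model_kind == "quadratic") T_M else "4D-CBCT",
              T_C = if (corrected) T_C else NA_real_, corrected = corrected,
              anchor = if (corrected) anchor else NA_character_,
              scan_a = scan_a$scan_id, scan_b = scan_b$scan_id,
              elapsed_min = abs(scan_b$acquired_at - scan_a$acquired_at) / 60)
}

#' Five-number boxplot summary (Tukey convention)
#'
#' Median and quartiles by linear interpolation (quantile type 7); whiskers
#' at the most extreme data points within 1.5 IQR of the quartiles;
#' everything beyond is an outlier.
#'
#' @param values Nonempty numeric vector.
#' @return List with `median`, `q25`, `q75`, `whisker_lo`, `whisker_hi`,
#'   `outliers`, `n`.
#' @export
box_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || any(!is.finite(values))) {
    err_invalid("values must be a nonempty finite numeric vector")
  }
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  list(median = q[2], q25 = q[1], q75 = q[3],
       whisker_lo = min(inside), whisker_hi = max(inside),
       outliers = sort(values[values < lo_fence | values > hi_fence]),
       n = length(values))
}

#' Sweep the modeling/correction-period grid over scan pairs
#'
#' Evaluates every scan pair in both estimation directions (A to B and
#' B to A) over the grid of modeling periods `T_M_set`, uncorrected and
#' corrected at every feasible correction period (`T_C <= T_M`; infeasible
#' cells are skipped, not errored). The phase-linear comparator, when
#' requested, is evaluated uncorrected and at every `T_C` under the label
#' `T_M = "4D-CBCT"`. Per-cell failures (e.g. degenerate fits on
#' pathological scans) are caught, counted and excluded.
#'
#' @param pairs List of scan pairs: elements with `scan_a`/`scan_b`
#'   entries, e.g. cohort entries from [simulate_cohort()].
#' @param T_M_set Modeling periods in seconds.
#' @param T_C_set Correction periods in seconds.
#' @param model_kinds Subset of `c("quadratic", "phase_linear")`.
#' @param anchor Target-drift anchor for corrected cells.
#' @param invert_breathing_sign,per_marker_target_drift See [inter_scan()].
#' @return An object of class `rm_grid_summary`: list with `results` (long
#'   `data.frame`, one row per evaluation), `summary` (per-cell box
#'   statistics of the 3D RMSE), `failures` (`data.frame` of skipped
#'   cells) and `n_failed`.
#' @export
grid_sweep <- function(pairs, T_M_set = c(5, 10, 15, 25, 35), T_C_set = c(5, 10, 15),
                       model_kinds = "quadratic", anchor = "scan_a",
                       invert_breathing_sign = FALSE,
                       per_marker_target_drift = FALSE) {
  if (length(pairs) == 0) err_invalid("no scan pairs supplied")
  model_kinds <- match.arg(model_kinds, c("quadratic", "phase_linear"), several.ok = TRUE)
  rows <- list()
  fails <- list()
  run_cell <- function(sa, sb, kind, tm, tc, corrected) {
    rep <- tryCatch(
      suppressWarnings(inter_scan(sa, sb, model_kind = kind, T_M = tm, T_C = tc,
                                  corrected = corrected, anchor = anchor,
                                  per_marker_target_drift = per_marker_target_drift,
                                  invert_breathing_sign = invert_breathing_sign)),
      respmotion_error = function(e) e
    )
    if (inherits(rep, "rm_rmse_report")) {
      rows[[length(rows) + 1L]] <<- as.data.frame(rep)
    } else {
      fails[[length(fails) + 1L]] <<- data.frame(
        scan_a = sa$scan_id, scan_b = sb$scan_id, model_kind = kind,
        T_M_s = if (kind == "quadratic") as.character(tm) else "4D-CBCT",
        T_C_s = if (is.null(tc)) NA_real_ else tc, corrected = corrected,
        message = conditionMessage(rep), stringsAsFactors = FALSE
      )
    }
  }
  for (pair in pairs) {
    for (ord in list(c("scan_a", "scan_b"), c("scan_b", "scan_a"))) {
      sa <- pair[[ord[1]]]; sb <- pair[[ord[2]]]
      for (kind in model_kinds) {
        if (kind == "quadratic") {
          for (tm in T_M_set) {
            run_cell(sa, sb, kind, tm, NULL, FALSE)
            for (tc in T_C_set[T_C_set <= tm]) run_cell(sa, sb, kind, tm, tc, TRUE)
          }
        } else {
          run_cell(sa, sb, kind, NA, NULL, FALSE)
          for (tc in T_C_set) run_cell(sa, sb, kind, NA, tc, TRUE)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(scan_a = character(0), scan_b = character(0), model_kind = character(0),
               T_M_s = character(0), T_C_s = numeric(0), corrected = logical(0),
               message = character(0), stringsAsFactors = FALSE)
  cells <- unique(results[, c("model_kind", "T_M_s", "T_C_s", "corrected")])
  summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(j) {
    sel <- results$model_kind == cells$model_kind[j] &
      results$T_M_s == cells$T_M_s[j] &
      (is.na(results$T_C_s) == is.na(cells$T_C_s[j])) &
      (is.na(cells$T_C_s[j]) | results$T_C_s %in% cells$T_C_s[j]) &
      results$corrected == cells$corrected[j]
    b <- box_summary(results$rmse_3d_mm[sel])
    data.frame(cells[j, , drop = FALSE],
               median_mm = b$median, q25_mm = b$q25, q75_mm = b$q75,
               whisker_lo_mm = b$whisker_lo, whisker_hi_mm = b$whisker_hi,
               outlier_count = length(b$outliers), n = b$n,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(results = results, summary = summ, failures = failures,
                 n_failed = nrow(failures)),
            class = "rm_grid_summary")
}

#' @export
print.rm_grid_summary <- function(x, ...) {
  cat(sprintf("<rm_grid_summary>  %d evaluations, %d failed cells\n",
              nrow(x$results), x$n_failed))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Boxplot of 3D RMSE per modeling period
#'
#' A basic boxplot of the grid-sweep distributions (one box per `T_M`),
#' drawn from the per-cell Tukey statistics.
#'
#' @param grid An `rm_grid_summary`.
#' @param corrected Show drift-corrected (`TRUE`) or uncorrected cells.
#' @param T_C Correction period of the corrected cells to show.
#' @param ... Passed to [graphics::bxp()].
#' @return Invisibly, the matrix of box statistics.
#' @export
plot_grid_summary <- function(grid, corrected = TRUE, T_C = 10, ...) {
  stopifnot(inherits(grid, "rm_grid_summary"))
  r <- grid$results
  sel <- if (corrected) r$corrected & !is.na(r$T_C_s) & r$T_C_s == T_C else !r$corrected
  r <- r[sel, , drop = FALSE]
  if (nrow(r) == 0) err_invalid("no grid cells match the requested selection")
  tms <- unique(r$T_M_s)
  stats <- vapply(tms, function(tm) {
    b <- box_summary(r$rmse_3d_mm[r$T_M_s == tm])
    c(b$whisker_lo, b$q25, b$median, b$q75, b$whisker_hi)
  }, numeric(5))
  graphics::bxp(list(stats = stats, n = table(r$T_M_s)[tms], names = tms),
                ylab = "3D RMSE (mm)", xlab = "T_M (s)", ...)
  invisible(stats)
}
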