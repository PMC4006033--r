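# Calibration of the listener-specific uncertainty U: sweep U over a grid
# (default 0.1 to 4.0 in steps of 0.1), predict aggregate PE and QE for
# the listener's own DTFs at each U, and pick the U minimizing the squared
# residual to the actual performance.

#' Default calibration grid for U
#' @export
default_u_grid <- function() seq(0.1, 4.0, by = 0.1)

#' Predicted performance as a function of U
#'
#' For each uncertainty on the grid, aggregate predicted PE and QE over
#' the given targets using `listener_dtf` for the incoming sound and
#' `template_dtf` for the template set (normally the same set: complete
#' calibration). Both curves are non-decreasing in U: larger uncertainty
#' flattens the PMVs.
#'
#' @param listener_dtf,template_dtf [dtf_set()]s.
#' @param targets data.frame with `lateral`, `polar` columns (defaults to
#'   the full grid within +/-30 deg lateral).
#' @param U_grid uncertainties to sweep.
#' @param config a [model_config()].
#' @return data.frame with columns `U`, `PE`, `QE`.
#' @export
performance_curve <- function(listener_dtf, template_dtf = listener_dtf,
                              targets = NULL, U_grid = default_u_grid(),
                              config = model_config()) {
  if (any(U_grid <= 0)) stop("U grid must be positive", call. = FALSE)
  if (is.null(targets)) targets <- .default_targets(config)
  if (!identical(listener_dtf, template_dtf)) {
    # mismatched sets: fall back to the general (slower) per-target path
    scores <- lapply(U_grid, function(U) {
      per <- lapply(seq_len(nrow(targets)), function(i)
        predicted_scores(predict_pmv(targets[i, ], listener_dtf, template_dtf,
                                     U, config), targets$polar[i]))
      aggregate_scores(per)
    })
    return(data.frame(U = U_grid,
                      PE = vapply(scores, `[[`, numeric(1), "PE"),
                      QE = vapply(scores, `[[`, numeric(1), "QE")))
  }
  pre <- .seg_pre(listener_dtf, config)
  .performance_over_U(pre, targets, U_grid, config)
}

#' Calibrate the uncertainty of a listener
#'
#' Actual PE/QE are computed from the response set (lateral +/-30 deg);
#' predicted PE/QE are computed at every grid U for the actual target
#' directions; the selected `U_k` minimizes
#' `(PE_pred - PE_act)^2 + (QE_pred - QE_act)^2` with PE in degrees and
#' QE in percent entered unweighted. Ties resolve to the smaller U.
#'
#' @param rs a [response_set()].
#' @param dtf the listener's [dtf_set()].
#' @param U_grid uncertainties to sweep.
#' @param config a [model_config()].
#' @return object of class `calibration_result`: list with `U_grid`,
#'   `residuals`, `U_k`, `predicted_at_U_k` ([performance_scores()]),
#'   `actual` and the full `curve`.
#' @export
calibrate_uncertainty <- function(rs, dtf, U_grid = default_u_grid(),
                                  config = model_config()) {
  stopifnot(inherits(rs, "response_set"), inherits(dtf, "dtf_set"))
  act <- actual_scores(rs)
  tr <- rs$trials[abs(rs$trials$target_lateral) <= 30, , drop = FALSE]
  targets <- data.frame(lateral = tr$target_lateral, polar = tr$target_polar)
  curve <- performance_curve(dtf, dtf, targets, U_grid, config)
  pe_res <- ifelse(is.na(curve$PE) | is.na(act$PE), 0, (curve$PE - act$PE)^2)
  res <- pe_res + (curve$QE - act$QE)^2
  k <- which.min(res)   # ties: first = smallest U on an ascending grid
  structure(list(U_grid = U_grid, residuals = res, U_k = U_grid[k],
                 predicted_at_U_k = performance_scores(curve$PE[k], curve$QE[k]),
                 actual = act, curve = curve,
                 residual_weighting = "unweighted PE^2 + QE^2"),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration: U_k = %.2f (residual %.3f)\n", x$U_k,
              min(x$residuals)))
  cat(sprintf("  actual    PE = %5.2f deg, QE = %5.2f %%\n",
              x$actual$PE, x$actual$QE))
  cat(sprintf("  predicted PE = %5.2f deg, QE = %5.2f %%\n",
              x$predicted_at_U_k$PE, x$predicted_at_U_k$QE))
  invisible(x)
}

#' Serialize a calibration result to JSON
#'
#' @param x a `calibration_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(x, path) {
  stopifnot(inherits(x, "calibration_result"))
  jsonlite::write_json(list(
    U_grid = x$U_grid, residuals = x$residuals, U_k = x$U_k,
    predicted = list(PE = x$predicted_at_U_k$PE, QE = x$predicted_at_U_k$QE),
    actual = list(PE = x$actual$PE, QE = x$actual$QE),
    residual_weighting = x$residual_weighting),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
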