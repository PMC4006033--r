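# Factor analysis: permute the calibrated uncertainties U_k (non-acoustic
# factor) and DTF sets D_k (acoustic factor) across a listener group, and
# quantify how much predicted performance varies along each factor.  The
# permutation grid entry (i, j) uses DTF set i for BOTH the incoming sound
# and the template set (complete re-calibration) with uncertainty j; rows
# and columns are sorted by ascending calibrated U.

#' Permutation grid of DTF sets and uncertainties
#'
#' @param group list of [listener_model()]s with calibrated uncertainties.
#' @param targets target data.frame (default: full grid, lateral
#'   +/-30 deg).
#' @param config a [model_config()].
#' @return object of class `permutation_grid`: `listener_order` (ids
#'   sorted by ascending U), `U` (sorted uncertainties), `PE_matrix` and
#'   `QE_matrix` (K x K; rows = DTF set, columns = uncertainty).
#' @export
permutation_grid <- function(group, targets = NULL, config = model_config()) {
  if (length(group) < 2) stop("need at least 2 listeners", call. = FALSE)
  U <- vapply(group, function(l) l$uncertainty, numeric(1))
  if (any(is.na(U)))
    stop("all listeners must be calibrated (finite uncertainty)", call. = FALSE)
  ord <- order(U)
  group <- group[ord]; U <- U[ord]
  ids <- vapply(group, function(l) l$dtf$listener_id, character(1))
  if (is.null(targets)) targets <- .default_targets(config)
  K <- length(group)
  PE <- QE <- matrix(NA_real_, K, K, dimnames = list(DTF = ids, U = ids))
  for (i in seq_len(K)) {
    pre <- .seg_pre(group[[i]]$dtf, config)
    curve <- .performance_over_U(pre, targets, U, config)
    PE[i, ] <- curve$PE
    QE[i, ] <- curve$QE
  }
  structure(list(listener_order = ids, U = U, PE_matrix = PE, QE_matrix = QE),
            class = "permutation_grid")
}

#' @export
print.permutation_grid <- function(x, ...) {
  K <- length(x$listener_order)
  cat(sprintf("Permutation grid over %d listeners (U from %.2f to %.2f)\n",
              K, min(x$U), max(x$U)))
  cat(sprintf("  baseline (diagonal) PE: %.1f-%.1f deg, QE: %.1f-%.1f %%\n",
              min(diag(x$PE_matrix)), max(diag(x$PE_matrix)),
              min(diag(x$QE_matrix)), max(diag(x$QE_matrix))))
  invisible(x)
}

#' Performance relative to the listener-specific baseline
#'
#' `Delta(i, j) = entry(i, j) - diagonal(j)`: the change a listener with
#' uncertainty U_j would experience when fully re-calibrated to DTF set
#' D_i. Averaged over all uncertainties per DTF set; positive means the
#' DTF set degrades the group's performance.
#'
#' @param grid a [permutation_grid()].
#' @return data.frame with one row per DTF set: `listener_id`,
#'   `dPE_mean`, `dPE_sd`, `dQE_mean`, `dQE_sd`.
#' @export
relative_performance <- function(grid) {
  stopifnot(inherits(grid, "permutation_grid"))
  dPE <- sweep(grid$PE_matrix, 2, diag(grid$PE_matrix))
  dQE <- sweep(grid$QE_matrix, 2, diag(grid$QE_matrix))
  data.frame(listener_id = grid$listener_order,
             dPE_mean = rowMeans(dPE), dPE_sd = apply(dPE, 1, stats::sd),
             dQE_mean = rowMeans(dQE), dQE_sd = apply(dQE, 1, stats::sd),
             row.names = NULL)
}

#' Per-factor standard deviations of the permutation grid
#'
#' Two SD families per performance metric: across each row (own DTFs,
#' uncertainty varied -- the non-acoustic factor) and across each column
#' (own uncertainty, DTF set varied -- the acoustic factor), plus their
#' group means/SDs and the mean ratio. A ratio above 1 means uncertainty
#' moves predictions more than the DTF set does.
#'
#' @param grid a [permutation_grid()].
#' @return object of class `factor_contribution`: per-listener
#'   `sd_over_U` / `sd_over_D` for PE and QE, a `summary` data.frame and
#'   `ratio` (list with `PE`, `QE`).
#' @export
factor_sds <- function(grid) {
  stopifnot(inherits(grid, "permutation_grid"))
  out <- list(listener_order = grid$listener_order)
  for (m in c("PE", "QE")) {
    M <- grid[[paste0(m, "_matrix")]]
    out[[paste0("sd_over_U_", m)]] <- apply(M, 1, stats::sd)  # row: U varied
    out[[paste0("sd_over_D_", m)]] <- apply(M, 2, stats::sd)  # col: DTF varied
  }
  out$summary <- data.frame(
    metric = rep(c("PE", "QE"), each = 2),
    factor = rep(c("uncertainty", "dtf_set"), 2),
    mean_sd = c(mean(out$sd_over_U_PE), mean(out$sd_over_D_PE),
                mean(out$sd_over_U_QE), mean(out$sd_over_D_QE)),
    sd_sd = c(stats::sd(out$sd_over_U_PE), stats::sd(out$sd_over_D_PE),
              stats::sd(out$sd_over_U_QE), stats::sd(out$sd_over_D_QE)))
  out$ratio <- list(PE = mean(out$sd_over_U_PE) / mean(out$sd_over_D_PE),
                    QE = mean(out$sd_over_U_QE) / mean(out$sd_over_D_QE))
  structure(out, class = "factor_contribution")
}

#' @export
print.factor_contribution <- function(x, ...) {
  cat("Factor contributions (group mean SD +/- SD):\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s, %-11s varied: %5.2f +/- %.2f\n",
                s$metric[i], s$factor[i], s$mean_sd[i], s$sd_sd[i]))
  cat(sprintf("  ratio uncertainty/DTF: PE %.2f, QE %.2f\n",
              x$ratio$PE, x$ratio$QE))
  invisible(x)
}

#' Pearson correlation coefficient
#'
#' Product-moment correlation computed from first principles (used as one
#' route of a dual implementation/oracle check).
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) stop("zero variance", call. = FALSE)
  sum(dx * dy) / (sx * sy)
}

#' Predictions under listener-constant parameterizations
#'
#' Evaluates the group with one parameter held constant: either a single
#' uncertainty for everyone (own DTFs; `mode = "constant_U"`) or a single
#' DTF set for everyone (own uncertainties; `mode = "constant_DTF"`),
#' and correlates the predictions with the actual per-listener scores.
#' Probe values from the real-data study: U = 2.89 (best PE correlation),
#' 1.87 (best QE correlation), 2.0 (literature value).
#'
#' @param group list of [listener_model()]s (calibrated).
#' @param actual list of [performance_scores()], one per group member (in
#'   group order).
#' @param mode `"constant_U"` or `"constant_DTF"`.
#' @param value for `constant_U`: the shared uncertainty; for
#'   `constant_DTF`: the listener id whose DTF set everyone borrows.
#' @param targets,config as elsewhere.
#' @return list with `predicted` (data.frame id/PE/QE), `r_PE`, `r_QE`,
#'   `group_sd` (SD of predicted PE and QE across listeners).
#' @export
constant_parameter_eval <- function(group, actual,
                                    mode = c("constant_U", "constant_DTF"),
                                    value, targets = NULL,
                                    config = model_config()) {
  mode <- match.arg(mode)
  K <- length(group)
  if (K < 3) stop("need at least 3 listeners for correlations", call. = FALSE)
  if (length(actual) != K) stop("one actual score set per listener", call. = FALSE)
  if (is.null(targets)) targets <- .default_targets(config)
  ids <- vapply(group, function(l) l$dtf$listener_id, character(1))
  if (mode == "constant_U") {
    if (!is.numeric(value) || value <= 0) stop("constant U must be > 0", call. = FALSE)
    pred <- lapply(group, function(l) {
      pre <- .seg_pre(l$dtf, config)
      .performance_over_U(pre, targets, value, config)
    })
  } else {
    if (!value %in% ids) stop("unknown listener id for constant DTF", call. = FALSE)
    dtf <- group[[match(value, ids)]]$dtf
    pre <- .seg_pre(dtf, config)
    pred <- lapply(group, function(l)
      .performance_over_U(pre, targets, l$uncertainty, config))
  }
  pdf <- data.frame(listener_id = ids,
                    PE = vapply(pred, function(p) p$PE[1], numeric(1)),
                    QE = vapply(pred, function(p) p$QE[1], numeric(1)))
  aPE <- vapply(actual, function(s) s$PE, numeric(1))
  aQE <- vapply(actual, function(s) s$QE, numeric(1))
  list(mode = mode, value = value, predicted = pdf,
       r_PE = pearson(aPE, pdf$PE), r_QE = pearson(aQE, pdf$QE),
       group_sd = c(PE = stats::sd(pdf$PE), QE = stats::sd(pdf$QE)))
}
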