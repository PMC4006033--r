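# Internal fast path.  Under complete calibration the incoming sound and
# the template set are filtered by the same DTF set, so all inter-spectral
# distances reduce to pairwise template distances, which are independent of
# the uncertainty U.  Precomputing the squared-distance matrices per
# sagittal segment makes sweeps over U (calibration grids, permutation
# matrices) cheap.

# sd(x_i - x_j) for all column pairs of a bands x n matrix, via
# var(x_i) + var(x_j) - 2 cov(x_i, x_j); returns the SQUARED distances.
.pairwise_sqdist <- function(m) {
  C <- stats::cov(m)
  v <- diag(C)
  d2 <- outer(v, v, "+") - 2 * C
  d2[d2 < 0] <- 0
  d2
}

# Per-segment precomputation for one DTF set: template set plus squared
# pairwise distance matrices per ear.
.seg_pre <- function(dtf, config) {
  pre <- list()
  for (seg in config$lateral_segments) {
    has <- any(abs(dtf$directions$lateral - seg) <= 10)
    if (!has) next
    tpl <- build_template_set(dtf, seg, config$spec)
    pre[[as.character(seg)]] <- list(
      tpl = tpl,
      d2l = .pairwise_sqdist(tpl$left),
      d2r = .pairwise_sqdist(tpl$right))
  }
  if (length(pre) == 0) stop("DTF set covers no configured segment", call. = FALSE)
  pre
}

# PMV matrix (templates x length(U)) for one target given the segment
# precomputation: row `it` of the distance matrices, Gaussian similarity
# per U, binaural combination, column normalization.
.pmv_over_U <- function(ps, it, lat, U, phi) {
  w <- binaural_weights(lat, phi)
  sl <- exp(-outer(ps$d2l[it, ], 1 / (2 * U^2)))
  sr <- exp(-outer(ps$d2r[it, ], 1 / (2 * U^2)))
  si <- w[["left"]] * sl + w[["right"]] * sr
  sweep(si, 2, colSums(si), "/")
}

# Aggregate predicted PE/QE over a target list for each U in U_grid.
# `targets` is a data.frame(lateral, polar); duplicated targets count with
# their multiplicity (arithmetic average across all targets considered).
.performance_over_U <- function(pre, targets, U_grid, config) {
  key <- paste(targets$lateral, targets$polar)
  uk <- !duplicated(key)
  counts <- as.numeric(table(key)[key[uk]])
  ut <- targets[uk, , drop = FALSE]
  nU <- length(U_grid)
  PEm <- matrix(NA_real_, nrow(ut), nU)
  QEm <- matrix(NA_real_, nrow(ut), nU)
  for (i in seq_len(nrow(ut))) {
    seg <- config$lateral_segments[.nearest(ut$lateral[i], config$lateral_segments)]
    if (abs(ut$lateral[i] - seg) > 10 + 1e-9)
      stop(sprintf("target lateral %g deg outside configured segments", ut$lateral[i]),
           call. = FALSE)
    ps <- pre[[as.character(seg)]]
    if (is.null(ps))
      stop(sprintf("DTF set does not cover segment %g", seg), call. = FALSE)
    it <- .nearest(ut$polar[i], ps$tpl$polar)
    P <- .pmv_over_U(ps, it, ut$lateral[i], U_grid, config$binaural_phi)
    e <- polar_error(ut$polar[i], ps$tpl$polar)
    loc <- abs(e) <= 90
    QEm[i, ] <- 100 * colSums(P[!loc, , drop = FALSE])
    mloc <- colSums(P[loc, , drop = FALSE])
    pe <- sqrt(colSums(P[loc, , drop = FALSE] * e[loc]^2) / mloc)
    pe[mloc <= 0] <- NA_real_
    PEm[i, ] <- pe
  }
  PE <- apply(PEm, 2, function(col) {
    ok <- !is.na(col)
    if (!any(ok)) NA_real_ else sum(col[ok] * counts[ok]) / sum(counts[ok])
  })
  QE <- colSums(QEm * counts) / sum(counts)
  data.frame(U = U_grid, PE = PE, QE = QE)
}

#' Listener model: DTF set plus uncertainty
#'
#' @param dtf a [dtf_set()].
#' @param uncertainty calibrated (or assumed) uncertainty U, > 0.
#' @param ground_truth_U for synthetic listeners, the uncertainty used to
#'   simulate responses (NA for real data).
#' @return object of class `listener_model`.
#' @export
listener_model <- function(dtf, uncertainty, ground_truth_U = NA_real_) {
  stopifnot(inherits(dtf, "dtf_set"))
  if (!is.na(uncertainty) && uncertainty <= 0)
    stop("uncertainty must be > 0", call. = FALSE)
  structure(list(dtf = dtf, uncertainty = uncertainty,
                 ground_truth_U = ground_truth_U),
            class = "listener_model")
}

# default target list: the full direction grid within |lateral| <= 30
.default_targets <- function(config) {
  expand.grid(polar = config$polar_grid,
              lateral = config$lateral_segments)[, c("lateral", "polar")]
}
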