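# Localization performance metrics: the quadrant error (QE, percentage of
# responses -- or probability mass -- whose absolute wrapped polar error
# exceeds 90 deg) and the local polar RMS error (PE, RMS of the remaining
# polar errors).  Only targets within +/-30 deg lateral are evaluated.

#' Performance scores
#' @param PE local polar RMS error, degrees (NA when undefined).
#' @param QE quadrant error, percent.
#' @return object of class `performance_scores`.
#' @export
performance_scores <- function(PE, QE) {
  if (!is.na(PE) && PE < 0) stop("PE must be >= 0", call. = FALSE)
  if (QE < -1e-9 || QE > 100 + 1e-9) stop("QE must be in [0, 100]", call. = FALSE)
  structure(list(PE = PE, QE = QE), class = "performance_scores")
}

#' @export
print.performance_scores <- function(x, ...) {
  cat(sprintf("PE = %.2f deg, QE = %.2f %%\n", x$PE, x$QE)); invisible(x)
}

#' Actual performance scores of a response set
#'
#' Restricts to trials with |target lateral| <= `lateral_limit`, wraps
#' polar errors into (-180, 180], and computes QE as the percentage of
#' trials with |error| > 90 deg and PE as the RMS error over the rest.
#' |error| = 90 exactly counts as local. If every trial is a quadrant
#' error, PE is NA.
#'
#' @param rs a [response_set()].
#' @param lateral_limit degrees (default 30).
#' @return a [performance_scores()].
#' @export
actual_scores <- function(rs, lateral_limit = 30) {
  stopifnot(inherits(rs, "response_set"))
  tr <- rs$trials[abs(rs$trials$target_lateral) <= lateral_limit, , drop = FALSE]
  if (nrow(tr) == 0)
    stop("no trials within the lateral range", call. = FALSE)
  e <- polar_error(tr$target_polar, tr$response_polar)
  qe_mask <- abs(e) > 90
  QE <- 100 * mean(qe_mask)
  PE <- if (all(qe_mask)) NA_real_ else sqrt(mean(e[!qe_mask]^2))
  performance_scores(PE, QE)
}

#' Predicted performance scores of a PMV for one target
#'
#' QE is the total probability mass at response angles whose absolute
#' wrapped error exceeds 90 deg; PE is the root of the probability-
#' weighted mean squared error over the local (|error| <= 90 deg) angles.
#'
#' @param p a [pmv()].
#' @param target_polar target polar angle, degrees.
#' @return a [performance_scores()] (PE is NA if no local mass).
#' @export
predicted_scores <- function(p, target_polar) {
  stopifnot(inherits(p, "pmv"))
  e <- polar_error(target_polar, p$response_angles)
  local <- abs(e) <= 90
  QE <- 100 * sum(p$probabilities[!local])
  m <- sum(p$probabilities[local])
  PE <- if (m <= 0) NA_real_ else
    sqrt(sum(p$probabilities[local] * e[local]^2) / m)
  performance_scores(PE, min(QE, 100))
}

#' Aggregate scores over targets
#'
#' Arithmetic mean of PE and of QE across targets (and lateral segments).
#' Entries whose PE is NA are excluded from the PE mean but still count
#' toward the QE mean.
#'
#' @param scores list of [performance_scores()].
#' @return a [performance_scores()].
#' @export
aggregate_scores <- function(scores) {
  if (length(scores) == 0) stop("empty score list", call. = FALSE)
  pe <- vapply(scores, function(s) s$PE, numeric(1))
  qe <- vapply(scores, function(s) s$QE, numeric(1))
  PE <- if (all(is.na(pe))) NA_real_ else mean(pe, na.rm = TRUE)
  performance_scores(PE, mean(qe))
}
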