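# Comparison and spatial-mapping stages.  The distance between the internal
# representation of the incoming sound and each template is the standard
# deviation of the inter-spectral (per-band dB) differences; a Gaussian
# maps distance to a similarity index with listener-specific width U; the
# monaural similarities are combined by a binaural weighting that fades out
# the contralateral ear with lateral angle; normalization over template
# angles yields the probability mass vector (PMV) of polar responses.

#' Model configuration
#'
#' @param U_default default uncertainty (Gaussian mapping width).
#' @param binaural_phi lateral-angle scale of the binaural weighting
#'   sigmoid, degrees.
#' @param polar_grid polar template/response grid, degrees.
#' @param lateral_segments sagittal-segment centers, degrees (segments are
#'   20 degrees wide).
#' @param spec a [filterbank_spec()].
#' @return object of class `model_config`.
#' @export
model_config <- function(U_default = 2.0, binaural_phi = 13.3,
                         polar_grid = seq(-30, 210, by = 5),
                         lateral_segments = c(-20, 0, 20),
                         spec = filterbank_spec()) {
  if (U_default <= 0) stop("U_default must be > 0", call. = FALSE)
  if (binaural_phi <= 0) stop("binaural_phi must be > 0", call. = FALSE)
  structure(list(U_default = U_default, binaural_phi = binaural_phi,
                 polar_grid = polar_grid, lateral_segments = lateral_segments,
                 spec = spec),
            class = "model_config")
}

#' Inter-spectral distance between two internal representations
#'
#' Sample standard deviation (denominator N-1) of the per-band dB
#' differences. Insensitive to any constant offset, hence to overall
#' stimulus level.
#'
#' @param target,template band-magnitude vectors (dB) on the same grid.
#' @return nonnegative scalar distance, dB.
#' @export
interspectral_distance <- function(target, template) {
  if (length(target) != length(template))
    stop("band grids differ between target and template", call. = FALSE)
  stats::sd(as.numeric(target) - as.numeric(template))
}

#' Gaussian similarity index
#'
#' `SI = exp(-d^2 / (2 U^2))`; the peak value is irrelevant after PMV
#' normalization, so the zero-mean unit-peak form is used.
#'
#' @param distance nonnegative distance(s), dB.
#' @param U uncertainty, > 0.
#' @return similarity in (0, 1\].
#' @export
similarity <- function(distance, U) {
  if (any(U <= 0)) stop("U must be > 0", call. = FALSE)
  exp(-distance^2 / (2 * U^2))
}

#' Binaural weights for a lateral angle
#'
#' Logistic fade of the contralateral ear:
#' `w_left = 1 / (1 + exp(-lateral / phi))`, `w_right = 1 - w_left`
#' (positive lateral = left). At the analysis range (|lateral| <= 30 deg)
#' predictions are insensitive to moderate changes of `phi`.
#'
#' @param lateral lateral angle, degrees in \[-90, 90\].
#' @param phi sigmoid scale, degrees.
#' @return named vector `c(left = , right = )`, summing to 1.
#' @export
binaural_weights <- function(lateral, phi = 13.3) {
  if (abs(lateral) > 90) stop("lateral out of [-90, 90]", call. = FALSE)
  wl <- 1 / (1 + exp(-lateral / phi))
  c(left = wl, right = 1 - wl)
}

#' Construct a PMV
#'
#' @param response_angles polar angles, degrees, sorted.
#' @param probabilities nonnegative, summing to 1.
#' @return object of class `pmv`.
#' @export
pmv <- function(response_angles, probabilities) {
  if (length(response_angles) != length(probabilities))
    stop("angle and probability lengths differ", call. = FALSE)
  if (any(probabilities < 0)) stop("negative probability", call. = FALSE)
  s <- sum(probabilities)
  if (abs(s - 1) > 1e-10)
    stop(sprintf("probabilities sum to %.12f, not 1", s), call. = FALSE)
  structure(list(response_angles = response_angles,
                 probabilities = probabilities), class = "pmv")
}

# SD of column-differences between representation matrix T (bands x
# angles) and a target vector, for all template angles at once.
.dist_to_templates <- function(target_rep, tpl_mat) {
  d <- tpl_mat - target_rep
  sqrt(colSums((d - rep(colMeans(d), each = nrow(d)))^2) / (nrow(d) - 1))
}

# Nearest index helper (ties -> first, i.e. the smaller angle).
.nearest <- function(x, grid) which.min(abs(grid - x))

#' Predict the response PMV for one target
#'
#' For each template polar angle of the target's sagittal segment the
#' per-ear inter-spectral distance is mapped to a similarity index, the
#' monaural indices are weighted by the binaural weights of the target's
#' lateral angle and summed, and the resulting binaural similarities are
#' normalized to a probability mass vector over the template angles.
#' Targets off the template grid are assigned the nearest template.
#'
#' @param target a single-row [direction()] (or list with `lateral`,
#'   `polar`).
#' @param incoming_dtf DTF set filtering the incoming sound.
#' @param template_dtf DTF set behind the internal template set (equal to
#'   `incoming_dtf` under complete calibration).
#' @param U uncertainty, > 0.
#' @param config a [model_config()].
#' @return a [pmv()] over the segment's polar template angles.
#' @export
predict_pmv <- function(target, incoming_dtf, template_dtf = incoming_dtf,
                        U = config$U_default, config = model_config()) {
  if (U <= 0) stop("U must be > 0", call. = FALSE)
  lat <- target$lateral[1]; pol <- target$polar[1]
  seg <- config$lateral_segments[.nearest(lat, config$lateral_segments)]
  if (abs(lat - seg) > 10 + 1e-9)
    stop(sprintf("target lateral %g deg not covered by any configured segment", lat),
         call. = FALSE)
  tpl <- build_template_set(template_dtf, seg, config$spec)
  inc <- build_template_set(incoming_dtf, seg, config$spec)
  it <- .nearest(pol, inc$polar)
  w <- binaural_weights(lat, config$binaural_phi)
  dl <- .dist_to_templates(inc$left[, it], tpl$left)
  dr <- .dist_to_templates(inc$right[, it], tpl$right)
  si <- w["left"] * similarity(dl, U) + w["right"] * similarity(dr, U)
  pmv(tpl$polar, si / sum(si))
}
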