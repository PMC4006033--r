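# Peripheral processing: gammatone filterbank on the ERB-number scale,
# hair-cell stage (half-wave rectification + 2nd-order Butterworth low-pass),
# RMS averaging.  Two routes produce the same internal representation:
#   - the signal path filters an actual waveform (stochastic for noise), and
#   - the spectral path integrates a DTF magnitude spectrum against the
#     analytic filter magnitude responses (deterministic; exact for
#     stationary broadband noise, and the default everywhere).

#' Filterbank specification
#'
#' Defaults give 28 gammatone bands between 0.7 and 18 kHz at one-ERB
#' spacing, with a 1-kHz second-order Butterworth low-pass in the
#' hair-cell stage.
#'
#' @param f_low lowest center frequency, Hz.
#' @param f_high highest admissible center frequency, Hz.
#' @param spacing band spacing in ERB units.
#' @param lowpass_cutoff hair-cell low-pass cutoff, Hz.
#' @param lowpass_order hair-cell low-pass order (Butterworth).
#' @return object of class `filterbank_spec`.
#' @export
filterbank_spec <- function(f_low = 700, f_high = 18000, spacing = 1,
                            lowpass_cutoff = 1000, lowpass_order = 2) {
  if (!is.numeric(f_low) || !is.numeric(f_high) || f_low <= 0 || f_low >= f_high)
    stop("need 0 < f_low < f_high", call. = FALSE)
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  structure(list(f_low = f_low, f_high = f_high, spacing = spacing,
                 lowpass_cutoff = lowpass_cutoff,
                 lowpass_order = lowpass_order),
            class = "filterbank_spec")
}

#' ERB-number of a frequency
#'
#' Glasberg-Moore ERB-number scale: `21.4 * log10(0.00437 * f + 1)`.
#'
#' @param f frequency, Hz.
#' @return ERB-number (dimensionless).
#' @export
erb_number <- function(f) 21.4 * log10(0.00437 * f + 1)

#' Inverse of [erb_number()]
#' @param n ERB-number.
#' @return frequency, Hz.
#' @export
erb_number_inv <- function(n) (10^(n / 21.4) - 1) / 0.00437

#' Equivalent rectangular bandwidth at a frequency
#' @param f frequency, Hz.
#' @return bandwidth, Hz.
#' @export
erb_bandwidth <- function(f) 24.7 * (0.00437 * f + 1)

#' Gammatone filterbank center frequencies
#'
#' Centers are placed from `f_low` upward at `spacing` ERB-number steps,
#' never exceeding `f_high`. The default spec yields exactly 28 centers.
#'
#' @param spec a [filterbank_spec()].
#' @return increasing vector of center frequencies, Hz.
#' @export
gammatone_center_frequencies <- function(spec = filterbank_spec()) {
  stopifnot(inherits(spec, "filterbank_spec"))
  n_lo <- erb_number(spec$f_low)
  n_hi <- erb_number(spec$f_high)
  erb_number_inv(seq(n_lo, n_hi, by = spec$spacing))
}

# Squared magnitude response of a 4th-order all-pole gammatone filter,
# peak-normalized to 1 at fc. b = 1.019 * ERB(fc) (Patterson-style).
gammatone_power_response <- function(f, fc) {
  b <- 1.019 * erb_bandwidth(fc)
  (1 + ((f - fc) / b)^2)^(-4)
}

# Band-integration weight matrix for the spectral path: rows = bands,
# columns = frequency-grid points; row-normalized so that a flat power
# spectrum maps to exactly 1 per band.  Uses trapezoid df weights.
band_weight_matrix <- function(freq, spec) {
  if (min(freq) > spec$f_low || max(freq) < spec$f_high)
    stop(sprintf("frequency grid [%g, %g] Hz does not cover the filterbank range [%g, %g] Hz",
                 min(freq), max(freq), spec$f_low, spec$f_high), call. = FALSE)
  if (is.unsorted(freq, strictly = TRUE))
    stop("frequency grid must be strictly increasing", call. = FALSE)
  fc <- gammatone_center_frequencies(spec)
  df <- diff(freq)
  w <- c(df[1] / 2, (df[-1] + df[-length(df)]) / 2, df[length(df)] / 2)
  W <- t(vapply(fc, function(f0) gammatone_power_response(freq, f0) * w,
                numeric(length(freq))))
  W / rowSums(W)
}

RMS_FLOOR <- 1e-5  # -100 dB; guards log of silence

#' Internal representation from a magnitude spectrum (spectral path)
#'
#' Deterministic shortcut valid for stationary broadband noise: each band
#' magnitude is the dB power average of the spectrum weighted by the
#' band's squared gammatone magnitude response,
#' `10*log10( sum |H|^2 |G_b|^2 df / sum |G_b|^2 df )`.
#'
#' @param magnitude_db dB magnitude spectrum (vector matching `freq`, or a
#'   matrix with one column per spectrum).
#' @param freq frequency grid, Hz, strictly increasing, covering
#'   `[f_low, f_high]` of the spec.
#' @param spec a [filterbank_spec()].
#' @return vector (or matrix, one column per input spectrum) of band
#'   magnitudes in dB; attribute `band_centers` carries the center
#'   frequencies.
#' @export
internal_representation_spectral <- function(magnitude_db, freq,
                                             spec = filterbank_spec()) {
  W <- band_weight_matrix(freq, spec)
  H2 <- 10^(as.matrix(magnitude_db) / 10)
  if (nrow(H2) != length(freq))
    stop("magnitude_db length does not match frequency grid", call. = FALSE)
  p <- W %*% H2
  out <- 10 * log10(pmax(p, RMS_FLOOR^2))
  attr(out, "band_centers") <- gammatone_center_frequencies(spec)
  if (ncol(out) == 1) { bc <- attr(out, "band_centers"); out <- drop(out); attr(out, "band_centers") <- bc }
  out
}

# 2nd-order Butterworth low-pass biquad via bilinear transform.
butter2_lowpass <- function(fc, fs) {
  K <- tan(pi * fc / fs)
  norm <- 1 + sqrt(2) * K + K^2
  list(b = c(K^2, 2 * K^2, K^2) / norm,
       a = c(2 * (K^2 - 1), 1 - sqrt(2) * K + K^2) / norm)
}

iir_filter <- function(b, a, x) {
  # direct form I with zero initial conditions:
  # y[n] = sum_k b[k] x[n-k] - sum_k a[k] y[n-k]
  v <- as.numeric(stats::filter(c(rep(0, length(b) - 1), x), b,
                                method = "convolution", sides = 1))
  v <- v[-seq_len(length(b) - 1)]
  as.numeric(stats::filter(v, -a, method = "recursive"))
}

# power response of the digital biquad at normalized frequencies w (rad)
.biquad_power <- function(bq, w) {
  z <- exp(-1i * w)
  Mod((bq$b[1] + bq$b[2] * z + bq$b[3] * z^2) /
        (1 + bq$a[1] * z + bq$a[2] * z^2))^2
}

# Expected RMS of gammatone band -> half-wave rectification -> low-pass for
# unit-variance Gaussian white noise, from the exact autocorrelation of the
# rectified Gaussian (z = y/2 + |y|/2; E[|y_0||y_m|] =
# (2 sigma^2 / pi)(sqrt(1 - rho^2) + rho asin rho)); used to calibrate the
# signal path so that white noise maps to 0 dB per band, matching the
# spectral path's normalization.
.chain_gain <- function(G2, lp_pow) {
  M <- length(G2)
  r <- Re(stats::fft(G2, inverse = TRUE)) / M
  s2 <- r[1]
  rho <- pmin(pmax(r / s2, -1), 1)
  rz <- r / 4 + (s2 / (2 * pi)) * (sqrt(1 - rho^2) + rho * asin(rho))
  Sz <- pmax(Re(stats::fft(rz)), 0)
  sqrt(mean(Sz * lp_pow))
}

#' Internal representation of a waveform (signal path)
#'
#' Per band: gammatone filter, half-wave rectification, Butterworth
#' low-pass, RMS, `20*log10`. Gammatone filtering is performed in the
#' frequency domain with the analytic 4th-order all-pole magnitude
#' response (zero phase). Each band is calibrated by the analytically
#' expected chain output for unit-variance white noise, so a white input
#' yields 0 dB per band in expectation (the spectral path's convention);
#' calibrated RMS is floored at 1e-5 (-100 dB).
#'
#' @param x waveform (numeric vector).
#' @param fs sampling rate, Hz; must be at least `2 * f_high`.
#' @param spec a [filterbank_spec()].
#' @return vector of band magnitudes, dB, with `band_centers` attribute.
#' @export
internal_representation_signal <- function(x, fs, spec = filterbank_spec()) {
  if (fs < 2 * spec$f_high)
    stop(sprintf("sampling rate %g Hz below Nyquist for f_high = %g Hz", fs, spec$f_high),
         call. = FALSE)
  n <- length(x)
  if (n < 0.05 * fs)
    warning("stimulus shorter than 50 ms; band estimates may be unstable")
  fc <- gammatone_center_frequencies(spec)
  X <- stats::fft(x)
  fgrid <- (seq_len(n) - 1) / n * fs
  fgrid[fgrid > fs / 2] <- fs - fgrid[fgrid > fs / 2]   # magnitude response at |f|
  lp <- butter2_lowpass(spec$lowpass_cutoff, fs)
  lp_pow <- .biquad_power(lp, 2 * pi * (seq_len(n) - 1) / n)
  out <- vapply(fc, function(f0) {
    G2 <- gammatone_power_response(fgrid, f0)
    y <- Re(stats::fft(X * sqrt(G2), inverse = TRUE)) / n
    y <- pmax(y, 0)                                     # half-wave rectification
    y <- iir_filter(lp$b, lp$a, y)
    20 * log10(max(sqrt(mean(y^2)) / .chain_gain(G2, lp_pow), RMS_FLOOR))
  }, numeric(1))
  attr(out, "band_centers") <- fc
  out
}

#' Build the internal template set of a DTF set for one sagittal segment
#'
#' Selects all directions of `dtf` whose lateral angle lies within 10
#' degrees of the segment center and computes, per polar angle and ear,
#' the internal representation of the DTF via the spectral path. Templates
#' double as the response-angle candidates of the mapping stage.
#'
#' @param dtf a [dtf_set()].
#' @param lateral_segment segment center, degrees.
#' @param spec a [filterbank_spec()].
#' @return object of class `template_set`: list with `lateral_segment`,
#'   `polar` (sorted unique polar angles), `left` and `right` (matrices,
#'   bands x angles), `band_centers`.
#' @export
build_template_set <- function(dtf, lateral_segment, spec = filterbank_spec()) {
  stopifnot(inherits(dtf, "dtf_set"))
  sel <- which(abs(dtf$directions$lateral - lateral_segment) <= 10)
  if (length(sel) == 0)
    stop(sprintf("no DTF directions within 10 deg of lateral segment %g", lateral_segment),
         call. = FALSE)
  pol <- dtf$directions$polar[sel]
  if (anyDuplicated(pol))
    stop("duplicate polar angles within one lateral segment", call. = FALSE)
  if (length(pol) < 2)
    stop("need at least 2 polar angles per segment", call. = FALSE)
  ord <- order(pol)
  sel <- sel[ord]
  left <- internal_representation_spectral(dtf$magnitude$left[, sel, drop = FALSE],
                                           dtf$freq, spec)
  right <- internal_representation_spectral(dtf$magnitude$right[, sel, drop = FALSE],
                                            dtf$freq, spec)
  structure(list(lateral_segment = lateral_segment,
                 polar = pol[ord],
                 left = as.matrix(left), right = as.matrix(right),
                 band_centers = gammatone_center_frequencies(spec)),
            class = "template_set")
}
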