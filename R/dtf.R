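# DTF sets: per-listener, per-ear, per-direction magnitude spectra -- the
# acoustic factor of the model.  HRTFs are reduced to DTFs by removing the
# common transfer function (CTF), the per-ear log-magnitude average over
# all directions.

#' Construct a DTF (or HRTF) set
#'
#' @param listener_id character identifier (e.g. `"VL01"`).
#' @param directions a [direction()] data.frame (one row per direction).
#' @param freq frequency grid, Hz, strictly increasing.
#' @param magnitude list with elements `left` and `right`: dB magnitude
#'   matrices, `length(freq)` rows x `nrow(directions)` columns.
#' @param fs sampling rate associated with the set, Hz.
#' @param ir optional list with `left`/`right` impulse-response matrices
#'   (samples x directions).
#' @return object of class `dtf_set`.
#' @export
dtf_set <- function(listener_id, directions, freq, magnitude, fs = 48000,
                    ir = NULL) {
  stopifnot(is.character(listener_id), length(listener_id) == 1)
  validate_angles(directions$lateral, directions$polar, where = listener_id)
  if (is.unsorted(freq, strictly = TRUE))
    stop("freq must be strictly increasing", call. = FALSE)
  for (ear in c("left", "right")) {
    m <- magnitude[[ear]]
    if (is.null(m)) stop(sprintf("missing %s-ear magnitudes", ear), call. = FALSE)
    if (!all(dim(as.matrix(m)) == c(length(freq), nrow(directions))))
      stop(sprintf("%s-ear magnitude matrix must be freq x directions", ear),
           call. = FALSE)
    if (!all(is.finite(m)))
      stop(sprintf("non-finite %s-ear magnitudes", ear), call. = FALSE)
    magnitude[[ear]] <- as.matrix(m)
  }
  structure(list(listener_id = listener_id,
                 directions = directions,
                 freq = as.numeric(freq),
                 magnitude = magnitude[c("left", "right")],
                 fs = fs, ir = ir),
            class = "dtf_set")
}

#' @export
print.dtf_set <- function(x, ...) {
  cat(sprintf("DTF set '%s': %d directions, %d frequency points (%g-%g Hz), fs = %g Hz\n",
              x$listener_id, nrow(x$directions), length(x$freq),
              min(x$freq), max(x$freq), x$fs))
  cat(sprintf("  lateral planes: %s; polar span: [%g, %g] deg\n",
              paste(sort(unique(x$directions$lateral)), collapse = ", "),
              min(x$directions$polar), max(x$directions$polar)))
  invisible(x)
}

#' Compute DTFs from an HRTF set
#'
#' The common transfer function (CTF) is the per-ear mean of the dB
#' magnitude spectra over all directions; the DTF magnitudes are the HRTF
#' magnitudes minus the CTF. The operation is idempotent: applied to its
#' own output it changes nothing. Optionally reconstructs minimum-phase
#' impulse responses, windowed with an asymmetric Tukey window (0.5 ms
#' fade-in, 1 ms fade-out) and truncated to 5.33 ms (rounded up to the
#' next sample, 256 samples at 48 kHz).
#'
#' @param hrtf a [dtf_set()]-shaped container holding HRTF magnitudes.
#' @param compute_ir logical; also reconstruct impulse responses?
#' @return a `dtf_set` with zero-mean (across directions) dB magnitudes.
#' @export
compute_dtf_from_hrtf <- function(hrtf, compute_ir = FALSE) {
  stopifnot(inherits(hrtf, "dtf_set"))
  if (nrow(hrtf$directions) < 1) stop("need at least one direction", call. = FALSE)
  mag <- lapply(hrtf$magnitude, function(m) m - rowMeans(m))
  ir <- NULL
  if (compute_ir) {
    ir <- lapply(mag, function(m) {
      apply(m, 2, function(col)
        windowed_minphase_ir(hrtf$freq, col, hrtf$fs))
    })
  }
  dtf_set(hrtf$listener_id, hrtf$directions, hrtf$freq, mag, hrtf$fs, ir)
}

# number of samples covering 5.33 ms, rounded up (never truncate below
# the stated duration): 256 at 48 kHz.
ir_length <- function(fs, duration = 0.00533) ceiling(duration * fs)

# asymmetric Tukey window: raised-cosine fade-in over `fade_in` s,
# flat middle, raised-cosine fade-out over `fade_out` s.
tukey_asym <- function(n, fs, fade_in = 0.0005, fade_out = 0.001) {
  n_in <- min(round(fade_in * fs), n)
  n_out <- min(round(fade_out * fs), n - n_in)
  w <- rep(1, n)
  if (n_in > 0)
    w[seq_len(n_in)] <- 0.5 * (1 - cos(pi * (seq_len(n_in) - 1) / n_in))
  if (n_out > 0) {
    i <- seq_len(n_out)
    w[n - n_out + i] <- 0.5 * (1 + cos(pi * i / n_out))
  }
  w
}

# Windowed minimum-phase reconstruction: the minimum-phase response is
# delayed by the fade-in duration (a pure delay, magnitude-preserving) so
# the Tukey onset ramp covers zeros rather than the response peak, then
# windowed and truncated to 5.33 ms.
windowed_minphase_ir <- function(freq, mag_db, fs, fade_in = 0.0005) {
  n <- ir_length(fs)
  d <- round(fade_in * fs)
  h <- c(rep(0, d), minimum_phase_ir(freq, mag_db, fs, n - d))
  h * tukey_asym(n, fs, fade_in = fade_in)
}

# Minimum-phase impulse response whose magnitude matches `mag_db` given on
# grid `freq`, computed via the real cepstrum on an FFT grid of length
# `nfft`, truncated to n samples.
minimum_phase_ir <- function(freq, mag_db, fs, n, nfft = 4096) {
  fbins <- seq(0, fs / 2, length.out = nfft / 2 + 1)
  # extend flat outside the provided grid
  mdb <- stats::approx(freq, mag_db, xout = fbins, rule = 2)$y
  logmag <- mdb / 20 * log(10)
  full <- c(logmag, rev(logmag[c(-1, -(nfft / 2 + 1))]))
  cep <- Re(stats::fft(full, inverse = TRUE)) / nfft
  # fold the cepstrum onto the causal part
  fold <- cep
  fold[2:(nfft / 2)] <- 2 * cep[2:(nfft / 2)]
  fold[(nfft / 2 + 2):nfft] <- 0
  H <- exp(stats::fft(fold))
  h <- Re(stats::fft(H, inverse = TRUE)) / nfft
  h[seq_len(n)]
}

# Magnitude spectrum (dB) of an impulse response on an arbitrary grid,
# via zero-padded FFT and interpolation.
ir_to_magnitude <- function(h, fs, freq, nfft = 4096) {
  nfft <- max(nfft, length(h))
  H <- stats::fft(c(h, rep(0, nfft - length(h))))
  fbins <- (seq_len(nfft / 2 + 1) - 1) / nfft * fs
  mdb <- 20 * log10(pmax(Mod(H[seq_len(nfft / 2 + 1)]), 1e-10))
  stats::approx(fbins, mdb, xout = freq, rule = 2)$y
}
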