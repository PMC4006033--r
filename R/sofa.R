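# SOFA (Spatially Oriented Format for Acoustics) I/O for the
# SimpleFreeFieldHRIR convention.  SOFA files are netCDF-4/HDF5; with no
# native R HDF5 binding available in the target environment, reading and
# writing are delegated to a bundled python/h5py bridge exchanging JSON.
# Source coordinates are converted between SOFA's spherical
# azimuth/elevation and the interaural-polar system used throughout.

.sofa_bridge <- function() {
  script <- system.file("python", "sofa_bridge.py", package = "sagloc")
  if (!nzchar(script)) stop("bundled SOFA bridge not found", call. = FALSE)
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("SOFA support needs a python interpreter with h5py on the PATH",
         call. = FALSE)
  list(py = py, script = script)
}

#' Load a DTF set from a SOFA file
#'
#' Reads a SimpleFreeFieldHRIR file, converts source positions from
#' spherical (azimuth/elevation) to interaural-polar coordinates, and
#' Fourier-transforms the impulse responses to dB magnitudes on `freq`.
#' Directions whose polar angle falls outside \[-90, 270) after
#' conversion are rejected.
#'
#' @param path SOFA file.
#' @param listener_id identifier for the resulting set.
#' @param freq target frequency grid, Hz.
#' @return a [dtf_set()] (impulse responses retained in `$ir`).
#' @export
load_dtf_sofa <- function(path, listener_id = basename(path),
                          freq = default_freq_grid()) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  br <- .sofa_bridge()
  out <- suppressWarnings(
    system2(br$py, c(br$script, "read", shQuote(path)), stdout = TRUE,
            stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop(sprintf("SOFA read failed: %s", paste(out, collapse = " ")),
         call. = FALSE)
  dat <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyMatrix = TRUE)
  sp <- dat$source_position            # M x 3: az, el, r
  ip <- sph_to_interaural(sp[, 1], sp[, 2])
  fs <- dat$sampling_rate
  ir <- dat$ir                         # M x R x N array
  if (length(dim(ir)) != 3 || dim(ir)[2] < 2)
    stop("SOFA file must carry 2-receiver FIR data", call. = FALSE)
  mag <- list(
    left = vapply(seq_len(dim(ir)[1]),
                  function(m) ir_to_magnitude(ir[m, 1, ], fs, freq),
                  numeric(length(freq))),
    right = vapply(seq_len(dim(ir)[1]),
                   function(m) ir_to_magnitude(ir[m, 2, ], fs, freq),
                   numeric(length(freq))))
  dtf_set(listener_id, direction(ip$lateral, ip$polar), freq, mag, fs,
          ir = list(left = t(ir[, 1, , drop = TRUE]),
                    right = t(ir[, 2, , drop = TRUE])))
}

#' Write a DTF set to a SOFA file
#'
#' Magnitudes are turned into minimum-phase impulse responses (5.33 ms,
#' asymmetric Tukey window) unless the set already carries impulse
#' responses; interaural-polar directions are converted back to SOFA's
#' spherical coordinates.
#'
#' @param dtf a [dtf_set()].
#' @param path output SOFA file.
#' @return `path`, invisibly.
#' @export
write_dtf_sofa <- function(dtf, path) {
  stopifnot(inherits(dtf, "dtf_set"))
  br <- .sofa_bridge()
  n_ir <- ir_length(dtf$fs)
  get_ir <- function(ear, j) {
    if (!is.null(dtf$ir)) return(dtf$ir[[ear]][, j])
    windowed_minphase_ir(dtf$freq, dtf$magnitude[[ear]][, j], dtf$fs)
  }
  M <- nrow(dtf$directions)
  ir <- array(0, dim = c(M, 2, n_ir))
  for (j in seq_len(M)) {
    ir[j, 1, ] <- get_ir("left", j)
    ir[j, 2, ] <- get_ir("right", j)
  }
  sph <- interaural_to_sph(dtf$directions$lateral, dtf$directions$polar)
  payload <- jsonlite::toJSON(list(
    sampling_rate = dtf$fs,
    source_position = cbind(sph$azimuth, sph$elevation, 1.2),
    ir = ir), digits = NA, auto_unbox = TRUE)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(payload, tmp)
  out <- suppressWarnings(
    system2(br$py, c(br$script, "write", shQuote(path)), stdin = tmp,
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop(sprintf("SOFA write failed: %s", paste(out, collapse = " ")),
         call. = FALSE)
  invisible(path)
}
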