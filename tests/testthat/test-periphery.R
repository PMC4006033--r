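test_that("default filterbank has exactly 28 bands at unit-ERB spacing", {
  fc <- gammatone_center_frequencies(filterbank_spec())
  expect_length(fc, 28)
  expect_equal(fc[1], 700)
  expect_true(all(fc <= 18000))
  expect_equal(diff(erb_number(fc)), rep(1, 27), tolerance = 1e-9)
})

test_that("ERB-number scale matches its closed form", {
  # oracle: 21.4 * log10(0.00437 * f + 1)
  expect_equal(erb_number(1000), 21.4 * log10(0.00437 * 1000 + 1))
  expect_equal(round(erb_number(1000), 2), 15.62)
  expect_equal(erb_number_inv(erb_number(c(700, 5000, 18000))),
               c(700, 5000, 18000), tolerance = 1e-9)
  expect_length(gammatone_center_frequencies(filterbank_spec(1000, 1001)), 1)
  expect_error(filterbank_spec(1000, 1000), "f_low")
})

test_that("spectral path: flat spectra and gain offsets are exact", {
  freq <- default_freq_grid(257)
  flat <- rep(0, length(freq))
  r0 <- internal_representation_spectral(flat, freq)
  expect_equal(as.numeric(r0), rep(0, 28), tolerance = 1e-9)
  shaped <- 10 * sin(seq(0, 6 * pi, length.out = length(freq)))
  r1 <- internal_representation_spectral(shaped, freq)
  r2 <- internal_representation_spectral(shaped + 7.5, freq)
  expect_equal(as.numeric(r2 - r1), rep(7.5, 28), tolerance = 1e-9)
  expect_error(internal_representation_spectral(flat, freq * 10), "cover")
})

test_that("signal path: level scaling, silence floor, Nyquist guard", {
  set.seed(21)
  fs <- 48000
  x <- rnorm(fs / 4)
  r1 <- internal_representation_signal(x, fs)
  r2 <- internal_representation_signal(2 * x, fs)
  expect_equal(as.numeric(r2 - r1), rep(20 * log10(2), 28), tolerance = 0.1)
  rz <- internal_representation_signal(rep(0, fs / 4), fs)
  expect_equal(as.numeric(rz), rep(-100, 28))
  expect_error(internal_representation_signal(x, 30000), "Nyquist")
})

test_that("a deep spectral notch surfaces as the band minimum (signal path)", {
  set.seed(22)
  fs <- 48000
  freq <- default_freq_grid(257)
  notch_db <- -30 * exp(-0.5 * ((erb_number(freq) - erb_number(8000)) / 0.8)^2)
  n <- fs / 4
  fgrid <- (seq_len(n) - 1) / n * fs
  fgrid[fgrid > fs / 2] <- fs - fgrid[fgrid > fs / 2]
  G <- 10^(approx(freq, notch_db, xout = pmin(pmax(fgrid, min(freq)), max(freq)))$y / 20)
  reps <- sapply(1:20, function(i) {
    x <- rnorm(n)
    y <- Re(fft(fft(x) * G, inverse = TRUE)) / n
    as.numeric(internal_representation_signal(y, fs))
  })
  avg <- rowMeans(reps)
  fc <- gammatone_center_frequencies()
  expect_equal(which.min(avg), which.min(abs(fc - 8000)))
})

test_that("spectral and signal paths agree within 1 dB for filtered noise", {
  set.seed(23)
  fs <- 48000
  freq <- default_freq_grid(257)
  dtf_db <- 8 * sin(2 * pi * erb_number(freq) / 9) -
    20 * exp(-0.5 * ((erb_number(freq) - erb_number(9000)) / 1)^2)
  rs <- as.numeric(internal_representation_spectral(dtf_db, freq))
  n <- fs / 2
  fgrid <- (seq_len(n) - 1) / n * fs
  fgrid[fgrid > fs / 2] <- fs - fgrid[fgrid > fs / 2]
  G <- 10^(approx(freq, dtf_db, xout = pmin(pmax(fgrid, min(freq)), max(freq)))$y / 20)
  reps <- sapply(1:50, function(i) {
    x <- rnorm(n)
    y <- Re(fft(fft(x) * G, inverse = TRUE)) / n
    as.numeric(internal_representation_signal(y, fs))
  })
  avg <- rowMeans(reps)
  # absolute agreement: the signal path is calibrated to the white-noise
  # expectation, the spectral path normalizes bands to flat = 0 dB
  expect_lt(max(abs(avg - rs)), 1)
})

test_that("template sets cover the segment's polar grid", {
  d <- fix_listener_dtf()
  tpl <- build_template_set(d, 0)
  expect_s3_class(tpl, "template_set")
  expect_length(tpl$polar, 49)
  expect_equal(dim(tpl$left), c(28, 49))
  expect_false(is.unsorted(tpl$polar, strictly = TRUE))
  # definitional identity: template at theta equals direct processing
  j <- which(tpl$polar == 30)
  col <- which(d$directions$lateral == 0 & d$directions$polar == 30)
  direct <- internal_representation_spectral(d$magnitude$left[, col], d$freq)
  expect_equal(tpl$left[, j], as.numeric(direct))
  expect_error(build_template_set(d, 60), "no DTF directions")
  # cue_quality = 0: all templates identical
  d0 <- fix_listener_dtf(cue_quality = 0)
  tpl0 <- build_template_set(d0, 0)
  expect_equal(max(abs(tpl0$left - tpl0$left[, 1])), 0, tolerance = 1e-9)
})
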