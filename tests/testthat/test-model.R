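test_that("inter-spectral distance is a level-blind sample SD", {
  x <- c(1, 2, 3, 4)
  expect_equal(interspectral_distance(x, x), 0)
  expect_equal(interspectral_distance(x + 6, x), 0)      # constant offset
  expect_equal(interspectral_distance(c(0, 10, 20), c(0, 0, 0)), 10)
  expect_error(interspectral_distance(x, x[1:3]), "band grids")
})

test_that("Gaussian similarity mapping", {
  expect_equal(similarity(0, 2.3), 1)
  expect_equal(similarity(1.7, 1.7), exp(-0.5))
  expect_equal(similarity(2, 1), exp(-2))
  expect_error(similarity(1, 0), "U must be")
})

test_that("binaural weights form a logistic pair summing to one", {
  expect_equal(binaural_weights(0), c(left = 0.5, right = 0.5))
  w <- binaural_weights(13.3, phi = 13.3)
  expect_equal(unname(w["left"]), 1 / (1 + exp(-1)), tolerance = 1e-12)
  w90 <- binaural_weights(-90, phi = 13.3)
  expect_equal(unname(w90["left"]), 1 / (1 + exp(90 / 13.3)), tolerance = 1e-12)
  expect_lt(w90[["left"]], 0.002)
  set.seed(31)
  for (lat in runif(10, -90, 90))
    expect_equal(sum(binaural_weights(lat)), 1)
})

test_that("predict_pmv: self-match, no-cue uniformity, level-rove invariance", {
  d <- fix_listener_dtf()
  cfg <- fix_config()
  p <- predict_pmv(direction(0, 0), d, d, U = 0.1, cfg)
  expect_equal(p$response_angles[which.max(p$probabilities)], 0)
  expect_equal(sum(p$probabilities), 1, tolerance = 1e-12)

  d0 <- fix_listener_dtf(cue_quality = 0)
  pu <- predict_pmv(direction(0, 45), d0, d0, U = 2, cfg)
  expect_equal(pu$probabilities, rep(1 / 49, 49), tolerance = 1e-9)

  roved <- d
  roved$magnitude$left <- roved$magnitude$left + 5
  roved$magnitude$right <- roved$magnitude$right + 5
  p_roved <- predict_pmv(direction(20, 100), roved, d, U = 2, cfg)
  p_ref <- predict_pmv(direction(20, 100), d, d, U = 2, cfg)
  expect_lt(max(abs(p_roved$probabilities - p_ref$probabilities)), 1e-9)
})

test_that("PMV entropy is non-decreasing in U", {
  d <- fix_listener_dtf()
  cfg <- fix_config()
  ent <- vapply(seq(0.5, 4, by = 0.5), function(U) {
    p <- predict_pmv(direction(0, 30), d, d, U, cfg)$probabilities
    -sum(p * log(p))
  }, numeric(1))
  expect_true(all(diff(ent) >= -1e-9))
})

test_that("template order does not affect the PMV", {
  d <- fix_listener_dtf()
  cfg <- fix_config()
  set.seed(32)
  perm <- sample(nrow(d$directions))
  d2 <- dtf_set(d$listener_id, d$directions[perm, ], d$freq,
                list(left = d$magnitude$left[, perm],
                     right = d$magnitude$right[, perm]), d$fs)
  p1 <- predict_pmv(direction(0, 60), d, d, U = 1.5, cfg)
  p2 <- predict_pmv(direction(0, 60), d2, d2, U = 1.5, cfg)
  expect_equal(p1$response_angles, p2$response_angles)
  expect_equal(p1$probabilities, p2$probabilities, tolerance = 1e-12)
})

test_that("PMV equals the hand-composed four-stage formula on a toy case", {
  cfg <- toy_config()
  d <- toy_dtf()
  target <- direction(0, 30)
  U <- 1.3
  # oracle composed by hand: representation -> SD distance -> Gaussian SI
  # -> binaural sum -> normalization
  rep_l <- internal_representation_spectral(d$magnitude$left, d$freq)
  rep_r <- internal_representation_spectral(d$magnitude$right, d$freq)
  it <- 3  # polar 30 is the 3rd direction
  si <- vapply(1:3, function(j) {
    dl <- stats::sd(rep_l[, it] - rep_l[, j])
    dr <- stats::sd(rep_r[, it] - rep_r[, j])
    0.5 * exp(-dl^2 / (2 * U^2)) + 0.5 * exp(-dr^2 / (2 * U^2))
  }, numeric(1))
  oracle <- si / sum(si)
  p <- predict_pmv(target, d, d, U, cfg)
  expect_equal(p$probabilities, oracle, tolerance = 1e-12)
  expect_equal(p$response_angles, c(-30, 0, 30))
})

test_that("pairwise distance fast path matches the direct SD route", {
  tpl <- build_template_set(fix_listener_dtf(), 0)
  D2 <- sagloc:::.pairwise_sqdist(tpl$left)
  set.seed(33)
  for (k in 1:20) {
    ij <- sample(ncol(tpl$left), 2)
    expect_equal(sqrt(D2[ij[1], ij[2]]),
                 interspectral_distance(tpl$left[, ij[1]], tpl$left[, ij[2]]),
                 tolerance = 1e-9)
  }
})

test_that("pmv constructor validates probabilities", {
  expect_error(pmv(c(0, 10), c(0.6, 0.6)), "sum")
  expect_error(pmv(c(0, 10), c(1.2, -0.2)), "negative")
})
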