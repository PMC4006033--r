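toy_group <- function(K = 3, U = NULL, same_dtf = FALSE) {
  if (is.null(U)) U <- seq(1.5, by = 0.4, length.out = K)
  lapply(seq_len(K), function(k)
    listener_model(fix_listener_dtf(seed = if (same_dtf) 1 else k),
                   uncertainty = U[k]))
}

test_that("permutation grid: shape, ordering, diagonal identity", {
  g <- toy_group(3, U = c(2.3, 1.5, 1.9))
  grid <- permutation_grid(g)
  expect_equal(dim(grid$PE_matrix), c(3, 3))
  expect_equal(grid$U, c(1.5, 1.9, 2.3))             # ascending U ordering
  expect_equal(grid$listener_order, c("VL02", "VL03", "VL01"))
  # diagonal == baseline listener-specific predictions, bit for bit
  for (k in 1:3) {
    id <- grid$listener_order[k]
    l <- g[[match(id, vapply(g, function(x) x$dtf$listener_id, character(1)))]]
    base <- performance_curve(l$dtf, U_grid = grid$U[k])
    expect_identical(grid$PE_matrix[k, k], base$PE)
    expect_identical(grid$QE_matrix[k, k], base$QE)
  }
  expect_error(permutation_grid(g[1]), "at least 2")
  expect_error(permutation_grid(toy_group(2, U = c(NA, 2))), "calibrated")
})

test_that("degenerate groups: shared DTF flattens columns, shared U rows", {
  g_dtf <- toy_group(3, same_dtf = TRUE)
  grid1 <- permutation_grid(g_dtf)
  for (j in 1:3)
    expect_equal(max(grid1$PE_matrix[, j]) - min(grid1$PE_matrix[, j]), 0,
                 tolerance = 1e-9)
  g_u <- toy_group(3, U = rep(2, 3))
  grid2 <- permutation_grid(g_u)
  for (i in 1:3)
    expect_equal(max(grid2$PE_matrix[i, ]) - min(grid2$PE_matrix[i, ]), 0,
                 tolerance = 1e-9)
})

test_that("relative performance matches the hand-evaluated definition", {
  grid <- structure(list(listener_order = c("A", "B"), U = c(1, 2),
                         PE_matrix = matrix(c(30, 34, 40, 44), 2),
                         QE_matrix = matrix(c(10, 12, 14, 16), 2)),
                    class = "permutation_grid")
  rel <- relative_performance(grid)
  # row 1: (0 + (40 - 44)) / 2 = -2 ; row 2: ((34 - 30) + 0) / 2 = +2
  expect_equal(rel$dPE_mean, c(-2, 2))
  expect_equal(rel$dQE_mean, c(-1, 1))
  # diagonal deltas are zero by construction
  dPE <- sweep(grid$PE_matrix, 2, diag(grid$PE_matrix))
  expect_equal(diag(dPE), c(0, 0))
})

test_that("factor SDs separate row and column variation", {
  constg <- structure(list(listener_order = c("A", "B"), U = c(1, 2),
                           PE_matrix = matrix(5, 2, 2),
                           QE_matrix = matrix(3, 2, 2)),
                      class = "permutation_grid")
  f0 <- factor_sds(constg)
  expect_equal(unname(f0$sd_over_U_PE), c(0, 0))
  expect_equal(unname(f0$sd_over_D_QE), c(0, 0))

  # variation only along columns (U effect only)
  ug <- structure(list(listener_order = c("A", "B"), U = c(1, 2),
                       PE_matrix = matrix(c(10, 10, 20, 20), 2),
                       QE_matrix = matrix(c(1, 1, 2, 2), 2)),
                  class = "permutation_grid")
  fu <- factor_sds(ug)
  expect_true(all(fu$sd_over_U_PE > 0))
  expect_equal(unname(fu$sd_over_D_PE), c(0, 0))
  expect_true(is.infinite(fu$ratio$PE) || fu$ratio$PE > 1e6)
})

test_that("pearson matches a brute-force covariance computation", {
  expect_equal(pearson(1:5, 1:5), 1)
  expect_equal(pearson(1:5, 2 * (1:5) + 3), 1)
  expect_equal(pearson(c(1, 2, 3), c(1, 3, 2)), 0.5)
  # spec example with actual/predicted PEs: direct formula evaluation
  expect_equal(pearson(c(30, 34, 38), c(31, 33, 39)),
               32 / sqrt(32 * (11.111111 + 1.7777778 + 21.777778)),
               tolerance = 1e-6)
  set.seed(61)
  for (k in 1:10) {
    x <- rnorm(20); y <- rnorm(20)
    brute <- mean((x - mean(x)) * (y - mean(y))) /
      sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
    expect_equal(pearson(x, y), brute, tolerance = 1e-12)
  }
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
})

test_that("constant-parameter evaluation correlates predictions with actuals", {
  g <- toy_group(4, U = c(1.5, 1.9, 2.3, 2.7))
  actual <- lapply(g, function(l) {
    rs <- generate_responses(l, 150, seed = 90 + round(10 * l$uncertainty))
    actual_scores(rs)
  })
  ev_u <- constant_parameter_eval(g, actual, mode = "constant_U", value = 2)
  expect_true(abs(ev_u$r_PE) <= 1 && abs(ev_u$r_QE) <= 1)
  expect_true(all(ev_u$group_sd >= 0))
  ids <- vapply(g, function(l) l$dtf$listener_id, character(1))
  ev_d <- constant_parameter_eval(g, actual, mode = "constant_DTF",
                                  value = ids[2])
  # listener-specific U preserved: predictions track the U ordering
  expect_gt(ev_d$r_QE, 0)
  expect_error(constant_parameter_eval(g[1:2], actual[1:2],
                                       mode = "constant_U", value = 2),
               "at least 3")
  expect_error(constant_parameter_eval(g, actual, mode = "constant_DTF",
                                       value = "nobody"), "unknown")
})
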