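test_that("sharpness is the unit-sum power-spectrum centroid", {
  freq <- (0:6) / (13 * 9 / 60)
  expect_equal(sharpness(rep(1, 13)), 0)               # all power at DC
  imp <- replace(numeric(13), 7, 1)
  expect_equal(sharpness(imp), mean(freq))             # flat spectrum
  expect_error(sharpness(rep(0, 13)), "all-zero")
  # surround inhibition makes the DOG sharper than its centre lobe alone
  x <- ((1:13) - 7) * 9
  centre_only <- 4 * dnorm(x, 0, 5)
  expect_gt(sharpness(dog13()), sharpness(centre_only))
  # scale invariance
  expect_equal(sharpness(3 * dog13()), sharpness(dog13()))
})

test_that("nonlinearity index combines the two markers with a rectified second marker", {
  # template-matcher expectation: both markers vanish
  nl <- nonlinearity_index(1.2, 1.2, 1.5, 0)
  expect_equal(nl$marker1, 0)
  expect_equal(nl$marker2, 0)                          # sign(0) = 0
  expect_equal(nl$nonlinearity, 0)
  # nonlinear case: second-order structure in excess of first-order
  nl2 <- nonlinearity_index(1.5, 0.8, 1.2, 2)
  expect_equal(nl2$marker1, 0.7)
  expect_equal(nl2$marker2, (2 - 1.2) * 1)
  expect_equal(nl2$linearity, -nl2$nonlinearity)
  # null gate: lambda2 within its null band contributes nothing
  nl3 <- nonlinearity_index(1.5, 0.8, 1.2, 0.05, lambda2_null_sd = 0.02)
  expect_equal(nl3$marker2, 0)
  nl4 <- nonlinearity_index(1.5, 0.8, 1.2, 0.05, lambda2_null_sd = 0.01)
  expect_equal(nl4$marker2, (0.05 - 1.2) * 1)
})

test_that("dependence is a Pearson correlation with level-index abscissa", {
  expect_equal(dependence(1:4, levels = 1:4), 1)
  s <- metric_surface(outer(1:4, c(2, 1, 3, 5)), "m")
  expect_equal(dependence(s, "snr"), cor(as.vector(s$values), as.vector(row(s$values))))
  # index abscissa equals log2 of the contrast multiplier (affine invariance)
  v <- c(0.3, 1.1, 0.8, 2.0)
  expect_equal(dependence(v, levels = 1:4),
               cor(v, log2(contrast_multiplier(1:4))))
  # raw multipliers give a genuinely different coefficient
  expect_false(isTRUE(all.equal(dependence(v, "contrast", levels = 1:4),
                                dependence(v, "contrast", levels = 1:4,
                                           raw_levels = TRUE))))
  expect_warning(r <- dependence(rep(1, 4), levels = 1:4), "constant")
  expect_true(is.na(r))
})

test_that("separable surfaces are their own prediction and score SVD index 1", {
  S <- outer(c(1, 2, 3, 4), c(1, 2, 4, 8))
  expect_equal(separability_prediction(S), S)
  expect_equal(svd_index(S), 1, tolerance = 1e-12)
  set.seed(61)
  R <- matrix(runif(16) + 0.5, 4, 4)
  P <- separability_prediction(R)
  expect_equal(rowSums(P), rowSums(R))
  expect_equal(colSums(P), colSums(R))
  expect_gt(norm(R - P, "F"), 0)
  expect_equal(svd_index(diag(4)), 0.25)               # equal singular values
  expect_equal(svd_index(5 * R), svd_index(R))         # scale invariance
  expect_gte(svd_index(R), 0.25)                       # rank-4 lower bound
  expect_error(svd_index(matrix(0, 4, 4)), "all-zero")
})

test_that("d-prime conversion and efficiency follow their closed forms", {
  expect_equal(dprime_from_pc(0.5), 0)
  expect_equal(dprime_from_pc(pnorm(1 / sqrt(2))), 1)  # inverse-function oracle
  p <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(dprime_from_pc(p)) > 0))
  expect_true(is.finite(dprime_from_pc(1, m = 100)))
  expect_error(dprime_from_pc(1), "strictly inside")
  expect_equal(efficiency(3, 3), 1)
  expect_equal(efficiency(1.5, 3), 0.25)
  expect_error(efficiency(1, 0), "positive")
})

test_that("trend-test wrappers behave at the null and under a perfect trend", {
  x <- c(1.2, 0.8, 1.4, 1.1, 0.9)
  expect_equal(wilcoxon_signed_rank(x, x), 1)          # identical pairs
  m <- matrix(rep(1:4, each = 8), 8, 4) + matrix(rnorm(32, sd = 0.01), 8, 4)
  expect_lt(friedman_trend(m), 1e-4)                   # strict ordering
  expect_error(friedman_trend(matrix(1, 1, 4)), ">= 2")
  # type-I error calibration at the nominal 5% level
  set.seed(62)
  rej <- mean(replicate(400, wilcoxon_signed_rank(rnorm(20)) < 0.05))
  expect_lt(abs(rej - 0.05), 0.03)
})
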