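test_that("noise classification fills the four response-conditional bins", {
  set.seed(51)
  ss <- quick_session(quick_cond(), observer_config("template", noise_sd = 0.3), 500)
  cn <- classify_noise(ss$trials, ss$responses)
  counts <- vapply(cn[c("n11", "n10", "n00", "n01")], ncol, integer(1))
  expect_equal(sum(counts), 2L * 500L)              # two samples per trial
  expect_equal(counts[["n11"]], counts[["n01"]])    # correct trials feed both q bins
  expect_equal(counts[["n10"]], counts[["n00"]])
  expect_equal(cn$pc, mean(ss$responses$correct))
  # an all-correct observer leaves the z = 0 bins empty -> descriptor undefined
  re1 <- ss$responses; re1$correct <- TRUE
  expect_error(first_order(classify_noise(ss$trials, re1)), "fewer than")
})

test_that("template observer yields matched target-present/absent descriptors peaked at the centre", {
  set.seed(52)
  cfg <- observer_config("template", noise_sd = 0.25)
  ss <- quick_session(condition_spec("bright", 4, 2), cfg, 30000)
  ds <- drive_set(classify_noise(ss$trials, ss$responses))
  expect_equal(which.max(ds$h), 7L)
  # linear template: lambda^[1] = lambda^[0] and lambda2 ~ 0
  expect_lt(abs(ds$lambda1_tp - ds$lambda1_ta), 0.1)
  expect_lt(abs(ds$lambda2), 0.1)
  expect_gt(ds$lambda1, 1)
})

test_that("energy observer produces flat target-absent spatial descriptors but modulated power descriptors", {
  set.seed(53)
  cfg <- observer_config("energy", noise_sd = 0.05)
  ss <- quick_session(condition_spec("bright", 2, 2), cfg, 30000)
  cn <- classify_noise(ss$trials, ss$responses)
  ds <- drive_set(cn)
  # spatial target-absent component is at the decoupled floor (no modulation)
  expect_lt(abs(ds$lambda1_ta - lambda_null_mean(13)), 0.12)
  # the second-order descriptor carries strong structure instead
  expect_gt(ds$lambda2, 0.5)
  # Fourier-power target-absent descriptor detects the non-phase-locked
  # structure: its RMS stands clearly above a decoupled reference
  po <- first_order_power(cn)
  null_rms <- replicate(30, {
    cn0 <- classify_noise(ss$trials, decouple(ss$responses))
    sqrt(mean(first_order_power(cn0)$h0^2))
  })
  expect_gt(sqrt(mean(po$h0^2)), mean(null_rms) + 5 * sd(null_rms))
})

test_that("decoupled-process descriptors sit at the analytic RMS floor", {
  # Monte-Carlo oracle for the reconstructed RMS* forms: ratios of measured
  # to expected RMS concentrate on 1 for every region
  set.seed(54)
  m <- 2000; pc_target <- 0.7; sig <- 2
  cond <- condition_spec("bright", 2, 2)
  ratios <- replicate(200, {
    tr <- make_trials(cond, m)
    z <- runif(m) < pc_target
    re <- data.frame(block_id = tr$block_id, trial_index = tr$trial_index,
                     r0 = 0, r1 = 0, response = as.integer(z), correct = z)
    cn <- classify_noise(tr, re)
    fo <- first_order(cn); H <- second_order(cn)
    off <- row(H) != col(H)
    c(h  = sqrt(mean(fo$h^2))  / rms_star(1, m, cn$pc, sig, "full"),
      h1 = sqrt(mean(fo$h1^2)) / rms_star(1, m, cn$pc, sig, "component"),
      Hd = sqrt(mean(diag(H)^2)) / rms_star(2, m, cn$pc, sig, "diagonal"),
      Ho = sqrt(mean(H[off]^2)) / rms_star(2, m, cn$pc, sig, "offdiagonal"))
  })
  means <- rowMeans(ratios)
  expect_true(all(means > 0.97 & means < 1.03),
              info = paste(round(means, 4), collapse = " "))
})

test_that("rms_star scales with sigma and rejects degenerate inputs", {
  expect_equal(rms_star(1, 100, 0.75, 4) / rms_star(1, 100, 0.75, 2), 2)
  expect_equal(rms_star(2, 100, 0.75, 4, "diagonal") /
               rms_star(2, 100, 0.75, 2, "diagonal"), 4)
  expect_equal(rms_star(1, 100, 0.5, 1), sqrt(2 / (100 * 0.25)))
  expect_error(rms_star(1, 100, 1, 1), "strictly inside")
  expect_error(rms_star(3, 100, 0.5, 1), "order")
})

test_that("drive obeys its log identities", {
  x <- rnorm(13)
  fl <- sqrt(mean(x^2))
  expect_equal(drive(x, fl), 0)                      # region at its floor
  expect_equal(drive(2 * x, fl), log(2))             # doubling adds log 2
  expect_error(drive(numeric(0), 1), "empty")
  expect_error(drive(x, 0), "positive")
})

test_that("decoupling preserves marginals and zeroes the drives", {
  set.seed(55)
  ss <- quick_session(quick_cond(), observer_config("hybrid_gc_nlin", noise_sd = 0.2), 4000)
  dec <- decouple(ss$responses)
  expect_equal(mean(dec$correct), mean(ss$responses$correct))  # pc exact
  expect_setequal(dec$response, ss$responses$response)
  lam <- replicate(60, {
    d <- drive_set(classify_noise(ss$trials, decouple(ss$responses)))
    c(d$lambda1, d$lambda2)
  })
  # mean null drives match the exact small-sample null expectation
  se1 <- sd(lam[1, ]) / sqrt(ncol(lam))
  expect_lt(abs(mean(lam[1, ]) - lambda_null_mean(13)), 3 * se1 + 0.01)
  expect_lt(abs(mean(lam[2, ])), 3 * sd(lam[2, ]) / sqrt(ncol(lam)) + 0.02)
})

test_that("null drive spread is stable across shuffle batches", {
  set.seed(56)
  ss <- quick_session(quick_cond(), observer_config("template", noise_sd = 0.3), 3000)
  sds <- replicate(3, sd(replicate(60, {
    drive_set(classify_noise(ss$trials, decouple(ss$responses)))$lambda1
  })))
  expect_lt(max(sds) / min(sds), 1.5)
})

test_that("eigen-decomposition reconstructs H and flags no structure under the null", {
  set.seed(57)
  ss <- quick_session(quick_cond(), observer_config("energy", noise_sd = 0.05), 4000)
  H <- second_order(classify_noise(ss$trials, ss$responses))
  ed <- eigendecompose(H, ss$trials, ss$responses, n_shuffles = 40)
  expect_equal(ed$vectors %*% diag(ed$values) %*% t(ed$vectors), H,
               tolerance = 1e-10)
  expect_true(all(abs(crossprod(ed$vectors) - diag(13)) < 1e-10))
  expect_error(eigendecompose(matrix(rnorm(169), 13, 13)), "symmetric")
  expect_warning(eigendecompose(H, ss$trials, ss$responses, n_shuffles = 5),
                 "shuffle")
  # decoupled descriptor: no significant eigenvalues at the 3x threshold
  hits <- vapply(1:5, function(i) {
    cn0 <- classify_noise(ss$trials, decouple(ss$responses))
    e0 <- eigendecompose(second_order(cn0), ss$trials, ss$responses,
                         n_shuffles = 30)
    e0$significant_pos + e0$significant_neg
  }, numeric(1))
  expect_lte(sum(hits > 0), 1)
})
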