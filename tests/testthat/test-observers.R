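test_that("the DOG front-end filter is unit-energy, even and Mexican-hat shaped", {
  f <- dog_filter(dog_spec())
  expect_equal(sum(f^2), 1, tolerance = 1e-12)
  fv <- as.vector(f)
  expect_equal(fv, rev(fv))
  half <- (length(f) + 1) / 2
  expect_gt(f[half], 0)
  expect_lt(f[half + 3], 0)  # surround (27 arcmin) is inhibitory
  expect_error(dog_spec(support = 24), "odd")
  expect_error(dog_spec(sigma1 = 30, sigma2 = 20), "smaller")
})

test_that("front-end convolution is linear with zero-padded boundaries", {
  f <- dog_filter()
  expect_equal(frontend(rep(0, 13), f), rep(0, 13))
  imp <- replace(numeric(13), 7, 1)
  out <- frontend(imp, f)
  half <- (length(f) - 1) / 2
  expect_equal(out, f[half + 1 + ((1:13) - 7)])  # centred (symmetric) filter
  set.seed(21)
  s <- rnorm(13)
  for (a in c(-2, 0.5))
    expect_equal(frontend(a * s, f), a * frontend(s, f), tolerance = 1e-12)
})

test_that("divisive gain control follows the printed normalisation formulas", {
  expect_equal(gain_control_linear(rep(0, 13)), rep(0, 13))
  b <- c(rep(1, 6), rep(-1, 6), 0)       # signed sum zero
  expect_equal(gain_control_linear(b), b / 10)
  bn <- abs(rnorm(13))
  S <- sum(bn)
  expect_equal(sum(gain_control_nonlinear(bn)), S / (0.4 + S))
  expect_lt(sum(gain_control_nonlinear(1e6 * bn)), 1)   # saturates below 1
  expect_gt(sum(gain_control_nonlinear(1e6 * bn)), 0.999)
  expect_equal(gain_control_nonlinear(rep(0, 5)), rep(0, 5))
  expect_error(gain_control_nonlinear(c(-1, 1)), "non-negative")
})

test_that("template observer is linear and energy observer is polarity blind", {
  set.seed(22)
  tpl <- observer_config("template", noise_sd = 0)
  s1 <- rnorm(13); s2 <- rnorm(13)
  expect_equal(decision_variable(s1 + s2, tpl),
               decision_variable(s1, tpl) + decision_variable(s2, tpl),
               tolerance = 1e-10)
  en <- observer_config("energy", noise_sd = 0)
  expect_equal(decision_variable(-s1, en), decision_variable(s1, en),
               tolerance = 1e-12)
})

test_that("the MAX observer broadens its window as contrast decreases", {
  set.seed(23)
  cfg <- observer_config("max", noise_sd = 0)
  s <- rnorm(13, sd = 2)
  f <- dog_filter(cfg$dog)
  b <- frontend(cfg$input_gain * s, f)
  expect_equal(decision_variable(s, cfg, contrast_level = 1),
               max(readout_weights(160) * b))
  expect_equal(decision_variable(s, cfg, contrast_level = 4),
               max(readout_weights(40) * b))
  expect_error(decision_variable(s, cfg), "contrast level")
})

test_that("the difference rule resolves ties to the non-target", {
  cond <- condition_spec("bright", 1, 1)
  tr <- make_trials(cond, 5)
  tr$n1 <- tr$n0            # identical stimuli in both intervals...
  tr$t1 <- rep(0, 5)        # ...and no signal
  cfg <- observer_config("template", noise_sd = 0)
  re <- respond(tr, cfg)
  expect_true(all(re$response == 0L))
})

test_that("overwhelming intrinsic noise drives performance to chance", {
  set.seed(24)
  tr <- make_trials(condition_spec("bright", 4, 4), 1e4)
  re <- respond(tr, observer_config("template", noise_sd = 1e6))
  expect_equal(mean(re$correct), 0.5, tolerance = 0.02)
})

test_that("calibration reaches threshold performance and fails gracefully below ceiling", {
  set.seed(25)
  cfg <- calibrate_noise_sd(observer_config("max"), n_trials_per_condition = 600)
  expect_gt(cfg$noise_sd, 0)
  expect_true(abs(attr(cfg, "mean_dprime") - 1) <= 0.05)
  # the template architecture cannot reach mean d' = 1 at these parameters
  expect_error(calibrate_noise_sd(observer_config("template"),
                                  n_trials_per_condition = 400),
               "calibration failure")
  fb <- calibrate_noise_sd(observer_config("template"),
                           n_trials_per_condition = 400,
                           target = "ceiling_fraction")
  expect_gt(fb$noise_sd, 0)
  expect_lt(attr(fb, "mean_dprime"), attr(fb, "ceiling"))
})

test_that("ideal observer reaches the SNR-valued d' and is exact without noise", {
  set.seed(26)
  tr <- make_trials(condition_spec("bright", 2, 4), 4e4)
  d <- dprime_from_pc(mean(ideal_respond(tr)$correct))
  expect_equal(d, 4, tolerance = 0.1)  # ideal d' = SNR
  pol <- make_trials(condition_spec("polarity", 1, 1), 100)
  pol$n0[] <- 0; pol$n1[] <- 0          # noiseless stimuli
  expect_true(all(ideal_respond(pol)$correct))
  mx <- make_trials(condition_spec("mixed", 1, 1), 10)
  expect_error(ideal_respond(mx), "mixed")
})

test_that("double-pass agreement brackets the deterministic and noise-dominated limits", {
  set.seed(27)
  dp <- make_session(list(quick_cond()), 10, "double_pass")
  pa0 <- summarize_double_pass(respond(dp, observer_config("template", noise_sd = 0)), dp)$pa
  expect_equal(pa0, 1)
  paInf <- summarize_double_pass(respond(dp, observer_config("template", noise_sd = 1e6)), dp)$pa
  expect_lt(abs(paInf - 0.5), 0.1)
})

test_that("simulation is reproducible under a fixed seed", {
  cond <- quick_cond()
  cfg <- observer_config("hybrid_gc_nlin", noise_sd = 0.2)
  set.seed(28); a <- respond(make_trials(cond, 100), cfg)
  set.seed(28); b <- respond(make_trials(cond, 100), cfg)
  expect_identical(a, b)
})

test_that("noise structure shapes the SNR-dependence of estimated internal noise", {
  # response-dependent noise scales with the stimulus-driven response, so the
  # fitted internal noise grows with SNR; a fixed late additive source
  # predicts the opposite direction
  set.seed(31)
  nint_by_snr <- function(cfg, n = 120) vapply(c(1, 4), function(snr) {
    dp <- make_session(list(condition_spec("bright", 2, snr)), n, "double_pass")
    estimate_internal_noise(summarize_double_pass(respond(dp, cfg), dp))$n_int
  }, numeric(1))
  rd <- nint_by_snr(observer_config("energy", noise_sd = 1.5,
                                    noise_location = "early",
                                    noise_scaling = "response_dependent"))
  ri <- nint_by_snr(observer_config("energy", noise_sd = 0.05))
  expect_gt(rd[2], rd[1])
  expect_lt(ri[2], ri[1])
})
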