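#' Difference-of-Gaussians front-end filter specification
#'
#' @param k centre-lobe amplitude (default 4).
#' @param sigma1 SD of the positive (centre) Gaussian, arcmin (default 5).
#' @param sigma2 SD of the negative (surround) Gaussian, arcmin (default 20).
#' @param spacing sample spacing in arcmin; equals the bar width (default 9).
#' @param support number of taps, odd (default 25, i.e. +/-108 arcmin, where
#'   the DOG tails are < 1e-4 of the peak).
#' @return object of class `"dog_spec"`.
#' @export
dog_spec <- function(k = 4, sigma1 = 5, sigma2 = 20, spacing = 9, support = 25L) {
  if (support %% 2 != 1) stop("'support' must be odd")
  if (!(sigma1 < sigma2)) stop("'sigma1' must be smaller than 'sigma2'")
  structure(list(k = k, sigma1 = sigma1, sigma2 = sigma2,
                 spacing = spacing, support = as.integer(support)),
            class = "dog_spec")
}

#' Unit-energy difference-of-Gaussians filter
#'
#' Taps `f_i = k * phi(x_i, sigma1) - phi(x_i, sigma2)` on the stimulus
#' sampling grid, normalised to unit energy (sum of squared taps = 1). The
#' result is the customary Mexican-hat profile: positive centre, negative
#' surround.
#'
#' @param spec a [dog_spec()].
#' @return numeric vector of `spec$support` taps with attribute `"x"` (tap
#'   positions in arcmin).
#' @export
dog_filter <- function(spec = dog_spec()) {
  stopifnot(inherits(spec, "dog_spec"))
  half <- spec$support %/% 2
  x <- (-half:half) * spec$spacing
  f <- spec$k * stats::dnorm(x, 0, spec$sigma1) - stats::dnorm(x, 0, spec$sigma2)
  f <- f / sqrt(sum(f^2))
  attr(f, "x") <- x
  f
}

# Banded matrix applying 'same' convolution with zero padding: row i of the
# output is sum_j f[i-j] s[j]; background luminance is 0 in contrast units,
# so zero padding is the physically neutral boundary.
conv_matrix <- function(f, n_bars) {
  half <- (length(f) - 1) %/% 2
  d <- outer(seq_len(n_bars), seq_len(n_bars), "-")
  M <- matrix(0, n_bars, n_bars)
  keep <- abs(d) <= half
  M[keep] <- f[half + 1 + d[keep]]
  M
}

#' Front-end convolution
#'
#' Applies the front-end filter to a stimulus by 'same' convolution with
#' zero-padded boundaries, returning one output per bar position.
#'
#' @param s stimulus vector (length `n_bars`) or matrix (`n_bars` x trials).
#' @param f filter taps (odd length), e.g. from [dog_filter()].
#' @return vector or matrix of the same shape as `s`.
#' @export
frontend <- function(s, f) {
  v <- is.null(dim(s))
  S <- if (v) matrix(s, ncol = 1) else s
  out <- conv_matrix(f, nrow(S)) %*% S
  if (v) drop(out) else out
}

#' Divisive gain control of the linear branch
#'
#' `b / (10 + (sum(b))^2)`: the pooled (signed-sum) output is squared inside
#' the normalisation, so squaring never acts on individual filter outputs
#' along this branch.
#'
#' @param b linear-branch output vector or matrix (columns = stimuli).
#' @return gain-controlled output, same shape.
#' @export
gain_control_linear <- function(b) {
  if (is.null(dim(b))) return(b / (10 + sum(b)^2))
  sweep(b, 2, 10 + colSums(b)^2, "/")
}

#' Divisive gain control of the nonlinear (energy) branch
#'
#' `b / (0.4 + sum(b))`, defined for the squared (non-negative) branch output.
#'
#' @param b nonlinear-branch output (elementwise >= 0), vector or matrix.
#' @return gain-controlled output, same shape. The column sums of the output
#'   are `S/(0.4+S) < 1`, i.e. the pooled energy saturates.
#' @export
gain_control_nonlinear <- function(b) {
  if (any(b < 0)) stop("nonlinear-branch input must be elementwise non-negative")
  if (is.null(dim(b))) return(b / (0.4 + sum(b)))
  sweep(b, 2, 0.4 + colSums(b), "/")
}

#' Gaussian read-out weighting profile
#'
#' The attentional window: a Gaussian of SD `sigma_w` (arcmin) evaluated at
#' the bar positions, centred on the target bar, peak 1 (not renormalised).
#'
#' @param sigma_w window SD in arcmin.
#' @param n_bars,center,spacing bar geometry.
#' @return numeric vector of length `n_bars`.
#' @export
readout_weights <- function(sigma_w, n_bars = 13L, center = 7L, spacing = 9) {
  x <- (seq_len(n_bars) - center) * spacing
  exp(-x^2 / (2 * sigma_w^2))
}

#' Model-observer configuration
#'
#' Parameterises one model observer. Variants follow the two-branch family:
#' `"template"` (#1, linear branch only), `"energy"` (#2, squaring branch
#' only), `"gc_energy"` (#3, gain-controlled energy branch), `"hybrid_gc_nlin"`
#' (#4, linear + gain-controlled energy), `"hybrid_gc_both"` (#5, both
#' branches gain-controlled; switches to its own front-end defaults k = 6,
#' sigma1 = 2.5, sigma2 = 10 arcmin and sigma_w = 10 arcmin), and `"max"`
#' (MAX uncertainty rule over weighted linear-filter outputs, with an
#' attentional window that broadens as contrast drops).
#'
#' The intrinsic noise `e` is zero-mean Gaussian, iid across positions and
#' drawn fresh for every stimulus; its SD is fixed for a given observer.
#' `noise_location = "early"` injects it before the squaring of the energy
#' branch, `(s*f + e)^2`; `noise_scaling = "response_dependent"` scales it by
#' the magnitude of the front-end output (`b_i + |b_i| e_i`).
#'
#' `input_gain` converts stored stimulus contrast units into the front-end's
#' operating units (default 0.3 * 1/3 = 0.1 per contrast unit), chosen so that
#' the energy-branch normalisation pool crosses its semi-saturation constant
#' (0.4) within the experimental contrast range; this is what lets the hybrid
#' variants transition from energy-dominated to linear behaviour as contrast
#' grows (see the package vignette).
#'
#' @param variant observer architecture, see Details.
#' @param dog front-end filter spec; default [dog_spec()] (overridden for
#'   variant `"hybrid_gc_both"` unless supplied explicitly).
#' @param sigma_w read-out window SD in arcmin (default 40).
#' @param noise_sd SD of the intrinsic noise `e`; usually set by
#'   [calibrate_noise_sd()].
#' @param noise_location `"late"` (after squaring) or `"early"` (before).
#' @param noise_scaling `"response_independent"` or `"response_dependent"`.
#' @param max_sigma_w named map from contrast level (1..4) to window SD in
#'   arcmin for the MAX observer (default 160, 120, 80, 40: broader window at
#'   lower contrast).
#' @param input_gain front-end gain per stimulus contrast unit.
#' @return object of class `"observer_config"`.
#' @export
observer_config <- function(variant = c("template", "energy", "gc_energy",
                                        "hybrid_gc_nlin", "hybrid_gc_both", "max"),
                            dog = NULL, sigma_w = NULL, noise_sd = 0,
                            noise_location = c("late", "early"),
                            noise_scaling = c("response_independent",
                                              "response_dependent"),
                            max_sigma_w = c(`1` = 160, `2` = 120, `3` = 80, `4` = 40),
                            input_gain = 0.1) {
  variant <- match.arg(variant)
  noise_location <- match.arg(noise_location)
  noise_scaling <- match.arg(noise_scaling)
  if (is.null(dog))
    dog <- if (variant == "hybrid_gc_both") dog_spec(k = 6, sigma1 = 2.5, sigma2 = 10)
           else dog_spec()
  if (is.null(sigma_w))
    sigma_w <- if (variant == "hybrid_gc_both") 10 else 40
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  structure(list(variant = variant, dog = dog, sigma_w = sigma_w,
                 noise_sd = noise_sd, noise_location = noise_location,
                 noise_scaling = noise_scaling, max_sigma_w = max_sigma_w,
                 input_gain = input_gain),
            class = "observer_config")
}

#' @export
print.observer_config <- function(x, ...) {
  cat(sprintf("<observer_config> variant=%s sigma_w=%g noise_sd=%g (%s, %s) input_gain=%g\n",
              x$variant, x$sigma_w, x$noise_sd, x$noise_location,
              x$noise_scaling, x$input_gain))
  invisible(x)
}

# Core decision-variable engine, vectorised over stimulus columns.
# S: n_bars x m stimulus matrix in contrast units. Returns length-m vector.
decision_variable_matrix <- function(S, config, contrast_level = NULL,
                                     n_bars = nrow(S), center = (nrow(S) + 1) %/% 2) {
  f <- dog_filter(config$dog)
  B <- frontend(config$input_gain * S, f)
  m <- ncol(B)
  E <- matrix(stats::rnorm(n_bars * m, 0, config$noise_sd), n_bars, m)
  if (config$noise_scaling == "response_dependent") E <- abs(B) * E

  if (config$variant == "max") {
    if (is.null(contrast_level)) stop("MAX observer needs the trial contrast level")
    sw <- config$max_sigma_w[as.character(contrast_level)]
    if (length(unique(sw)) == 1) {
      w <- readout_weights(sw[1], n_bars, center, config$dog$spacing)
      return(apply(w * B + E, 2, max))
    }
    W <- vapply(sw, readout_weights, numeric(n_bars),
                n_bars = n_bars, center = center, spacing = config$dog$spacing)
    return(apply(W * B + E, 2, max))
  }

  w <- readout_weights(config$sigma_w, n_bars, center, config$dog$spacing)
  early <- config$noise_location == "early"
  branch <- switch(config$variant,
    template = B + E,   # early vs late is immaterial along a linear branch
    energy = if (early) (B + E)^2 else B^2 + E,
    gc_energy = if (early) gain_control_nonlinear((B + E)^2)
                else gain_control_nonlinear(B^2) + E,
    hybrid_gc_nlin = if (early) B + gain_control_nonlinear((B + E)^2)
                     else B + gain_control_nonlinear(B^2) + E,
    hybrid_gc_both = if (early)
        gain_control_linear(B) + gain_control_nonlinear((B + E)^2)
      else gain_control_linear(B) + gain_control_nonlinear(B^2) + E)
  drop(crossprod(branch, w))
}

#' Decision variable for one stimulus
#'
#' Computes the scalar figure of merit the observer assigns to a stimulus:
#' the weighted sum (or maximum, for the MAX rule) of the configured branch
#' outputs plus a fresh draw of intrinsic noise.
#'
#' @param s stimulus vector (contrast units) or `n_bars` x m matrix.
#' @param config an [observer_config()].
#' @param contrast_level contrast level of the trial(s); required for the MAX
#'   observer, whose window SD depends on it.
#' @return scalar (or length-m vector) decision variable.
#' @export
decision_variable <- function(s, config, contrast_level = NULL) {
  v <- is.null(dim(s))
  S <- if (v) matrix(s, ncol = 1) else s
  r <- decision_variable_matrix(S, config, contrast_level)
  if (v) r[1] else r
}

#' Simulate observer responses on a trial set
#'
#' Computes decision variables for both stimuli of every trial (independent
#' intrinsic-noise draws per stimulus) and applies the difference rule: the
#' target stimulus is chosen iff `r1 - r0 > 0`; ties (difference <= 0) go to
#' the non-target.
#'
#' @param trials a `trial_set`.
#' @param config an [observer_config()].
#' @return data frame with one row per trial: `block_id`, `trial_index`, `r0`,
#'   `r1`, `response` (1 = chose target stimulus), `correct` (logical; equal
#'   to `response` here because responses are coded by stimulus identity).
#' @export
respond <- function(trials, config) {
  stopifnot(inherits(trials, "trial_set"), inherits(config, "observer_config"))
  s <- stimulus_matrices(trials)
  r0 <- decision_variable_matrix(s$s0, config, trials$contrast_level,
                                 trials$n_bars, trials$center)
  r1 <- decision_variable_matrix(s$s1, config, trials$contrast_level,
                                 trials$n_bars, trials$center)
  resp <- as.integer(r1 - r0 > 0)
  data.frame(block_id = trials$block_id, trial_index = trials$trial_index,
             r0 = r0, r1 = r1, response = resp, correct = resp == 1L)
}

#' Simulate a session
#'
#' Thin wrapper over [respond()]: double-pass repeats replay the stored
#' stimuli while intrinsic noise is drawn fresh for every presentation.
#'
#' @inheritParams respond
#' @return response data frame, see [respond()].
#' @export
simulate_session <- function(trials, config) respond(trials, config)

#' Ideal-observer responses
#'
#' The ideal observer applies the template `t^[1] - t^[0]` to the stimulus
#' difference and responds by its sign (ties to non-target). For the bar
#' tasks this reduces to comparing the centre bars. It is undefined for the
#' mixed-polarity task (no fixed template exists).
#'
#' @param trials a `trial_set`.
#' @return response data frame as in [respond()].
#' @export
ideal_respond <- function(trials) {
  stopifnot(inherits(trials, "trial_set"))
  if (any(trials$task == "mixed"))
    stop("the ideal template observer is undefined for the mixed-polarity task")
  s <- stimulus_matrices(trials)
  tmpl <- trials$t1 - trials$t0   # centre offset of the template, per trial
  d <- tmpl * (s$s1[trials$center, ] - s$s0[trials$center, ])
  resp <- as.integer(d > 0)
  data.frame(block_id = trials$block_id, trial_index = trials$trial_index,
             r0 = 0, r1 = d, response = resp, correct = resp == 1L)
}

#' Calibrate the intrinsic-noise SD to threshold performance
#'
#' Searches (bisection on log SD) for the intrinsic-noise SD at which the
#' observer's mean d' over the supplied condition grid equals
#' `target_dprime` (default 1, i.e. threshold). d' per condition is computed
#' from simulated proportion correct via `sqrt(2) * qnorm(pc)`. Simulations
#' reuse a common set of stimuli and unit-variance noise draws across SD
#' candidates, making the objective deterministic and monotone in SD.
#'
#' Architectures whose external-noise-limited ceiling (mean d' at SD 0) lies
#' below the target admit no solution; by default this raises an error. With
#' `target = "ceiling_fraction"` the function instead targets
#' `ceiling / sqrt(2)`, i.e. an intrinsic-noise source whose contribution to
#' the decision variable matches the external drive (internal noise near 1 in
#' external-noise units, the centre of the empirically plausible range).
#'
#' @param config an [observer_config()] (its `noise_sd` is ignored).
#' @param conditions list of [condition_spec()]s; default the 4x4 bright grid.
#' @param n_trials_per_condition simulated trials per condition and SD probe.
#' @param target_dprime target mean d'.
#' @param tol acceptable |mean d' - target|.
#' @param target `"absolute"` or `"ceiling_fraction"` (see Details).
#' @param max_iter bisection iterations.
#' @return the input config with `noise_sd` set; attributes `"mean_dprime"`
#'   (achieved value) and `"ceiling"` (noiseless mean d').
#' @export
calibrate_noise_sd <- function(config, conditions = condition_grid("bright"),
                               n_trials_per_condition = 2000,
                               target_dprime = 1, tol = 0.05,
                               target = c("absolute", "ceiling_fraction"),
                               max_iter = 40L) {
  target <- match.arg(target)
  if (length(conditions) == 0) stop("'conditions' must be non-empty")
  # Precompute stimuli and frozen unit-noise draws per condition.
  sets <- lapply(conditions, make_trials, n = n_trials_per_condition)
  frozen <- lapply(sets, function(tr) {
    m <- n_trials(tr)
    list(tr = tr,
         e0 = matrix(stats::rnorm(tr$n_bars * m), tr$n_bars, m),
         e1 = matrix(stats::rnorm(tr$n_bars * m), tr$n_bars, m))
  })
  mean_dprime <- function(sd) {
    d <- vapply(frozen, function(fz) {
      cfg <- config; cfg$noise_sd <- sd
      r0 <- dv_frozen(fz$tr, cfg, fz$e0, q = 0)
      r1 <- dv_frozen(fz$tr, cfg, fz$e1, q = 1)
      pc <- mean(r1 - r0 > 0)
      pc <- min(max(pc, 1 / (2 * length(r0))), 1 - 1 / (2 * length(r0)))
      sqrt(2) * stats::qnorm(pc)
    }, numeric(1))
    mean(d)
  }
  ceiling_d <- mean_dprime(0)
  tgt <- target_dprime
  if (ceiling_d < target_dprime - tol) {
    if (target == "absolute")
      stop(sprintf(paste0("calibration failure: noiseless mean d' (%.3f) is below ",
                          "the target (%.2f); intrinsic noise cannot raise d'"),
                   ceiling_d, target_dprime))
    tgt <- ceiling_d / sqrt(2)
  }
  lo <- 1e-4; hi <- 1
  while (mean_dprime(hi) > tgt && hi < 1e6) hi <- hi * 4
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    if (mean_dprime(mid) > tgt) lo <- mid else hi <- mid
    if (log(hi / lo) < 1e-3) break
  }
  sd <- sqrt(lo * hi)
  achieved <- mean_dprime(sd)
  if (abs(achieved - tgt) > tol)
    warning(sprintf("calibration achieved mean d' %.3f for target %.3f", achieved, tgt))
  config$noise_sd <- sd
  attr(config, "mean_dprime") <- achieved
  attr(config, "ceiling") <- ceiling_d
  config
}

# Decision variables with externally supplied standard-normal noise draws
# (scaled by config$noise_sd); used by the calibration to keep the objective
# deterministic across SD candidates.
dv_frozen <- function(trials, config, E_unit, q) {
  s <- stimulus_matrices(trials)
  S <- if (q == 1) s$s1 else s$s0
  f <- dog_filter(config$dog)
  B <- frontend(config$input_gain * S, f)
  E <- config$noise_sd * E_unit
  if (config$noise_scaling == "response_dependent") E <- abs(B) * E
  n_bars <- trials$n_bars; center <- trials$center
  if (config$variant == "max") {
    sw <- config$max_sigma_w[as.character(trials$contrast_level)]
    W <- vapply(sw, readout_weights, numeric(n_bars),
                n_bars = n_bars, center = center, spacing = config$dog$spacing)
    return(apply(W * B + E, 2, max))
  }
  w <- readout_weights(config$sigma_w, n_bars, center, config$dog$spacing)
  early <- config$noise_location == "early"
  branch <- switch(config$variant,
    template = B + E,
    energy = if (early) (B + E)^2 else B^2 + E,
    gc_energy = if (early) gain_control_nonlinear((B + E)^2)
                else gain_control_nonlinear(B^2) + E,
    hybrid_gc_nlin = if (early) B + gain_control_nonlinear((B + E)^2)
                     else B + gain_control_nonlinear(B^2) + E,
    hybrid_gc_both = if (early)
        gain_control_linear(B) + gain_control_nonlinear((B + E)^2)
      else gain_control_linear(B) + gain_control_nonlinear(B^2) + E)
  drop(crossprod(branch, w))
}
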