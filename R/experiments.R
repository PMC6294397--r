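#' Full in-silico replication over the contrast-by-SNR grid
#'
#' For every cell of the 4x4 condition grid: simulates `n_sims` independent
#' sessions of `n_trials_per_condition` trials, computes classification-image
#' descriptors and drives per session (averaged across sessions), simulates
#' `n_doublepass_blocks` 50-trial double-pass blocks and fits the
#' internal-noise model, and derives the scalar metrics (d', efficiency,
#' sharpness, linearity). Metric surfaces, their contrast/SNR dependence
#' coefficients and separability indices are assembled from the per-cell
#' values.
#'
#' The linearity index rectifies marker 2 with an architecture-level sign:
#' the rectifier is 1 when the grid-pooled second-order drive exceeds its
#' pooled SE by the 3x null-band criterion (genuine second-order structure
#' somewhere in the grid) and 0 otherwise (see [nonlinearity_index()]).
#' Estimating the sign per cell would inject `lambda1`-sized jumps wherever a
#' cell's `lambda2` estimate straddles 0 — the non-monotonicity pitfall of
#' this marker — whereas the presence of genuine second-order structure is a
#' property of the observer architecture, not of a single condition; and an
#' RMS *deficit* relative to the decoupled floor (negative `lambda2`, a
#' decisional-transducer artifact) is never evidence of nonlinear processing.
#'
#' @param config an [observer_config()] with calibrated `noise_sd`.
#' @param task task name (default `"bright"`).
#' @param n_trials_per_condition trials per simulated session.
#' @param n_sims replicate sessions per cell whose drives are averaged.
#' @param n_doublepass_blocks 50-trial double-pass blocks per cell.
#' @return object of class `"grid_result"`: `per_condition` (data frame, one
#'   row per cell), `surfaces` (named list of [metric_surface()]s),
#'   `dependence` (data frame of contrast and SNR Pearson coefficients per
#'   metric) and `separability` (SVD index and relative residual of the
#'   separable prediction per metric).
#' @export
run_grid <- function(config, task = "bright", n_trials_per_condition = 6000,
                     n_sims = 4L, n_doublepass_blocks = 30L) {
  stopifnot(inherits(config, "observer_config"))
  conds <- condition_grid(task)
  rows <- vector("list", length(conds))
  for (i in seq_along(conds)) {
    cond <- conds[[i]]
    lam <- matrix(NA_real_, 4, n_sims,
                  dimnames = list(c("lambda1", "lambda1_tp", "lambda1_ta", "lambda2"), NULL))
    sh <- pcs <- numeric(n_sims)
    for (s in seq_len(n_sims)) {
      tr <- make_trials(cond, n_trials_per_condition)
      re <- respond(tr, config)
      ds <- drive_set(classify_noise(tr, re))
      lam[, s] <- c(ds$lambda1, ds$lambda1_tp, ds$lambda1_ta, ds$lambda2)
      sh[s] <- sharpness(ds$h)
      pcs[s] <- mean(re$correct)
    }
    lam_mean <- rowMeans(lam)
    l2_se <- if (n_sims > 1) stats::sd(lam["lambda2", ]) / sqrt(n_sims)
             else null_lambda2_sd(cond, config, n_trials_per_condition)
    dp <- make_session(list(cond), n_doublepass_blocks, "double_pass")
    dp_re <- respond(dp, config)
    dp_sum <- summarize_double_pass(dp_re, dp)
    est <- tryCatch(estimate_internal_noise(dp_sum),
                    error = function(e) list(dprime_in = NA, n_int = NA,
                                             plausible = NA))
    m_tot <- n_sims * n_trials_per_condition
    d <- dprime_from_pc(mean(pcs), m = m_tot)
    rows[[i]] <- data.frame(
      task = cond$task, contrast_level = cond$contrast_level,
      snr_level = cond$snr_level, pc = mean(pcs), dprime = d,
      efficiency = efficiency(d, cond$snr_level),
      sharpness = mean(sh),
      lambda1 = lam_mean["lambda1"], lambda1_tp = lam_mean["lambda1_tp"],
      lambda1_ta = lam_mean["lambda1_ta"], lambda2 = lam_mean["lambda2"],
      lambda2_se = l2_se,
      pa = dp_sum$pa, n_int = est$n_int, dprime_in = est$dprime_in,
      n_int_plausible = est$plausible, row.names = NULL)
  }
  per_condition <- do.call(rbind, rows)
  # Architecture-level rectifying sign for marker 2: the grid-pooled lambda2
  # against its pooled SE, same 3x gate as eigenvalue significance. The gate
  # is one-sided: only a significant RMS *excess* over the decoupled floor
  # (lambda2 > 0) counts as second-order structure; a deficit is a
  # decisional-transducer artifact, not evidence of nonlinear processing.
  pooled_l2 <- mean(per_condition$lambda2)
  pooled_se <- sqrt(sum(per_condition$lambda2_se^2)) / nrow(per_condition)
  s2 <- if (pooled_l2 > 3 * pooled_se) 1 else 0
  nli <- lapply(seq_len(nrow(per_condition)), function(i)
    nonlinearity_index(per_condition$lambda1_tp[i], per_condition$lambda1_ta[i],
                       per_condition$lambda1[i], per_condition$lambda2[i],
                       sign_lambda2 = s2))
  per_condition$marker1 <- vapply(nli, `[[`, numeric(1), "marker1")
  per_condition$marker2 <- vapply(nli, `[[`, numeric(1), "marker2")
  per_condition$linearity <- vapply(nli, `[[`, numeric(1), "linearity")
  attr(per_condition, "sign_lambda2") <- s2
  metric_names <- c("dprime", "efficiency", "sharpness", "linearity",
                    "n_int", "lambda1", "lambda2", "marker1")
  surfaces <- lapply(metric_names, function(mn) {
    M <- matrix(NA_real_, 4, 4)
    M[cbind(per_condition$snr_level, per_condition$contrast_level)] <-
      per_condition[[mn]]
    metric_surface(M, mn)
  })
  names(surfaces) <- metric_names
  dep <- do.call(rbind, lapply(metric_names, function(mn) {
    s <- surfaces[[mn]]
    data.frame(metric = mn,
               contrast = tryCatch(dependence(s, "contrast"),
                                   error = function(e) NA_real_),
               snr = tryCatch(dependence(s, "snr"), error = function(e) NA_real_))
  }))
  sep <- do.call(rbind, lapply(metric_names, function(mn) {
    M <- surfaces[[mn]]$values
    ok <- all(is.finite(M)) && any(M != 0)
    data.frame(metric = mn,
               svd_index = if (ok) svd_index(M) else NA_real_,
               residual = if (ok && sum(M) != 0)
                 norm(M - separability_prediction(M), "F") / norm(M, "F")
               else NA_real_)
  }))
  structure(list(per_condition = per_condition, surfaces = surfaces,
                 dependence = dep, separability = sep,
                 config = config, n_trials_per_condition = n_trials_per_condition,
                 n_sims = n_sims),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %s observer, %d x %d trials per cell\n",
              x$config$variant, x$n_sims, x$n_trials_per_condition))
  print(x$dependence, row.names = FALSE)
  invisible(x)
}

# Decoupled-shuffle null SD of lambda2 for a single-session grid cell.
null_lambda2_sd <- function(cond, config, n_trials, n_shuffles = 20L) {
  tr <- make_trials(cond, n_trials)
  re <- respond(tr, config)
  vals <- vapply(seq_len(n_shuffles), function(i) {
    drive_set(classify_noise(tr, decouple(re)))$lambda2
  }, numeric(1))
  stats::sd(vals)
}

#' Restrict a session to the first trial of each block
#'
#' Data-selection filter used to test whether perceptual tuning reflects
#' within-block adaptation: keeps only trial 1 of every block (2% of the data
#' at 50-trial blocks).
#'
#' @param trials a `trial_set`.
#' @return a `trial_set` with one trial per block.
#' @export
first_trial_filter <- function(trials) {
  subset_trials(trials, trials$trial_index == 1L)
}

#' Threshold-versus-pedestal (dipper) simulation
#'
#' Contrast discrimination with noiseless bar stimuli: the non-target casts
#' the pedestal `rho0` on the centre bar, the target `rho0 + delta`. For each
#' pedestal, `delta` is swept geometrically, proportion correct is measured
#' over `n_trials` simulated 2AFC trials, and the 75%-correct threshold is
#' interpolated (linearly in percent correct versus log delta); this is
#' repeated `n_sims` times and averaged. The branch architectures are the
#' hybrid two-branch model (linear + gain-controlled energy), its linear
#' branch alone, and its gain-controlled energy branch alone.
#'
#' Pedestal placement: 0 (detection) plus `n_pedestals` log-spaced values
#' spanning two orders of magnitude anchored around the hybrid model's
#' detection threshold (from half a decade below to 1.5 decades above),
#' unless `pedestals` is supplied.
#'
#' @param noise_sd intrinsic-noise SD shared by all branch configurations.
#' @param branches subset of `c("hybrid", "linear", "nonlinear")`.
#' @param n_pedestals number of nonzero pedestal values.
#' @param n_sims simulation repeats per pedestal.
#' @param n_trials trials per delta probe and simulation.
#' @param n_delta delta probes per sweep.
#' @param pedestals optional explicit pedestal vector (contrast units).
#' @param input_gain front-end gain, as in [observer_config()].
#' @return object of class `"dipper_result"`: `pedestals` and, per branch,
#'   a matrix of per-simulation thresholds plus their mean and SD.
#' @export
dipper <- function(noise_sd, branches = c("hybrid", "linear", "nonlinear"),
                   n_pedestals = 10L, n_sims = 25L, n_trials = 1000L,
                   n_delta = 20L, pedestals = NULL, input_gain = 0.1) {
  branches <- match.arg(branches, several.ok = TRUE)
  cfg_of <- function(branch) observer_config(
    switch(branch, hybrid = "hybrid_gc_nlin", linear = "template",
           nonlinear = "gc_energy"),
    noise_sd = noise_sd, input_gain = input_gain)
  # Anchor the pedestal range at the hybrid detection threshold.
  if (is.null(pedestals)) {
    det <- dipper_threshold(cfg_of(branches[1]), pedestal = 0,
                            n_trials = 4 * n_trials, n_delta = n_delta)
    pedestals <- c(0, det * 10^seq(-0.5, 1.5, length.out = n_pedestals))
  } else if (!0 %in% pedestals) pedestals <- c(0, pedestals)
  out <- list()
  for (br in branches) {
    cfg <- cfg_of(br)
    th <- matrix(NA_real_, n_sims, length(pedestals))
    for (j in seq_along(pedestals)) for (s in seq_len(n_sims))
      th[s, j] <- dipper_threshold(cfg, pedestals[j], n_trials, n_delta,
                                   on_failure = "na")
    out[[br]] <- list(thresholds = th, mean = colMeans(th),
                      sd = apply(th, 2, stats::sd))
    # NA columns: performance ceiling below 75% (saturated branch)
  }
  structure(list(pedestals = pedestals, branches = out,
                 noise_sd = noise_sd, n_sims = n_sims, n_trials = n_trials),
            class = "dipper_result")
}

#' @export
print.dipper_result <- function(x, ...) {
  cat(sprintf("<dipper_result> %d pedestals, %d sims x %d trials; branches: %s\n",
              length(x$pedestals), x$n_sims, x$n_trials,
              paste(names(x$branches), collapse = ", ")))
  invisible(x)
}

# 75%-correct delta threshold at one pedestal for one observer config.
# Geometric delta sweep, auto-expanded (up to 3 times) until the psychometric
# range brackets 75%. A gain-controlled branch can saturate so that 75% is
# unattainable at large pedestals (vertical TvC handle); with
# on_failure = "na" this is reported as NA instead of an error.
dipper_threshold <- function(config, pedestal, n_trials, n_delta,
                             sweep_center = NULL, sweep_decades = 1.2,
                             on_failure = c("error", "na")) {
  on_failure <- match.arg(on_failure)
  n_bars <- 13L; center <- 7L
  if (is.null(sweep_center))
    sweep_center <- dipper_sweep_guess(config, pedestal)
  for (expansion in 0:3) {
    dec <- sweep_decades * 2^expansion
    delta <- sweep_center * 10^seq(-dec, dec, length.out = n_delta)
    S1 <- matrix(0, n_bars, n_delta * n_trials)
    S1[center, ] <- pedestal + rep(delta, each = n_trials)
    S0 <- matrix(0, n_bars, n_delta * n_trials)
    S0[center, ] <- pedestal
    r1 <- decision_variable_matrix(S1, config)
    r0 <- decision_variable_matrix(S0, config)
    pcs <- colMeans(matrix(r1 - r0 > 0, n_trials, n_delta))
    if (min(pcs) < 0.75 && max(pcs) > 0.75) {
      hi <- which(pcs >= 0.75)[1]
      if (hi == 1) return(delta[1])
      lo <- hi - 1L
      ld <- log(delta[lo]) + (0.75 - pcs[lo]) / (pcs[hi] - pcs[lo]) *
        (log(delta[hi]) - log(delta[lo]))
      return(exp(ld))
    }
    sweep_center <- if (min(pcs) >= 0.75) sweep_center / 5 else sweep_center * 5
  }
  if (on_failure == "na") return(NA_real_)
  stop("psychometric sweep failed to bracket 75% correct after 3 expansions")
}

# Cheap starting guess for the delta sweep: the 75%-correct signal scale of
# whichever branch (linear or quadratic) is more sensitive at this pedestal.
dipper_sweep_guess <- function(config, pedestal) {
  w <- readout_weights(config$sigma_w)
  f <- dog_filter(config$dog)
  t7 <- frontend(replace(numeric(13), 7, 1), f)
  tgt <- 0.674 * sqrt(2) * max(config$noise_sd, 1e-6) * sqrt(sum(w^2))
  g <- config$input_gain
  d_lin <- tgt / (g * sum(w * t7))
  q <- sum(w * t7^2) / 0.4                    # small-signal quadratic gain
  p <- pedestal
  d_quad <- -p + sqrt(p^2 + tgt / (g^2 * q))
  has_lin <- config$variant %in% c("template", "hybrid_gc_nlin", "hybrid_gc_both")
  has_quad <- config$variant %in% c("energy", "gc_energy",
                                    "hybrid_gc_nlin", "hybrid_gc_both")
  cand <- c(if (has_lin) d_lin, if (has_quad) d_quad)
  max(min(cand), 1e-4) + 0.05 * pedestal
}
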