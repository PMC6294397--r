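#' Stimulus condition specification
#'
#' Defines one cell of the contrast-by-SNR condition grid for the noisy-bar
#' tasks. Stimuli are 1-D arrays of `n_bars` vertical bars whose luminances are
#' stored in "contrast units": one unit is one step of the monitor's luminance
#' noise quantum (0.3 cd/m2 against the 30 cd/m2 background), so that the
#' noise SD equals the contrast multiplier numerically.
#'
#' @param task one of `"bright"` (bright-bar detection), `"dark"` (dark-bar
#'   detection), `"mixed"` (mixed-polarity detection: target polarity drawn at
#'   random each trial) or `"polarity"` (polarity discrimination: non-target
#'   carries the opposite-sign bar).
#' @param contrast_level integer 1..4, mapping to noise SD multipliers
#'   c = 1, 2, 4, 8.
#' @param snr_level integer 1..4; the target offset magnitude is
#'   `snr_level * sigma_N`, so `snr_level` equals the stimulus SNR.
#' @param n_bars number of bars (default 13).
#' @param center index of the target bar (default 7, the middle bar).
#' @return An object of class `"condition_spec"`: a list with the arguments
#'   plus `sigma_N` (noise SD in contrast units) and `rho1`, `rho0` (target /
#'   non-target centre offsets; `rho1` is `NA` for `"mixed"`, where its sign is
#'   drawn per trial).
#' @examples
#' cond <- condition_spec("bright", contrast_level = 4, snr_level = 2)
#' cond$sigma_N   # 8
#' cond$rho1      # 16
#' @export
condition_spec <- function(task = c("bright", "dark", "mixed", "polarity"),
                           contrast_level, snr_level,
                           n_bars = 13L, center = 7L) {
  task <- match.arg(task)
  stopifnot(length(contrast_level) == 1, length(snr_level) == 1)
  if (!contrast_level %in% 1:4) stop("'contrast_level' must be an integer in 1..4")
  if (!snr_level %in% 1:4) stop("'snr_level' must be an integer in 1..4")
  if (n_bars < 1) stop("'n_bars' must be >= 1")
  if (center < 1 || center > n_bars) stop("'center' must lie within 1..n_bars")
  sigma <- contrast_multiplier(contrast_level)
  mag <- snr_level * sigma
  rho1 <- switch(task, bright = mag, dark = -mag, polarity = mag, mixed = NA_real_)
  rho0 <- switch(task, bright = 0, dark = 0, polarity = -mag, mixed = 0)
  structure(list(task = task,
                 contrast_level = as.integer(contrast_level),
                 snr_level = as.integer(snr_level),
                 n_bars = as.integer(n_bars), center = as.integer(center),
                 sigma_N = sigma, rho1 = rho1, rho0 = rho0),
            class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("<condition_spec> task=%s contrast_level=%d (sigma_N=%g) snr_level=%d\n",
              x$task, x$contrast_level, x$sigma_N, x$snr_level))
  invisible(x)
}

#' Contrast multiplier for a contrast level
#'
#' The four logarithmically spaced noise-contrast multipliers.
#' @param level integer vector with values in 1..4.
#' @return numeric vector of multipliers from {1, 2, 4, 8}.
#' @export
contrast_multiplier <- function(level) {
  if (any(!level %in% 1:4)) stop("contrast level must be in 1..4")
  c(1, 2, 4, 8)[level]
}

#' Gaussian luminance-noise profile
#'
#' Draws one noise component: `n_bars` independent zero-mean Gaussian
#' luminances with SD `sigma_N` (contrast units).
#'
#' @param sigma_N noise SD, >= 0.
#' @param n_bars number of bars.
#' @return numeric vector of length `n_bars`.
#' @export
noise_profile <- function(sigma_N, n_bars = 13L) {
  if (!is.numeric(sigma_N) || length(sigma_N) != 1 || is.na(sigma_N) || sigma_N < 0)
    stop("'sigma_N' must be a single non-negative number")
  stats::rnorm(n_bars, 0, sigma_N)
}

#' Deterministic target/signal profile
#'
#' Zero everywhere except the centre bar, which carries the task-dependent
#' luminance offset `rho^[q]`. For the mixed-polarity task the sign of the
#' target offset is drawn equiprobably at each call.
#'
#' @param condition a [condition_spec()].
#' @param q interval flag: 1 for the target stimulus, 0 for the non-target.
#' @return numeric vector of length `condition$n_bars`.
#' @export
target_profile <- function(condition, q) {
  stopifnot(inherits(condition, "condition_spec"), q %in% c(0, 1))
  t <- numeric(condition$n_bars)
  rho <- if (q == 1) {
    if (condition$task == "mixed") {
      sgn <- if (stats::runif(1) < 0.5) 1 else -1
      sgn * condition$snr_level * condition$sigma_N
    } else condition$rho1
  } else condition$rho0
  t[condition$center] <- rho
  t
}

new_trial_set <- function(n0, n1, t0, t1, side, condition, block_id, trial_index,
                          pass_mate) {
  m <- ncol(n0)
  structure(list(
    n0 = n0, n1 = n1, t0 = t0, t1 = t1, side = side,
    task = rep(condition$task, m),
    contrast_level = rep(condition$contrast_level, m),
    snr_level = rep(condition$snr_level, m),
    sigma_N = rep(condition$sigma_N, m),
    block_id = block_id, trial_index = trial_index, pass_mate = pass_mate,
    n_bars = condition$n_bars, center = condition$center),
    class = "trial_set")
}

#' Number of trials in a trial set
#' @param trials a `trial_set`.
#' @return integer trial count.
#' @export
n_trials <- function(trials) {
  stopifnot(inherits(trials, "trial_set"))
  ncol(trials$n0)
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials, %d bars, %d block(s), tasks: %s\n",
              n_trials(x), x$n_bars, length(unique(x$block_id)),
              paste(unique(x$task), collapse = ",")))
  invisible(x)
}

#' Stimulus matrices of a trial set
#'
#' Reconstructs the physical stimuli `s^[q] = n^[q] + t^[q]` from the stored
#' noise components and centre offsets.
#'
#' @param trials a `trial_set`.
#' @return list with matrices `s0` and `s1` (`n_bars` x trials).
#' @export
stimulus_matrices <- function(trials) {
  s0 <- trials$n0; s1 <- trials$n1
  s0[trials$center, ] <- s0[trials$center, ] + trials$t0
  s1[trials$center, ] <- s1[trials$center, ] + trials$t1
  list(s0 = s0, s1 = s1)
}

#' Generate independent trials of one condition
#'
#' Each trial holds fresh noise components for the two intervals, the
#' deterministic signal offsets, and a uniformly random side assignment
#' (bookkeeping only: the analysis works with stimulus identity, not screen
#' side).
#'
#' @param condition a [condition_spec()].
#' @param n number of trials.
#' @param block_id block label for the generated trials.
#' @return a `trial_set`.
#' @export
make_trials <- function(condition, n, block_id = 1L) {
  stopifnot(inherits(condition, "condition_spec"), n >= 1)
  nb <- condition$n_bars
  n0 <- matrix(stats::rnorm(nb * n, 0, condition$sigma_N), nb, n)
  n1 <- matrix(stats::rnorm(nb * n, 0, condition$sigma_N), nb, n)
  t1 <- if (condition$task == "mixed") {
    sgn <- ifelse(stats::runif(n) < 0.5, 1, -1)
    sgn * condition$snr_level * condition$sigma_N
  } else rep(condition$rho1, n)
  t0 <- rep(condition$rho0, n)
  side <- ifelse(stats::runif(n) < 0.5, "AB", "BA")
  new_trial_set(n0, n1, t0, t1, side, condition,
                block_id = rep(as.integer(block_id), n),
                trial_index = seq_len(n), pass_mate = rep(NA_integer_, n))
}

#' Generate a single trial
#'
#' @inheritParams make_trials
#' @return a `trial_set` with one trial.
#' @export
make_trial <- function(condition) make_trials(condition, 1L)

#' Generate one 50-trial double-pass block
#'
#' Trials 26-50 replay the stimuli of trials 1-25 in randomly permuted order;
#' `pass_mate` links each first-pass trial to its repeat (a bijection between
#' the two halves). The condition is constant within the block.
#'
#' @param condition a [condition_spec()].
#' @param block_id block label.
#' @param n_pairs number of unique stimulus pairs per block (default 25, for
#'   the standard 50-trial block).
#' @return a `trial_set` of `2 * n_pairs` trials.
#' @export
make_double_pass_block <- function(condition, block_id = 1L, n_pairs = 25L) {
  first <- make_trials(condition, n_pairs, block_id = block_id)
  perm <- sample.int(n_pairs)
  n0 <- cbind(first$n0, first$n0[, perm, drop = FALSE])
  n1 <- cbind(first$n1, first$n1[, perm, drop = FALSE])
  t0 <- c(first$t0, first$t0[perm])
  t1 <- c(first$t1, first$t1[perm])
  side <- c(first$side, ifelse(stats::runif(n_pairs) < 0.5, "AB", "BA"))
  pass_mate <- c(rep(NA_integer_, n_pairs), perm)  # repeat i' <- original perm[i']
  new_trial_set(n0, n1, t0, t1, side, condition,
                block_id = rep(as.integer(block_id), 2L * n_pairs),
                trial_index = seq_len(2L * n_pairs), pass_mate = pass_mate)
}

#' Concatenate trial sets
#'
#' @param ... `trial_set` objects with matching bar geometry.
#' @return a combined `trial_set`. `block_id` values are kept as supplied;
#'   `trial_index` is kept per block.
#' @export
bind_trials <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "trial_set"))
    sets <- sets[[1]]
  stopifnot(all(vapply(sets, inherits, logical(1), "trial_set")))
  nb <- unique(vapply(sets, function(s) s$n_bars, integer(1)))
  ct <- unique(vapply(sets, function(s) s$center, integer(1)))
  if (length(nb) != 1 || length(ct) != 1) stop("trial sets differ in bar geometry")
  out <- sets[[1]]
  for (f in c("t0", "t1", "side", "task", "contrast_level", "snr_level",
              "sigma_N", "block_id", "trial_index", "pass_mate"))
    out[[f]] <- do.call(c, lapply(sets, `[[`, f))
  out$n0 <- do.call(cbind, lapply(sets, `[[`, "n0"))
  out$n1 <- do.call(cbind, lapply(sets, `[[`, "n1"))
  out
}

#' Subset a trial set
#'
#' @param trials a `trial_set`.
#' @param idx integer or logical index over trials.
#' @return a `trial_set` restricted to `idx`.
#' @export
subset_trials <- function(trials, idx) {
  out <- trials
  out$n0 <- trials$n0[, idx, drop = FALSE]
  out$n1 <- trials$n1[, idx, drop = FALSE]
  for (f in c("t0", "t1", "side", "task", "contrast_level", "snr_level",
              "sigma_N", "block_id", "trial_index", "pass_mate"))
    out[[f]] <- trials[[f]][idx]
  out
}

#' Generate a full session over a condition grid
#'
#' One or more blocks per condition; the condition (contrast level, SNR level)
#' is fixed within a block, mirroring the random block-wise assignment of the
#' experimental protocol.
#'
#' @param conditions list of [condition_spec()] objects (e.g. the full 4x4
#'   grid of one task).
#' @param n_blocks_per_condition blocks per condition.
#' @param block_type `"standard"` (50 independent trials) or `"double_pass"`.
#' @param trials_per_block trials per standard block (default 50).
#' @return a `trial_set` containing all blocks, with unique `block_id`s.
#' @export
make_session <- function(conditions, n_blocks_per_condition = 1L,
                         block_type = c("standard", "double_pass"),
                         trials_per_block = 50L) {
  block_type <- match.arg(block_type)
  if (length(conditions) == 0) stop("'conditions' must be a non-empty list")
  if (inherits(conditions, "condition_spec")) conditions <- list(conditions)
  if (n_blocks_per_condition < 1) stop("'n_blocks_per_condition' must be >= 1")
  blocks <- list(); bid <- 0L
  for (cond in conditions) {
    for (b in seq_len(n_blocks_per_condition)) {
      bid <- bid + 1L
      blocks[[bid]] <- if (block_type == "double_pass")
        make_double_pass_block(cond, block_id = bid,
                               n_pairs = as.integer(trials_per_block / 2))
      else make_trials(cond, trials_per_block, block_id = bid)
    }
  }
  bind_trials(blocks)
}

#' The standard 4x4 condition grid of one task
#'
#' @param task task name as in [condition_spec()].
#' @return list of 16 `condition_spec` objects, contrast level varying fastest.
#' @export
condition_grid <- function(task = "bright") {
  g <- expand.grid(contrast_level = 1:4, snr_level = 1:4)
  lapply(seq_len(nrow(g)), function(i)
    condition_spec(task, g$contrast_level[i], g$snr_level[i]))
}
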