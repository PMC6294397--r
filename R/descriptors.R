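#' Classify noise samples by interval and response
#'
#' Splits the noise components of every trial into the four reverse-
#' correlation bins `n^[q,z]`: `q` indexes the interval the sample was shown
#' in (1 target, 0 non-target) and `z` the response outcome (1 correct,
#' 0 incorrect). Each trial contributes one sample to a `q = 1` bin and one
#' to a `q = 0` bin.
#'
#' @param trials a `trial_set`.
#' @param responses aligned response data frame from [respond()].
#' @return object of class `"classified_noise"`: list of the four sample
#'   matrices `n11`, `n10`, `n00`, `n01` (bars x samples), plus `m`, `pc`,
#'   `sigma_N` and the bar geometry.
#' @export
classify_noise <- function(trials, responses) {
  stopifnot(inherits(trials, "trial_set"))
  if (nrow(responses) != n_trials(trials))
    stop("responses and trials are misaligned")
  z <- responses$correct
  sig <- unique(trials$sigma_N)
  if (length(sig) != 1)
    stop("classify_noise expects trials from a single condition (one sigma_N)")
  structure(list(
    n11 = trials$n1[, z, drop = FALSE],
    n10 = trials$n1[, !z, drop = FALSE],
    n00 = trials$n0[, !z, drop = FALSE],
    n01 = trials$n0[, z, drop = FALSE],
    m = n_trials(trials), pc = mean(z), sigma_N = sig,
    n_bars = trials$n_bars, center = trials$center,
    spacing = 9), class = "classified_noise")
}

#' @export
print.classified_noise <- function(x, ...) {
  cat(sprintf("<classified_noise> m=%d pc=%.3f sigma_N=%g\n", x$m, x$pc, x$sigma_N))
  invisible(x)
}

check_bins <- function(cn, min_n = 1L) {
  for (b in c("n11", "n10", "n00", "n01"))
    if (ncol(cn[[b]]) < min_n)
      stop(sprintf("classified-noise bin '%s' has fewer than %d samples", b, min_n))
}

#' First-order classification-image descriptors
#'
#' Target-present descriptor `h1 = mean(n^[1,1]) - mean(n^[1,0])`,
#' target-absent descriptor `h0 = mean(n^[0,0]) - mean(n^[0,1])`, and the
#' full descriptor `h = h1 + h0`. Only noise samples enter; the deterministic
#' target signal never does.
#'
#' @param cn a `"classified_noise"` object.
#' @return list with vectors `h`, `h1`, `h0`.
#' @export
first_order <- function(cn) {
  stopifnot(inherits(cn, "classified_noise"))
  check_bins(cn, 1L)
  h1 <- rowMeans(cn$n11) - rowMeans(cn$n10)
  h0 <- rowMeans(cn$n00) - rowMeans(cn$n01)
  list(h = h1 + h0, h1 = h1, h0 = h0)
}

#' One-sided power spectra of noise profiles
#'
#' @param x vector or matrix (bars x samples).
#' @param spacing sample spacing in arcmin (default 9).
#' @return matrix (frequencies x samples) of one-sided DFT power, DC
#'   included, with attribute `"freq"`: the frequency axis in cycles/deg.
#' @export
power_profiles <- function(x, spacing = 9) {
  X <- if (is.null(dim(x))) matrix(x, ncol = 1) else x
  nb <- nrow(X)
  nf <- nb %/% 2 + 1
  P <- abs(stats::mvfft(X))[seq_len(nf), , drop = FALSE]^2
  attr(P, "freq") <- (seq_len(nf) - 1) / (nb * spacing / 60)
  P
}

#' First-order descriptors in the Fourier-power domain
#'
#' Applies the same difference-of-bin-means combination rule as
#' [first_order()], but to the one-sided Fourier power profile of each noise
#' sample instead of its spatial profile. Although power is non-negative, the
#' descriptor can be negative (it is a difference of average power profiles).
#'
#' @param cn a `"classified_noise"` object.
#' @return list with vectors `h`, `h1`, `h0` over spatial frequency and the
#'   frequency axis `freq` (cycles/deg).
#' @export
first_order_power <- function(cn) {
  stopifnot(inherits(cn, "classified_noise"))
  check_bins(cn, 1L)
  p <- lapply(cn[c("n11", "n10", "n00", "n01")], power_profiles, spacing = cn$spacing)
  h1 <- rowMeans(p$n11) - rowMeans(p$n10)
  h0 <- rowMeans(p$n00) - rowMeans(p$n01)
  list(h = h1 + h0, h1 = h1, h0 = h0, freq = attr(p$n11, "freq"))
}

#' Second-order classification-image descriptor
#'
#' `H = cov(n^[1,1]) + cov(n^[0,0]) - cov(n^[1,0]) - cov(n^[0,1])`: the same
#' signed combination as the first-order descriptor with the mean replaced by
#' the sample covariance matrix (n-1 denominator). `H` is symmetric by
#' construction; it is the operational estimate of the second-order Volterra
#' kernel of the perceptual process.
#'
#' @param cn a `"classified_noise"` object.
#' @return `n_bars` x `n_bars` symmetric matrix.
#' @export
second_order <- function(cn) {
  stopifnot(inherits(cn, "classified_noise"))
  check_bins(cn, 2L)
  cv <- function(M) stats::cov(t(M))
  cv(cn$n11) + cv(cn$n00) - cv(cn$n10) - cv(cn$n01)
}

#' Expected RMS of a decoupled-process descriptor
#'
#' The noise floor against which descriptor amplitude is judged. For a
#' process whose responses are statistically decoupled from the stimuli, the
#' descriptor elements are zero-mean with analytically known SD; with
#' `k = sqrt(2 / (m * pc * (1 - pc)))` the expected RMS values are
#' `k * sigma_N` for the full first-order descriptor `h`,
#' `k * sigma_N / sqrt(2)` for its target-present/absent components,
#' `sqrt(2) * k * sigma_N^2` for the diagonal of `H`, and
#' `k * sigma_N^2` for its off-diagonal region. (These follow from the
#' sampling variance of the bin means / covariances and are validated against
#' a Monte-Carlo decoupled oracle in the test suite.)
#'
#' @param order descriptor order, 1 or 2.
#' @param m total trial count.
#' @param pc fraction correct, strictly inside (0, 1).
#' @param sigma_N noise SD.
#' @param region `"full"` or `"component"` for order 1; `"diagonal"`,
#'   `"offdiagonal"` or `"full"` (off-diagonal pre-scaled by sqrt(2), see
#'   [drive_set()]) for order 2.
#' @return expected RMS (positive scalar).
#' @export
rms_star <- function(order, m, pc, sigma_N,
                     region = c("full", "component", "diagonal", "offdiagonal")) {
  region <- match.arg(region)
  if (pc <= 0 || pc >= 1) stop("'pc' must lie strictly inside (0, 1)")
  if (m <= 0) stop("'m' must be positive")
  k <- sqrt(2 / (m * pc * (1 - pc)))
  if (order == 1) {
    switch(region,
           full = k * sigma_N,
           component = k * sigma_N / sqrt(2),
           stop("regions 'diagonal'/'offdiagonal' apply to order 2"))
  } else if (order == 2) {
    switch(region,
           diagonal = sqrt(2) * k * sigma_N^2,
           offdiagonal = k * sigma_N^2,
           full = sqrt(2) * k * sigma_N^2,
           stop("region 'component' applies to order 1"))
  } else stop("'order' must be 1 or 2")
}

#' Drive: log-ratio of descriptor RMS to its decoupled expectation
#'
#' `lambda = log(RMS(region) / rms_star)`, natural log. Zero for a process
#' whose responses carry no stimulus information (up to the small-sample bias
#' of the log of a noisy RMS).
#'
#' @param x descriptor region (vector or matrix of elements).
#' @param rms_star_value the matching expected RMS from [rms_star()].
#' @return scalar drive `lambda`.
#' @export
drive <- function(x, rms_star_value) {
  if (length(x) == 0) stop("empty descriptor region")
  if (!is.finite(rms_star_value) || rms_star_value <= 0)
    stop("'rms_star_value' must be positive")
  log(sqrt(mean(x^2)) / rms_star_value)
}

#' All drives of a classified-noise session
#'
#' Computes the first- and second-order descriptors and their drives:
#' `lambda1` (full `h`), `lambda1_tp` / `lambda1_ta` (target-present/absent
#' components against the component floor), and `lambda2` for `H`. For
#' `lambda2` the off-diagonal region is multiplied by sqrt(2) before pooling
#' with the diagonal, so that both regions share the diagonal's expected RMS.
#'
#' @param cn a `"classified_noise"` object.
#' @return list with the four drives plus the descriptors (`h`, `h1`, `h0`,
#'   `H`) and `m`, `pc`, `sigma_N`.
#' @export
drive_set <- function(cn) {
  fo <- first_order(cn)
  H <- second_order(cn)
  off <- row(H) != col(H)
  Hs <- H
  Hs[off] <- H[off] * sqrt(2)
  list(lambda1 = drive(fo$h, rms_star(1, cn$m, cn$pc, cn$sigma_N, "full")),
       lambda1_tp = drive(fo$h1, rms_star(1, cn$m, cn$pc, cn$sigma_N, "component")),
       lambda1_ta = drive(fo$h0, rms_star(1, cn$m, cn$pc, cn$sigma_N, "component")),
       lambda2 = drive(Hs, rms_star(2, cn$m, cn$pc, cn$sigma_N, "full")),
       h = fo$h, h1 = fo$h1, h0 = fo$h0, H = H,
       m = cn$m, pc = cn$pc, sigma_N = cn$sigma_N)
}

#' Decouple responses from stimuli
#'
#' Returns a copy of the response data frame with the response/correct
#' columns permuted across trials: the marginal statistics of stimuli and of
#' responses are untouched, but any statistical dependence between them is
#' destroyed. This is the null model for descriptor significance.
#'
#' @param responses response data frame.
#' @return permuted response data frame (`pc` is preserved exactly).
#' @export
decouple <- function(responses) {
  if (nrow(responses) < 2) stop("need at least 2 trials to decouple")
  perm <- sample.int(nrow(responses))
  out <- responses
  out$response <- responses$response[perm]
  out$correct <- responses$correct[perm]
  out$r0 <- responses$r0[perm]
  out$r1 <- responses$r1[perm]
  out
}

#' Eigen-decomposition of a second-order descriptor with a decoupled null
#'
#' Symmetric eigen-decomposition of `H`; significance of each eigenvalue is
#' judged against the pooled spread of eigenvalues obtained from
#' decoupled-process surrogates (responses randomly reassigned to trials,
#' descriptor recomputed). Eigenvalues outside `threshold_multiplier` null
#' SDs are counted as significant (positive / negative separately).
#'
#' @param H symmetric descriptor matrix.
#' @param trials,responses the session that produced `H` (used to build the
#'   decoupled surrogates). If omitted, no null band is computed.
#' @param n_shuffles number of decoupled surrogates (default 100; fewer than
#'   10 triggers a warning).
#' @param threshold_multiplier null-band half-width in null SDs (default 3).
#' @return object of class `"eigen_decomposition"`: `values` (sorted
#'   decreasing), `vectors` (columns, orthonormal), `null_sd`,
#'   `significant_pos`, `significant_neg`, `significant` (logical per
#'   eigenvalue).
#' @export
eigendecompose <- function(H, trials = NULL, responses = NULL,
                           n_shuffles = 100L, threshold_multiplier = 3) {
  if (!isSymmetric(unname(H), tol = 1e-8)) stop("'H' must be symmetric")
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  null_sd <- NA_real_
  if (!is.null(trials) && !is.null(responses)) {
    if (n_shuffles < 10) warning("fewer than 10 decoupled shuffles: null band unstable")
    null_vals <- unlist(lapply(seq_len(n_shuffles), function(i) {
      cn0 <- classify_noise(trials, decouple(responses))
      eigen(second_order(cn0), symmetric = TRUE, only.values = TRUE)$values
    }))
    null_sd <- stats::sd(null_vals)
  }
  sig <- if (is.na(null_sd)) rep(NA, length(e$values))
         else abs(e$values) > threshold_multiplier * null_sd
  structure(list(values = e$values, vectors = e$vectors, null_sd = null_sd,
                 significant = sig,
                 significant_pos = sum(sig & e$values > 0, na.rm = TRUE),
                 significant_neg = sum(sig & e$values < 0, na.rm = TRUE),
                 threshold_multiplier = threshold_multiplier),
            class = "eigen_decomposition")
}

#' @export
print.eigen_decomposition <- function(x, ...) {
  cat(sprintf("<eigen_decomposition> %d eigenvalues, null_sd=%s, N+=%d N-=%d\n",
              length(x$values),
              if (is.na(x$null_sd)) "NA" else sprintf("%.4g", x$null_sd),
              x$significant_pos, x$significant_neg))
  invisible(x)
}
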