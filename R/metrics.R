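#' Sharpness (spectral centroid) of a spatial profile
#'
#' Computes the one-sided power spectrum `p` of the profile over the
#' frequency axis `x` (cycles/deg, from the bar spacing), normalises `p` to
#' unit sum and returns the centroid `<p, x>`. Higher values indicate more
#' bandpass (finely tuned, Mexican-hat-like) profiles; a constant profile has
#' all power at DC and sharpness 0.
#'
#' @param profile numeric vector (e.g. a first-order descriptor or an
#'   eigenvector).
#' @param spacing sample spacing in arcmin (default 9).
#' @return spectral centroid in cycles/deg.
#' @export
sharpness <- function(profile, spacing = 9) {
  if (all(profile == 0)) stop("sharpness is undefined for an all-zero profile")
  P <- power_profiles(profile, spacing)
  x <- attr(P, "freq")
  p <- P[, 1] / sum(P[, 1])
  sum(p * x)
}

#' Aggregate nonlinearity / linearity index from drives
#'
#' Combines two markers of departure from the linear template matcher.
#' Marker 1 is the target-present minus target-absent drive difference
#' `lambda1_tp - lambda1_ta` (zero in expectation for a linear template,
#' positive for nonlinear processing). Marker 2 contrasts second- against
#' first-order structure, `(lambda2 - lambda1) * sign(lambda2)`: the
#' rectification by `sign(lambda2)` keeps the marker centred on zero for a
#' linear system, whose `lambda2` is expected to be 0 (with `sign(0) = 0`, a
#' perfectly linear system scores exactly 0).
#'
#' When an uncertainty for `lambda2` is supplied (`lambda2_null_sd`), the
#' sign is set to 0 whenever `|lambda2|` falls within
#' `null_multiplier * lambda2_null_sd` — the same decoupled-null band logic
#' used for eigenvalue significance — so that second-order structure only
#' contributes when statistically reliable.
#'
#' @param lambda1_tp,lambda1_ta,lambda1,lambda2 drives from [drive_set()].
#' @param lambda2_null_sd optional null/standard error for `lambda2`
#'   (default 0: paper-exact sign).
#' @param null_multiplier half-width of the sign gate in null SDs (default 3).
#' @param sign_lambda2 optional externally supplied rectifying sign (-1, 0 or
#'   1), e.g. estimated from the aggregate second-order drive of a whole
#'   session grid; overrides the per-value sign.
#' @return list with `marker1`, `marker2`, `nonlinearity` (their sum; more
#'   positive = more nonlinear) and `linearity` (sign-inverted aggregate).
#' @export
nonlinearity_index <- function(lambda1_tp, lambda1_ta, lambda1, lambda2,
                               lambda2_null_sd = 0, null_multiplier = 3,
                               sign_lambda2 = NULL) {
  stopifnot(is.finite(lambda1_tp), is.finite(lambda1_ta),
            is.finite(lambda1), is.finite(lambda2))
  marker1 <- lambda1_tp - lambda1_ta
  if (is.null(sign_lambda2)) {
    s <- sign(lambda2)
    if (abs(lambda2) <= null_multiplier * lambda2_null_sd) s <- 0
  } else s <- sign_lambda2
  marker2 <- (lambda2 - lambda1) * s
  agg <- marker1 + marker2
  list(marker1 = marker1, marker2 = marker2,
       nonlinearity = agg, linearity = -agg)
}

#' Contrast / SNR dependence of a metric
#'
#' Pearson correlation between metric values and the corresponding condition
#' level indices (1..4). Because the contrast multipliers 1, 2, 4, 8 are
#' log-spaced, correlating against the level index is identical to
#' correlating against log2 multiplier (affine invariance); set
#' `raw_levels = TRUE` to correlate against the raw multipliers instead.
#'
#' @param values metric values (a `metric_surface`, or a numeric vector).
#' @param axis `"contrast"` or `"snr"` (used when `values` is a surface).
#' @param levels level indices aligned with `values` (when a plain vector).
#' @param raw_levels correlate against raw contrast multipliers {1,2,4,8}.
#' @return Pearson correlation coefficient; `NA` (with a warning) when the
#'   metric is constant.
#' @export
dependence <- function(values, axis = c("contrast", "snr"), levels = NULL,
                       raw_levels = FALSE) {
  axis <- match.arg(axis)
  if (inherits(values, "metric_surface")) {
    v <- as.vector(values$values)
    lv <- if (axis == "snr") as.vector(row(values$values))
          else as.vector(col(values$values))
  } else {
    v <- as.numeric(values)
    if (is.null(levels)) stop("'levels' required for plain value vectors")
    lv <- levels
  }
  if (raw_levels && axis == "contrast") lv <- contrast_multiplier(lv)
  ok <- is.finite(v)
  if (sum(ok) < 3) stop("need at least 3 finite paired values")
  if (stats::sd(v[ok]) == 0) {
    warning("metric is constant; dependence undefined")
    return(NA_real_)
  }
  stats::cor(v[ok], lv[ok])
}

#' A 4x4 metric surface over the condition grid
#'
#' @param values 4x4 matrix, rows = SNR levels, columns = contrast levels.
#' @param metric_name label.
#' @return object of class `"metric_surface"`.
#' @export
metric_surface <- function(values, metric_name = "metric") {
  stopifnot(is.matrix(values), nrow(values) == 4, ncol(values) == 4)
  structure(list(values = values, metric_name = metric_name),
            class = "metric_surface")
}

#' Separable prediction of a metric surface
#'
#' Normalised outer product of the marginals:
#' `S*_ij = rowsum_i * colsum_j / grandsum`. If `S` is separable
#' (`S = x %o% y`), then `S* = S` exactly; the residual `S - S*` quantifies
#' inseparability.
#'
#' @param S a `metric_surface` or plain matrix.
#' @return matrix `S*` with the same marginals as `S`.
#' @export
separability_prediction <- function(S) {
  M <- if (inherits(S, "metric_surface")) S$values else S
  g <- sum(M)
  if (g == 0) stop("grand sum of the surface is zero")
  outer(rowSums(M), colSums(M)) / g
}

#' SVD separability index
#'
#' `v1^2 / sum(v_i^2)` over the singular values of the surface: 1 for an
#' exactly separable (rank-1) surface, down to `1/min(dim)` when all singular
#' values are equal. Invariant to overall scaling.
#'
#' @param S a `metric_surface` or plain matrix.
#' @return scalar in (0, 1].
#' @export
svd_index <- function(S) {
  M <- if (inherits(S, "metric_surface")) S$values else S
  if (all(M == 0)) stop("SVD index is undefined for an all-zero surface")
  v <- svd(M)$d
  v[1]^2 / sum(v^2)
}

#' Convert 2AFC proportion correct to d'
#'
#' Standard difference-rule mapping `d' = sqrt(2) * qnorm(pc)`. When the
#' trial count `m` is supplied, `pc` is clipped to
#' `[1/(2m), 1 - 1/(2m)]` to keep the estimate finite at perfect scores.
#'
#' @param pc proportion correct.
#' @param m optional trial count used for clipping.
#' @return d' (same length as `pc`).
#' @export
dprime_from_pc <- function(pc, m = NULL) {
  if (!is.null(m)) pc <- pmin(pmax(pc, 1 / (2 * m)), 1 - 1 / (2 * m))
  if (any(pc <= 0 | pc >= 1)) stop("'pc' must lie strictly inside (0, 1); supply 'm' to clip")
  sqrt(2) * stats::qnorm(pc)
}

#' Absolute efficiency relative to the ideal observer
#'
#' The squared ratio of measured to ideal d'. For the bar-detection tasks
#' the ideal d' equals the stimulus SNR, so `efficiency = (d / snr)^2`.
#'
#' @param d_measured measured d'.
#' @param snr stimulus SNR (ideal d').
#' @return efficiency in [0, Inf); 1 for ideal performance.
#' @export
efficiency <- function(d_measured, snr) {
  if (any(snr <= 0)) stop("'snr' must be positive")
  (d_measured / snr)^2
}

#' Nonparametric trend tests
#'
#' Thin wrappers around the two tests used for group-level inference:
#' a two-tailed Wilcoxon signed-rank test for paired comparisons (or one
#' sample against 0) and a Friedman test for trends across repeated ordinal
#' levels.
#'
#' @param x numeric vector (first sample, or differences when `y` omitted).
#' @param y optional second paired sample.
#' @return p-value of the two-tailed Wilcoxon signed-rank test.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  if (length(x) < 1) stop("insufficient data")
  d <- if (is.null(y)) x else x - y
  if (all(d == 0)) return(1)  # no departures at all: no evidence of an effect
  if (is.null(y)) stats::wilcox.test(x, exact = FALSE)$p.value
  else stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)$p.value
}

#' @rdname wilcoxon_signed_rank
#' @param m matrix of measurements: rows = subjects/replicates, columns =
#'   ordinal levels (e.g. the 4 contrast levels).
#' @return p-value of the Friedman test.
#' @export
friedman_trend <- function(m) {
  if (!is.matrix(m) || nrow(m) < 2 || ncol(m) < 2)
    stop("'m' must be a matrix with >= 2 rows and >= 2 columns")
  stats::friedman.test(m)$p.value
}
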