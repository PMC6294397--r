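#' Summarise a double-pass session
#'
#' Computes the two statistics that constrain the internal-noise model:
#' `pc`, the overall fraction of correct responses, and `pa`, the fraction of
#' pass-mated stimulus pairs on which the observer gave the same response
#' (same chosen stimulus identity, not screen side).
#'
#' @param responses response data frame from [respond()] (aligned with
#'   `trials`).
#' @param trials a `trial_set` containing double-pass blocks (`pass_mate`
#'   links).
#' @return object of class `"double_pass_summary"`: list with `pc`, `pa`,
#'   `m` (trial count), `n_pairs`.
#' @export
summarize_double_pass <- function(responses, trials) {
  stopifnot(inherits(trials, "trial_set"))
  if (nrow(responses) != n_trials(trials))
    stop("responses and trials are misaligned")
  pc <- mean(responses$correct)
  agree <- integer(0)
  for (b in unique(trials$block_id)) {
    in_b <- which(trials$block_id == b)
    mates <- trials$pass_mate[in_b]
    second <- in_b[!is.na(mates)]
    if (length(second) == 0) next
    first <- in_b[match(mates[!is.na(mates)], trials$trial_index[in_b])]
    agree <- c(agree, responses$response[second] == responses$response[first])
  }
  if (length(agree) == 0) stop("no pass-mated pairs in 'trials'")
  structure(list(pc = pc, pa = mean(agree), m = n_trials(trials),
                 n_pairs = length(agree)),
            class = "double_pass_summary")
}

#' @export
print.double_pass_summary <- function(x, ...) {
  cat(sprintf("<double_pass_summary> pc=%.3f pa=%.3f (m=%d, %d pairs)\n",
              x$pc, x$pa, x$m, x$n_pairs))
  invisible(x)
}

gauss_hermite_cache <- new.env(parent = emptyenv())

gh_nodes <- function(n = 64L) {
  key <- as.character(n)
  if (is.null(gauss_hermite_cache[[key]]))
    gauss_hermite_cache[[key]] <- pracma::gaussHermite(n)
  gauss_hermite_cache[[key]]
}

#' Forward map of the two-parameter SDT internal-noise model
#'
#' The decision variable is `d_ext + e_int` with `d_ext ~ N(dprime_in, 1)`
#' (fixed across a repeated pass) and `e_int ~ N(0, N_int)` (fresh every
#' presentation); the binary response is its sign. Then
#' `pc = Phi(dprime_in / sqrt(1 + N_int^2))` and
#' `pa = E[ Phi(d/N_int)^2 + (1 - Phi(d/N_int))^2 ]` over `d ~ N(dprime_in,
#' 1)`, evaluated by Gauss-Hermite quadrature. `N_int = 0` is the
#' deterministic limit (`pa = 1`).
#'
#' @param dprime_in mean of the stimulus-driven decision variable, >= 0.
#' @param n_int internal-noise SD in external-noise units, >= 0.
#' @param nodes number of Gauss-Hermite nodes (default 64).
#' @return named vector `c(pc = ..., pa = ...)`.
#' @export
sdt_forward <- function(dprime_in, n_int, nodes = 64L) {
  if (dprime_in < 0 || n_int < 0) stop("'dprime_in' and 'n_int' must be >= 0")
  pc <- stats::pnorm(dprime_in / sqrt(1 + n_int^2))
  if (n_int == 0) return(c(pc = pc, pa = 1))
  gh <- gh_nodes(nodes)
  d <- dprime_in + sqrt(2) * gh$x
  p <- stats::pnorm(d / n_int)
  pa <- sum(gh$w * (p^2 + (1 - p)^2)) / sqrt(pi)
  c(pc = pc, pa = pa)
}

# Vectorised forward map over parameter grids (same quadrature).
sdt_forward_grid <- function(dprime_in, n_int, nodes = 64L) {
  gh <- gh_nodes(nodes)
  pc <- stats::pnorm(dprime_in / sqrt(1 + n_int^2))
  D <- outer(dprime_in, sqrt(2) * gh$x, "+")        # params x nodes
  P <- stats::pnorm(D / n_int)
  pa <- drop((P^2 + (1 - P)^2) %*% gh$w) / sqrt(pi)
  pa[n_int == 0] <- 1
  cbind(pc = pc, pa = pa)
}

#' Estimate internal noise from double-pass consistency
#'
#' Fits the two-parameter SDT model by minimising the summed squared error
#' between measured and model `{pc, pa}`: a coarse log-spaced grid search
#' (81 x 81 over `n_int` in `[0.01, 100]`, `dprime_in` in `[0, 10]`) followed
#' by Nelder-Mead refinement.
#'
#' @param summary a `"double_pass_summary"`, or a numeric `pc` if `pa` given.
#' @param pa agreement fraction (when `summary` is numeric `pc`).
#' @return object of class `"internal_noise_estimate"`: list with
#'   `dprime_in`, `n_int`, `fit_mse`, `plausible` (1/5 < N_int < 5), and the
#'   input `pc`, `pa`.
#' @export
estimate_internal_noise <- function(summary, pa = NULL) {
  if (inherits(summary, "double_pass_summary")) {
    pc <- summary$pc; pa_obs <- summary$pa
  } else {
    pc <- summary; pa_obs <- pa
  }
  if (is.null(pa_obs)) stop("'pa' is required")
  if (pc <= 0 || pc >= 1) stop("'pc' must lie strictly between 0 and 1")
  grid_d <- seq(0, 10, length.out = 81)
  grid_n <- exp(seq(log(0.01), log(100), length.out = 81))
  fwd <- lapply(grid_n, function(nn) sdt_forward_grid(grid_d, nn))
  obj_grid <- vapply(seq_along(grid_n), function(j) {
    f <- fwd[[j]]
    (f[, "pc"] - pc)^2 + (f[, "pa"] - pa_obs)^2
  }, numeric(length(grid_d)))
  best <- arrayInd(which.min(obj_grid), dim(obj_grid))
  start <- c(grid_d[best[1]], log(grid_n[best[2]]))
  obj <- function(par) {
    d <- par[1]; nn <- exp(par[2])
    if (d < 0 || d > 20) return(1e6)
    f <- sdt_forward(d, nn)
    (f["pc"] - pc)^2 + (f["pa"] - pa_obs)^2
  }
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  n_int <- exp(fit$par[2])
  structure(list(dprime_in = fit$par[1], n_int = n_int, fit_mse = fit$value,
                 plausible = n_int > 1 / 5 && n_int < 5,
                 pc = pc, pa = pa_obs),
            class = "internal_noise_estimate")
}

#' @export
print.internal_noise_estimate <- function(x, ...) {
  cat(sprintf("<internal_noise_estimate> dprime_in=%.3f N_int=%.3f (mse=%.2e, plausible=%s)\n",
              x$dprime_in, x$n_int, x$fit_mse, x$plausible))
  invisible(x)
}

#' Simulate an abstract SDT double-pass observer
#'
#' Draws `n_pairs` values of `d_ext ~ N(dprime_in, 1)` and, for each of the
#' two passes, a fresh `e_int ~ N(0, n_int)`; responses are the signs. Used
#' as a Monte-Carlo oracle for [sdt_forward()] and for parameter-recovery
#' studies.
#'
#' @param dprime_in,n_int model parameters.
#' @param n_pairs number of repeated stimulus pairs.
#' @return list with `pc`, `pa` (and `n_pairs`).
#' @export
simulate_sdt_observer <- function(dprime_in, n_int, n_pairs) {
  d <- stats::rnorm(n_pairs, dprime_in, 1)
  r1 <- d + stats::rnorm(n_pairs, 0, n_int) > 0
  r2 <- d + stats::rnorm(n_pairs, 0, n_int) > 0
  list(pc = mean(c(r1, r2)), pa = mean(r1 == r2), n_pairs = n_pairs)
}
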