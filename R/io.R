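#' Write a trial log to CSV
#'
#' One row per trial with the noise vectors in full and the signal as its
#' scalar centre offset. Numeric values are written with 17 significant
#' digits so that the log round-trips bit-exactly through [read_trial_log()].
#'
#' @param trials a `trial_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  stopifnot(inherits(trials, "trial_set"))
  nb <- trials$n_bars
  num <- function(x) sprintf("%.17g", x)
  df <- data.frame(block_id = trials$block_id, trial_index = trials$trial_index,
                   task = trials$task, contrast_level = trials$contrast_level,
                   snr_level = trials$snr_level,
                   pass_mate = trials$pass_mate, side = trials$side,
                   stringsAsFactors = FALSE)
  n0 <- t(trials$n0); colnames(n0) <- paste0("n0_", seq_len(nb))
  n1 <- t(trials$n1); colnames(n1) <- paste0("n1_", seq_len(nb))
  df <- cbind(df, as.data.frame(apply(n0, 2, num)), t0_center = num(trials$t0),
              as.data.frame(apply(n1, 2, num)), t1_center = num(trials$t1))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial log written by [write_trial_log()]
#'
#' @param path CSV path.
#' @return a `trial_set`.
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nb <- sum(grepl("^n0_", names(df)))
  cond <- condition_spec(df$task[1], df$contrast_level[1], df$snr_level[1],
                         n_bars = nb)
  out <- new_trial_set(
    n0 = t(as.matrix(df[paste0("n0_", seq_len(nb))])),
    n1 = t(as.matrix(df[paste0("n1_", seq_len(nb))])),
    t0 = as.numeric(df$t0_center), t1 = as.numeric(df$t1_center),
    side = df$side, condition = cond,
    block_id = df$block_id, trial_index = df$trial_index,
    pass_mate = df$pass_mate)
  # restore per-trial condition labels (sessions may span conditions)
  out$task <- df$task
  out$contrast_level <- df$contrast_level
  out$snr_level <- df$snr_level
  out$sigma_N <- contrast_multiplier(df$contrast_level)
  dimnames(out$n0) <- dimnames(out$n1) <- NULL
  out
}

#' Write / read observer configuration as JSON
#'
#' @param config an [observer_config()].
#' @param path JSON path.
#' @return `path` invisibly (write); an `observer_config` (read).
#' @export
write_observer_config <- function(config, path) {
  stopifnot(inherits(config, "observer_config"))
  x <- unclass(config)
  x$dog <- unclass(x$dog)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_observer_config
#' @export
read_observer_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  observer_config(variant = x$variant,
                  dog = do.call(dog_spec, as.list(x$dog)),
                  sigma_w = x$sigma_w, noise_sd = x$noise_sd,
                  noise_location = x$noise_location,
                  noise_scaling = x$noise_scaling,
                  max_sigma_w = unlist(x$max_sigma_w),
                  input_gain = x$input_gain)
}

#' Write per-condition double-pass results as JSON
#'
#' @param grid a `"grid_result"` from [run_grid()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_grid_json <- function(grid, path) {
  stopifnot(inherits(grid, "grid_result"))
  jsonlite::write_json(list(per_condition = grid$per_condition,
                            dependence = grid$dependence,
                            separability = grid$separability),
                       path, dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
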