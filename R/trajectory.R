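#' Replay observed choices through a learning model
#'
#' Runs a model variant over an observed (or simulated) sequence of response
#' times and rewards, returning the latent decision signals per trial. All
#' signals except the reward prediction error reflect the state entering the
#' trial (the representation available at decision onset): entropy, the
#' location and height of the global value maximum, the chosen action's value
#' and (for the Kalman variant) uncertainty. The RPE is the obtained reward
#' minus the pre-update value at the chosen RT, aligned with feedback.
#' Learning state is reset at the start of every run.
#'
#' @param trials data.frame with columns \code{run}, \code{trial},
#'   \code{rt_ms}, \code{reward}, sorted by run then trial (a single
#'   subject's data).
#' @param basis a \code{\link{build_basis}} object.
#' @param params named list/vector of parameters: \code{alpha} (all
#'   variants), \code{gamma} (selective), \code{beta} (kept for reference),
#'   \code{tau} and \code{sigma_rew} (fixed_uv).
#' @param variant \code{"selective"}, \code{"full"}, \code{"fixed_uv"}, or
#'   \code{"rw"} (trial-level delta rule; value is scalar so entropy and
#'   RT_Vmax are undefined and returned as NA).
#' @return the input table with appended columns \code{rpe}, \code{entropy},
#'   \code{rt_vmax} (ms), \code{v_max}, \code{v_chosen}, and for
#'   \code{fixed_uv} also \code{u_chosen}, \code{u_percentile}.
#' @export
sceptic_trajectory <- function(trials, basis,
                               params,
                               variant = c("selective", "full", "fixed_uv",
                                           "rw")) {
  variant <- match.arg(variant)
  stopifnot(all(c("run", "trial", "rt_ms", "reward") %in% names(trials)))
  ord <- order(trials$run, trials$trial)
  if (any(ord != seq_len(nrow(trials))))
    stop("trials must be sorted by run, then trial")
  params <- as.list(params)
  bins <- rt_to_bin(trials$rt_ms, basis)
  run_start <- c(TRUE, trials$run[-1] != trials$run[-nrow(trials)])
  if (variant == "rw") {
    V <- 0
    rpe <- numeric(nrow(trials))
    for (i in seq_len(nrow(trials))) {
      if (run_start[i]) V <- 0
      rpe[i] <- trials$reward[i] - V
      V <- V + params$alpha * (trials$reward[i] - V)
    }
    trials$rpe <- rpe
    trials$entropy <- NA_real_
    trials$rt_vmax <- NA_real_
    trials$v_max <- NA_real_
    trials$v_chosen <- NA_real_
    return(trials)
  }
  E <- eligibility_matrix(basis)
  if (variant == "fixed_uv") {
    if (is.null(params$sigma_rew))
      params$sigma_rew <- reference_reward_sd(trials)
    tr <- cpp_kf_traj(bins, trials$reward, run_start, basis$phi, E,
                      params$alpha, params$tau %||% 0, params$sigma_rew)
  } else {
    tr <- cpp_sceptic_traj(bins, trials$reward, run_start, basis$phi, E,
                           params$alpha,
                           if (variant == "selective") params$gamma else 0,
                           if (variant == "selective") 1L else 2L)
  }
  trials$rpe <- tr$rpe
  trials$entropy <- tr$entropy
  trials$rt_vmax <- basis$grid[tr$v_max_bin]
  trials$v_max <- tr$v_max
  trials$v_chosen <- tr$v_chosen
  if (variant == "fixed_uv") {
    trials$u_chosen <- tr$u_chosen
    trials$u_percentile <- tr$u_percentile
  }
  trials
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write trial tables as delimited text
#'
#' Tab-separated tables with one row per trial; the minimal column set is
#' \code{subject, run, trial, contingency, rt_ms, rewarded, reward}.
#'
#' @param path file path.
#' @param trials data.frame to write.
#' @return \code{read_trials} returns a data.frame.
#' @export
read_trials <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
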