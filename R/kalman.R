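#' Initialize the Kalman-filter (fixed U+V) agent state
#'
#' The uncertainty-tracking variant keeps, for every basis element, a
#' posterior mean (expected value, updated with a fixed learning rate) and a
#' posterior standard deviation. Prior uncertainties are initialized equal to
#' the measurement noise, \eqn{\sigma_{b0}^2 = \sigma_{rew}^2}, which makes
#' the first-trial gain exactly 0.5.
#'
#' @param basis a \code{\link{build_basis}} object.
#' @param alpha fixed learning rate for the means, in (0, 1].
#' @param beta softmax temperature > 0.
#' @param tau uncertainty weight: positive values seek uncertain response
#'   times, negative values avoid them.
#' @param sigma_rew measurement noise scale (SD of returns, points); the
#'   conventional choice is the empirical SD of rewards in a typical run, see
#'   \code{\link{reference_reward_sd}}.
#' @return object of class \code{"kf_state"}.
#' @export
kf_init <- function(basis, alpha, beta = 20, tau = 0, sigma_rew) {
  if (sigma_rew <= 0) stop("sigma_rew must be positive")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (beta <= 0) stop("beta must be positive")
  structure(list(means = numeric(basis$n_basis),
                 sigmas = rep(sigma_rew, basis$n_basis),
                 sigma_rew = sigma_rew, alpha = alpha, beta = beta,
                 tau = tau, trial = 1L),
            class = "kf_state")
}

#' One Kalman-filter learning step
#'
#' Means move toward the reward with step size \code{alpha * e_b}; gains are
#' \deqn{k_b = \sigma_b^2 / (\sigma_b^2 + \sigma_{rew}^2)}
#' and posterior uncertainties shrink as
#' \deqn{\sigma_b \leftarrow (1 - e_b k_b)\, \sigma_b,}
#' so uncertainty decays only where the eligibility is appreciable: sampling a
#' response time sharpens knowledge locally while remote times stay uncertain.
#'
#' @param state a \code{\link{kf_init}} object.
#' @param basis the matching basis.
#' @param rt_ms chosen response time, ms.
#' @param reward obtained points.
#' @return updated state; attributes \code{"rpe"} (reward minus pre-update
#'   mean value at the chosen RT) and \code{"gain"} (per-element gains).
#' @export
kf_step <- function(state, basis, rt_ms, reward) {
  stopifnot(inherits(state, "kf_state"))
  e <- eligibility(basis, rt_ms)
  rpe <- reward - value_at(state$means, basis, rt_ms)
  gain <- state$sigmas^2 / (state$sigmas^2 + state$sigma_rew^2)
  state$means <- state$means + e * state$alpha * (reward - state$means)
  state$sigmas <- (1 - e * gain) * state$sigmas
  state$trial <- state$trial + 1L
  attr(state, "rpe") <- rpe
  attr(state, "gain") <- gain
  state
}

#' Uncertainty-weighted decision function
#'
#' Projects means and uncertainties through the basis, \eqn{V = \mu\phi} and
#' \eqn{U = \sigma\phi}, and combines them as \eqn{Q = V + \tau U}. With
#' \eqn{\tau = 0} the decision function is the value function itself.
#'
#' @param state a \code{\link{kf_init}} object.
#' @param basis the matching basis.
#' @return list with \code{grid}, \code{values} (Q, used for choice),
#'   \code{v} and \code{u} components; class \code{"value_function"} so
#'   \code{\link{rt_vmax}} and \code{\link{choose_rt}} apply.
#' @export
decision_q <- function(state, basis) {
  v <- drop(crossprod(state$means, basis$phi))
  u <- drop(crossprod(state$sigmas, basis$phi))
  structure(list(grid = basis$grid, values = v + state$tau * u,
                 v = v, u = u),
            class = "value_function")
}

#' Percentile of the chosen action's uncertainty
#'
#' Rank of \eqn{U(rt)} among the uncertainties of all grid responses on the
#' same trial (midrank for ties), scaled to 0-100. Normalizing within trial
#' removes the global exponential decay of uncertainty across learning and
#' isolates which part of the interval is relatively unexplored. Values
#' within 0.1% of the trial maximum count as tied, so the tiny interior
#' ripple of the basis envelope does not break ties arbitrarily; note that
#' the evaluated uncertainty function genuinely dips near the interval edges
#' (fewer overlapping elements), so even an unsampled agent ranks edge bins
#' below interior ones.
#'
#' @inheritParams decision_q
#' @param rt_ms chosen response time.
#' @return percentile in [0, 100].
#' @export
uncertainty_percentile <- function(state, basis, rt_ms) {
  if (rt_ms < 0 || rt_ms > basis$interval_ms)
    stop("rt_ms outside the decision interval")
  u <- drop(crossprod(state$sigmas, basis$phi))
  bin <- rt_to_bin(rt_ms, basis)
  tol <- 1e-3 * max(abs(u))
  below <- sum(u < u[bin] - tol)
  ties <- sum(abs(u - u[bin]) <= tol)
  100 * (below + (ties + 1) / 2 - 0.5) / length(u)
}

#' Reference reward SD for sigma_rew initialization
#'
#' Empirical SD of rewards from a reference run: either pooled over the runs
#' of a trial table, or simulated from a contingency under uniform responding.
#'
#' @param trials optional trial table with a \code{reward} column.
#' @param contingency optional \code{\link{make_contingency}} object used when
#'   no data are given; 1000 uniform-RT outcomes are drawn.
#' @param n_sim simulated draws in the no-data case.
#' @return scalar SD in points.
#' @export
reference_reward_sd <- function(trials = NULL, contingency = NULL,
                                n_sim = 1000) {
  if (!is.null(trials)) return(stats::sd(trials$reward))
  stopifnot(!is.null(contingency))
  rts <- stats::runif(n_sim, 0, contingency$interval_ms * 0.999)
  pr <- contingency$prob_fn(rts)
  mg <- contingency$mag_fn(rts)
  stats::sd(ifelse(stats::runif(n_sim) < pr, mg, 0))
}
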