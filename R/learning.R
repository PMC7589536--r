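#' Initialize an agent state
#'
#' @param basis a \code{\link{build_basis}} object.
#' @param variant \code{"selective"} (unchosen elements decay toward
#'   \code{h}) or \code{"full"} (no decay).
#' @param alpha learning rate in (0, 1).
#' @param gamma selective-maintenance decay rate in [0, 1); ignored by the
#'   full variant.
#' @param beta softmax temperature > 0.
#' @param h reversion point for decay (default 0).
#' @return object of class \code{"agent_state"} with zero-initialized weights.
#' @export
agent_init <- function(basis, variant = c("selective", "full"),
                       alpha, gamma = 0, beta = 20, h = 0) {
  variant <- match.arg(variant)
  check_rates(alpha, gamma, beta)
  structure(list(weights = numeric(basis$n_basis), trial = 1L,
                 variant = variant, alpha = alpha, gamma = gamma,
                 beta = beta, h = h),
            class = "agent_state")
}

check_rates <- function(alpha, gamma, beta) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)")
  if (beta <= 0) stop("beta must be positive")
  invisible(TRUE)
}

#' Delta-rule update of the basis weights
#'
#' Each element moves toward the obtained reward in proportion to the learning
#' rate and its eligibility:
#' \deqn{w_b \leftarrow w_b + e_b \alpha (reward - w_b)}
#' and, under selective maintenance, elements shielded from the update decay
#' toward the reversion point \eqn{h}:
#' \deqn{ - \gamma (1 - e_b)(w_b - h).}
#' With \eqn{\gamma = 0} the two variants coincide. The reward prediction
#' error at the chosen RT, \code{reward - V(rt)} with \code{V} evaluated
#' before the update, is attached as attribute \code{"rpe"}.
#'
#' @param state an \code{\link{agent_init}} object.
#' @param basis the matching basis.
#' @param rt_ms chosen response time in ms.
#' @param reward obtained points.
#' @return updated \code{agent_state}; attributes \code{"rpe"} and
#'   \code{"elig"} expose the scalar prediction error and eligibility vector.
#' @export
update_weights <- function(state, basis, rt_ms, reward) {
  stopifnot(inherits(state, "agent_state"))
  e <- eligibility(basis, rt_ms)
  v_rt <- value_at(state$weights, basis, rt_ms)
  rpe <- reward - v_rt
  w <- state$weights + e * state$alpha * (reward - state$weights)
  if (state$variant == "selective")
    w <- w - state$gamma * (1 - e) * (state$weights - state$h)
  state$weights <- w
  state$trial <- state$trial + 1L
  attr(state, "rpe") <- rpe
  attr(state, "elig") <- e
  state
}

# model-predicted value at an arbitrary rt (nearest grid bin center)
value_at <- function(weights, basis, rt_ms) {
  bin <- rt_to_bin(rt_ms, basis)
  sum(weights * basis$phi[, bin])
}

#' Map a response time to its choice-grid bin
#' @param rt_ms time in ms.
#' @param basis a \code{\link{build_basis}} object.
#' @return 1-based bin index.
#' @export
rt_to_bin <- function(rt_ms, basis) {
  bin <- floor(rt_ms / basis$bin_ms) + 1L
  pmin(pmax(bin, 1L), basis$n_grid)
}

#' Shannon entropy of the normalized weight vector
#'
#' \eqn{H = -\sum_b p_b \log p_b} with \eqn{p_b = w_b / \sum w_b}, in nats: a
#' log measure of the number of advantageous actions. Zero-weight elements
#' contribute nothing. When the total weight is (numerically) zero — e.g.
#' before any reward — all actions are equally plausible and the maximum
#' \eqn{\log n} is returned.
#'
#' @param weights nonnegative weight vector.
#' @param eps total-weight threshold below which the uniform convention
#'   applies.
#' @return entropy in nats, in [0, log(length(weights))].
#' @export
shannon_entropy <- function(weights, eps = 1e-12) {
  if (any(weights < 0)) stop("weights must be nonnegative")
  tot <- sum(weights)
  if (tot < eps) return(log(length(weights)))
  p <- weights / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Trial-level delta-rule value update
#'
#' The spatially unstructured alternative learner: a single expected value for
#' responding at all, updated by \eqn{V \leftarrow V + \alpha(reward - V)}.
#'
#' @param V current scalar value.
#' @param reward obtained points.
#' @param alpha learning rate in (0, 1].
#' @return updated value with attribute \code{"rpe"} = \code{reward - V}.
#' @export
rw_trial_update <- function(V, reward, alpha) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  out <- V + alpha * (reward - V)
  attr(out, "rpe") <- reward - V
  out
}
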