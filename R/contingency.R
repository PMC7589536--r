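#' Clock-task reward contingencies
#'
#' The clock task pays out probabilistic rewards as a function of the chosen
#' response time (RT) within a 4-s decision interval. Four monotone
#' contingencies are available: increasing expected value (\code{"IEV"}),
#' decreasing expected value (\code{"DEV"}), constant expected value
#' (\code{"CEV"}), and constant expected value with the probability/magnitude
#' tradeoff reversed (\code{"CEVR"}). In every contingency the reward
#' probability and magnitude vary monotonically in opposite directions, so
#' that learning the expected-value profile requires integrating both.
#'
#' The exact curve shapes are parameterized rather than fixed: probability is
#' linear in time between \code{p_start} and \code{p_end}, the expected value
#' is linear between \code{ev_start} and \code{ev_end}, and the magnitude is
#' defined implicitly as EV/probability (which keeps it monotone whenever the
#' probability and EV trends oppose or one is flat). Defaults give EV ranges
#' and tradeoffs qualitatively matching the task: IEV pays rarely-but-big late,
#' DEV pays big early, CEV/CEVR are flat in EV but differ in which of
#' probability and magnitude rises.
#'
#' @param kind one of \code{"IEV"}, \code{"DEV"}, \code{"CEV"}, \code{"CEVR"}.
#' @param params optional list overriding \code{interval_ms}, \code{p_start},
#'   \code{p_end}, \code{ev_start}, \code{ev_end}.
#' @return an object of class \code{"contingency"} with elements \code{kind},
#'   \code{interval_ms}, \code{prob_fn}, \code{mag_fn}.
#' @examples
#' cev <- make_contingency("CEV")
#' trial_ev(cev, 500); trial_ev(cev, 3500)  # constant EV
#' @export
make_contingency <- function(kind = c("IEV", "DEV", "CEV", "CEVR"),
                             params = list()) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    # prob decreasing, magnitude rising faster than prob falls: EV increases
    IEV  = list(p_start = 0.9, p_end = 0.5, ev_start = 40,  ev_end = 100),
    # mirror image: big frequent rewards early, EV decreases
    DEV  = list(p_start = 0.5, p_end = 0.9, ev_start = 100, ev_end = 40),
    # unlearnable: probability falls, magnitude compensates exactly
    CEV  = list(p_start = 0.7, p_end = 0.3, ev_start = 60,  ev_end = 60),
    # reversed tradeoff: probability rises, magnitude falls
    CEVR = list(p_start = 0.3, p_end = 0.7, ev_start = 60,  ev_end = 60))
  p <- utils::modifyList(c(list(interval_ms = 4000), defaults), params)
  if (p$p_start <= 0 || p$p_start > 1 || p$p_end <= 0 || p$p_end > 1)
    stop("probability endpoints must lie in (0, 1]")
  if (p$ev_start <= 0 || p$ev_end <= 0)
    stop("expected value endpoints must be positive")
  T_ms <- p$interval_ms
  prob_fn <- local({
    p0 <- p$p_start; p1 <- p$p_end; Tm <- T_ms
    function(rt_ms) p0 + (p1 - p0) * rt_ms / Tm
  })
  ev_fn <- local({
    e0 <- p$ev_start; e1 <- p$ev_end; Tm <- T_ms
    function(rt_ms) e0 + (e1 - e0) * rt_ms / Tm
  })
  mag_fn <- function(rt_ms) ev_fn(rt_ms) / prob_fn(rt_ms)
  structure(list(kind = kind, interval_ms = T_ms, params = p,
                 prob_fn = prob_fn, mag_fn = mag_fn),
            class = "contingency")
}

#' @exportS3Method base::print
print.contingency <- function(x, ...) {
  cat(sprintf("clock-task contingency %s over [0, %d) ms\n", x$kind,
              x$interval_ms))
  cat(sprintf("  EV %.1f -> %.1f, p(reward) %.2f -> %.2f\n",
              trial_ev(x, 0), trial_ev(x, x$interval_ms),
              x$prob_fn(0), x$prob_fn(x$interval_ms)))
  invisible(x)
}

#' Expected value of a response time under a contingency
#'
#' @param contingency a \code{\link{make_contingency}} object.
#' @param rt_ms response time(s) in ms, within \code{[0, interval_ms]}.
#' @return expected reward, \code{prob_fn(rt) * mag_fn(rt)}, in points.
#' @export
trial_ev <- function(contingency, rt_ms) {
  stopifnot(inherits(contingency, "contingency"))
  if (any(rt_ms < 0 | rt_ms > contingency$interval_ms))
    stop("rt_ms outside the decision interval")
  contingency$prob_fn(rt_ms) * contingency$mag_fn(rt_ms)
}

#' Draw a probabilistic trial outcome
#'
#' Rewarded with probability \code{prob_fn(rt)}; the reward equals
#' \code{mag_fn(rt)} when rewarded and 0 otherwise. A response time at or past
#' the end of the interval is a missed trial and always yields 0 points.
#' Uses R's global RNG stream, so outcomes are reproducible under
#' \code{set.seed}.
#'
#' @inheritParams trial_ev
#' @return a one-row data.frame: \code{rt_ms}, \code{rewarded},
#'   \code{reward}, \code{probability}, \code{magnitude}.
#' @export
sample_outcome <- function(contingency, rt_ms) {
  stopifnot(inherits(contingency, "contingency"), length(rt_ms) == 1L)
  if (rt_ms < 0 || rt_ms > contingency$interval_ms)
    stop("rt_ms outside the decision interval")
  if (rt_ms >= contingency$interval_ms) {   # missed trial
    return(data.frame(rt_ms = rt_ms, rewarded = 0L, reward = 0,
                      probability = 0, magnitude = 0))
  }
  pr <- contingency$prob_fn(rt_ms)
  mg <- contingency$mag_fn(rt_ms)
  hit <- as.integer(stats::runif(1) < pr)
  data.frame(rt_ms = rt_ms, rewarded = hit, reward = hit * mg,
             probability = pr, magnitude = mg)
}
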