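#' Build the lagged trial table for behavioral analyses
#'
#' Adds the one-trial-lagged predictors used by the exploration and
#' convergence models: previous response time, previous outcome, previous
#' global-maximum location, and the late-learning weight \code{-1/trial}.
#' Lags never cross run boundaries: the first trial of every run has missing
#' lagged fields. Subject-level moderator columns (e.g. synthetic brain
#' betas) are merged by subject.
#'
#' @param traj trajectory table (multi-subject) with \code{subject},
#'   \code{run}, \code{trial}, \code{rt_ms}, \code{rewarded},
#'   \code{rt_vmax}.
#' @param moderators optional data.frame with a \code{subject} column plus
#'   moderator columns.
#' @return data.frame with appended \code{rt_prev}, \code{reward_prev},
#'   \code{rt_vmax_prev}, \code{inv_trial}.
#' @export
lagged_trial_table <- function(traj, moderators = NULL) {
  stopifnot(all(c("subject", "run", "trial", "rt_ms", "rewarded") %in%
                  names(traj)))
  traj <- traj[order(traj$subject, traj$run, traj$trial), , drop = FALSE]
  g <- interaction(traj$subject, traj$run, drop = TRUE)
  lag1 <- function(x) stats::ave(x, g, FUN = function(v) c(NA, v[-length(v)]))
  traj$rt_prev <- lag1(traj$rt_ms)
  traj$reward_prev <- lag1(traj$rewarded)
  if (!is.null(traj$rt_vmax)) traj$rt_vmax_prev <- lag1(traj$rt_vmax)
  traj$inv_trial <- -1 / traj$trial
  if (!is.null(moderators)) traj <- merge(traj, moderators, by = "subject",
                                          sort = FALSE)
  traj[order(traj$subject, traj$run, traj$trial), , drop = FALSE]
}

#' Exploration index: RT autocorrelation and its moderators
#'
#' Mixed-effects regression of the current response time on the previous
#' response time, the previous outcome, and a subject-level moderator, with
#' random intercepts for subject and run-within-subject. The
#' \code{rt_prev} coefficient is the RT autocorrelation: values near 1 mean
#' perseveration, values near 0 mean large trial-to-trial swings, i.e.
#' exploration. A negative \code{rt_prev x moderator} interaction means
#' higher-moderator subjects explore more; the three-way term with the
#' previous outcome captures post-reward exploration.
#'
#' @param table a \code{\link{lagged_trial_table}} (>= 2 subjects).
#' @param moderator name of the moderator column, or NULL for the
#'   unmoderated model.
#' @return list: \code{model} (the lmer fit) and \code{coef} (fixed-effect
#'   table with estimates, SEs, t values).
#' @export
exploration_index <- function(table, moderator = NULL) {
  table <- stats::na.omit(table[, unique(c("subject", "run", "rt_ms",
                                           "rt_prev", "reward_prev",
                                           moderator))])
  if (length(unique(table$subject)) < 2) stop("need >= 2 subjects")
  # seconds keep the design matrix well-scaled against unit-SD moderators;
  # the rt_prev coefficient is dimensionless either way
  table$rt_s <- table$rt_ms / 1000
  table$rt_prev <- table$rt_prev / 1000
  rhs <- if (is.null(moderator)) "rt_prev * reward_prev" else
    sprintf("rt_prev * reward_prev * %s", moderator)
  fm <- stats::as.formula(paste("rt_s ~", rhs,
                                "+ (1 | subject) + (1 | subject:run)"))
  m <- lme4::lmer(fm, data = table, REML = TRUE,
                  control = lme4::lmerControl(calc.derivs = FALSE))
  list(model = m, coef = fixef_table(m))
}

#' Convergence index: attraction to the global value maximum
#'
#' Mixed-effects regression of the current response time on the previous
#' trial's global-maximum location and its interaction with \code{-1/trial}
#' (and optionally a subject-level moderator). A positive
#' \code{rt_vmax_prev} coefficient indicates exploitation — choices track
#' the learned maximum — and the \code{inv_trial} interaction tests whether
#' convergence strengthens late in learning.
#'
#' @inheritParams exploration_index
#' @return list: \code{model}, \code{coef}.
#' @export
convergence_index <- function(table, moderator = NULL) {
  table <- stats::na.omit(table[, unique(c("subject", "run", "rt_ms",
                                           "rt_vmax_prev", "inv_trial",
                                           moderator))])
  if (length(unique(table$subject)) < 2) stop("need >= 2 subjects")
  table$rt_s <- table$rt_ms / 1000
  table$rt_vmax_prev <- table$rt_vmax_prev / 1000
  rhs <- if (is.null(moderator)) "rt_vmax_prev * inv_trial" else
    sprintf("rt_vmax_prev * inv_trial * %s", moderator)
  fm <- stats::as.formula(paste("rt_s ~", rhs,
                                "+ (1 | subject) + (1 | subject:run)"))
  m <- lme4::lmer(fm, data = table, REML = TRUE,
                  control = lme4::lmerControl(calc.derivs = FALSE))
  list(model = m, coef = fixef_table(m))
}

fixef_table <- function(m) {
  cf <- lme4::fixef(m)
  se <- sqrt(diag(as.matrix(stats::vcov(m))))
  data.frame(term = names(cf), estimate = unname(cf), se = unname(se),
             t = unname(cf / se))
}

#' Counting-process survival table with time-varying covariates
#'
#' Expands every responded trial into 100 ms risk intervals across the
#' modeled 1000-3500 ms window, with the trial's momentary learned value and
#' uncertainty sampled in each interval as time-varying covariates. The row
#' whose interval contains the response carries the event; responses after
#' the window end are censored at 3500 ms, and responses at or before the
#' window start contribute no rows. Optionally the "no-go" bins hugging the
#' window edges are censored (dropped), and covariates are rescaled to
#' mean 0 / SD 1 within subject.
#'
#' Value comes from the selective-maintenance replay and uncertainty from the
#' Kalman-filter replay of the same choices, each evaluated on the 100 ms
#' choice grid from the state entering the trial.
#'
#' @param trials multi-subject trial table sorted by subject, run, trial.
#' @param basis a \code{\link{build_basis}} object.
#' @param value_params parameters for the selective value replay
#'   (\code{alpha}, \code{gamma}).
#' @param unc_params parameters for the fixed_uv uncertainty replay
#'   (\code{alpha}, \code{sigma_rew} optional).
#' @param window modeled interval, ms.
#' @param bin_ms sampling bin, ms.
#' @param censor_no_go drop bins adjacent to the window edges.
#' @param no_go_ms width censored at each edge when \code{censor_no_go}.
#' @param rescale standardize value/uncertainty within subject.
#' @return data.frame: \code{subject, run, trial, start, stop, event, value,
#'   uncertainty}.
#' @export
build_survival_table <- function(trials, basis, value_params, unc_params,
                                 window = c(1000, 3500), bin_ms = 100,
                                 censor_no_go = FALSE, no_go_ms = bin_ms,
                                 rescale = TRUE) {
  stopifnot(window[2] > window[1])
  subj_split <- split(trials, trials$subject)
  rows <- lapply(subj_split, function(df) {
    df <- df[order(df$run, df$trial), , drop = FALSE]
    Vg <- replay_grid(df, basis, value_params, "selective")$v
    Ug <- replay_grid(df, basis, unc_params, "fixed_uv")$u
    per_trial <- lapply(seq_len(nrow(df)), function(i) {
      rt <- df$rt_ms[i]
      if (rt <= window[1]) return(NULL)
      last <- min(rt, window[2])
      n_rows <- ceiling((last - window[1]) / bin_ms - 1e-9)
      starts <- window[1] + (seq_len(n_rows) - 1) * bin_ms
      stops <- pmin(starts + bin_ms, last)
      ev <- integer(length(starts))
      if (rt <= window[2]) ev[length(ev)] <- 1L
      gbin <- rt_to_bin(starts, basis)
      data.frame(subject = df$subject[i], run = df$run[i],
                 trial = df$trial[i], start = starts, stop = stops,
                 event = ev, value = Vg[i, gbin], uncertainty = Ug[i, gbin])
    })
    do.call(rbind, per_trial)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (censor_no_go) {
    out <- out[out$start >= window[1] + no_go_ms &
                 out$stop <= window[2] - no_go_ms, , drop = FALSE]
  }
  if (rescale) {
    out$value <- rescale_within_subject(out$value, out$subject)
    out$uncertainty <- rescale_within_subject(out$uncertainty, out$subject)
  }
  out
}

# replay observed choices, returning per-trial pre-update value (v) and
# uncertainty (u) functions on the choice grid (trials x n_grid matrices)
replay_grid <- function(df, basis, params, variant) {
  params <- as.list(params)
  E <- eligibility_matrix(basis)
  bins <- rt_to_bin(df$rt_ms, basis)
  run_start <- c(TRUE, df$run[-1] != df$run[-nrow(df)])
  n <- nrow(df)
  B <- basis$n_basis
  V <- matrix(0, n, basis$n_grid)
  U <- if (variant == "fixed_uv") matrix(0, n, basis$n_grid) else NULL
  if (variant == "fixed_uv" && is.null(params$sigma_rew)) {
    s <- stats::sd(df$reward)
    params$sigma_rew <- if (is.finite(s) && s > 0) s else
      max(mean(abs(df$reward)), 1)
  }
  w <- numeric(B)
  sig <- rep(params$sigma_rew %||% 0, B)
  for (i in seq_len(n)) {
    if (run_start[i]) {
      w <- numeric(B)
      sig <- rep(params$sigma_rew %||% 0, B)
    }
    V[i, ] <- drop(crossprod(w, basis$phi))
    if (!is.null(U)) U[i, ] <- drop(crossprod(sig, basis$phi))
    e <- E[, bins[i]]
    r <- df$reward[i]
    if (variant == "fixed_uv") {
      gain <- sig^2 / (sig^2 + params$sigma_rew^2)
      w <- w + e * params$alpha * (r - w)
      sig <- (1 - e * gain) * sig
    } else {
      wn <- w + e * params$alpha * (r - w)
      if (variant == "selective") wn <- wn - params$gamma * (1 - e) * w
      w <- wn
    }
  }
  list(v = V, u = U)
}

#' Standardize a covariate within subject
#'
#' @param x numeric vector.
#' @param subject grouping vector of the same length.
#' @return per-subject z-scores; a constant series within a subject yields
#'   zeros with a warning.
#' @export
rescale_within_subject <- function(x, subject) {
  out <- stats::ave(x, subject, FUN = function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warning("constant covariate within a subject; returning zeros")
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s
  })
  out
}

#' Mixed-effects proportional-hazards fit of the response hazard
#'
#' Convenience wrapper fitting a Cox model on the counting-process table,
#' with value and uncertainty (optionally interacted with subject-level
#' moderators) as time-varying covariates and a cluster term for subject.
#'
#' @param surv_table a \code{\link{build_survival_table}} result, optionally
#'   merged with moderator columns.
#' @param covariates character vector of model terms.
#' @return a \code{survival::coxph} fit.
#' @export
fit_hazard_model <- function(surv_table,
                             covariates = c("value", "uncertainty")) {
  fm <- stats::as.formula(paste(
    "survival::Surv(start, stop, event) ~",
    paste(covariates, collapse = " + "), "+ cluster(subject)"))
  survival::coxph(fm, data = surv_table)
}
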