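#' Parameterization of the model variants
#'
#' Free parameters are estimated in an unconstrained transformed space:
#' logistic for rates in (0,1) (\code{alpha}, \code{gamma}), log for the
#' positive temperature \code{beta}, identity for the sign-free uncertainty
#' weight \code{tau}.
#'
#' @param variant model variant id.
#' @return list with \code{names}, \code{to_natural}, \code{to_transformed}.
#' @keywords internal
param_info <- function(variant = c("selective", "full", "fixed_uv")) {
  variant <- match.arg(variant)
  nm <- switch(variant,
               selective = c("alpha", "gamma", "beta"),
               full      = c("alpha", "beta"),
               fixed_uv  = c("alpha", "beta", "tau"))
  trans <- list(alpha = stats::qlogis, gamma = stats::qlogis, beta = log,
                tau = identity)
  inv <- list(alpha = stats::plogis, gamma = stats::plogis, beta = exp,
              tau = identity)
  list(
    names = nm,
    to_natural = function(theta) {
      stats::setNames(vapply(seq_along(nm),
                             function(i) inv[[nm[i]]](theta[i]), 0), nm)
    },
    to_transformed = function(par) {
      stats::setNames(vapply(nm, function(p) trans[[p]](par[[p]]), 0), nm)
    })
}

#' Default population prior in transformed space
#'
#' Centered on a moderate learner: learning rate 0.1, decay 0.2, temperature
#' 20 points, no uncertainty preference; unit SDs.
#'
#' @inheritParams param_info
#' @return list with \code{mean} and \code{sd} vectors (transformed space).
#' @export
default_prior <- function(variant = c("selective", "full", "fixed_uv")) {
  variant <- match.arg(variant)
  full <- c(alpha = stats::qlogis(0.1), gamma = stats::qlogis(0.2),
            beta = log(20), tau = 0)
  nm <- param_info(variant)$names
  list(mean = full[nm], sd = stats::setNames(rep(1, length(nm)), nm))
}

#' Negative log likelihood of observed choices
#'
#' Sum over trials of minus the log softmax probability of the observed
#' response bin, with the value (or uncertainty-weighted Q) function computed
#' from the state \emph{before} the trial's update — the first trial of each
#' run is therefore uniform over the grid, contributing \code{log(n_grid)}.
#'
#' @param par named parameter vector on the natural scale (\code{alpha},
#'   \code{gamma}/\code{tau} as applicable, \code{beta}).
#' @param data single-subject trial table sorted by run, trial.
#' @param variant model variant.
#' @param basis a \code{\link{build_basis}} object.
#' @param sigma_rew measurement noise for \code{fixed_uv}; defaults to the
#'   empirical reward SD of \code{data}.
#' @param E optional precomputed \code{\link{eligibility_matrix}}.
#' @return scalar negative log likelihood (nats).
#' @export
nll_choice <- function(par, data, variant = c("selective", "full",
                                              "fixed_uv"),
                       basis, sigma_rew = NULL, E = NULL) {
  variant <- match.arg(variant)
  par <- as.list(par)
  if (any(data$rt_ms < 0 | data$rt_ms > basis$interval_ms))
    stop("rt_ms outside the decision interval")
  bins <- rt_to_bin(data$rt_ms, basis)
  run_start <- c(TRUE, data$run[-1] != data$run[-nrow(data)])
  if (is.null(E)) E <- eligibility_matrix(basis)
  if (variant == "fixed_uv") {
    if (is.null(sigma_rew)) sigma_rew <- reference_reward_sd(data)
    cpp_kf_nll(bins, data$reward, run_start, basis$phi, E,
               par$alpha, par$beta, par$tau %||% 0, sigma_rew)
  } else {
    cpp_sceptic_nll(bins, data$reward, run_start, basis$phi, E,
                    par$alpha,
                    if (variant == "selective") par$gamma else 0,
                    par$beta, if (variant == "selective") 1L else 2L)
  }
}

penalized_objective <- function(theta, info, data_pre, prior, variant,
                                basis, sigma_rew, E) {
  par <- info$to_natural(theta)
  nll <- nll_choice(par, data_pre, variant, basis, sigma_rew, E)
  nll + 0.5 * sum(((theta - prior$mean) / prior$sd)^2)
}

#' Fit one subject by penalized maximum likelihood (MAP)
#'
#' Minimizes the choice NLL plus a Gaussian prior penalty in transformed
#' space, from multiple starts placed at prior quantiles. Approximate
#' posterior SDs come from the curvature (inverse Hessian) at the mode. A
#' singular or non-positive-definite Hessian — e.g. for degenerate,
#' uninformative data — yields wide SDs and sets the convergence flag.
#'
#' @param data single-subject trial table (>= 50 trials recommended).
#' @param variant model variant.
#' @param basis a \code{\link{build_basis}} object.
#' @param prior list with transformed-space \code{mean}, \code{sd}; defaults
#'   to \code{\link{default_prior}}.
#' @param n_starts number of optimizer restarts (prior quantiles
#'   0.1..0.9).
#' @param start optional extra start (transformed space), e.g. a warm start.
#' @param sigma_rew see \code{\link{nll_choice}}.
#' @param E optional precomputed eligibility matrix.
#' @return object of class \code{"subject_fit"}: transformed modes
#'   (\code{theta}), natural-scale \code{par}, \code{theta_sd}, \code{nll}
#'   (unpenalized at the mode), \code{objective}, \code{converged}.
#' @export
fit_subject <- function(data, variant = c("selective", "full", "fixed_uv"),
                        basis, prior = NULL, n_starts = 5, start = NULL,
                        sigma_rew = NULL, E = NULL) {
  variant <- match.arg(variant)
  info <- param_info(variant)
  if (is.null(prior)) prior <- default_prior(variant)
  if (is.null(E)) E <- eligibility_matrix(basis)
  if (variant == "fixed_uv" && is.null(sigma_rew))
    sigma_rew <- reference_reward_sd(data)
  qs <- seq(0.1, 0.9, length.out = max(1, n_starts))
  starts <- lapply(qs, function(q) prior$mean + stats::qnorm(q) * prior$sd)
  if (!is.null(start)) starts <- c(list(start), starts)
  best <- NULL
  for (s in starts) {
    o <- try(stats::optim(s, penalized_objective, method = "BFGS",
                          info = info, data_pre = data, prior = prior,
                          variant = variant, basis = basis,
                          sigma_rew = sigma_rew, E = E,
                          control = list(reltol = 1e-6, maxit = 500)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("all optimizer starts failed")
  H <- try(stats::optimHess(best$par, penalized_objective, info = info,
                            data_pre = data, prior = prior, variant = variant,
                            basis = basis, sigma_rew = sigma_rew, E = E),
           silent = TRUE)
  converged <- best$convergence == 0
  sds <- rep(NA_real_, length(best$par))
  if (!inherits(H, "try-error")) {
    Hi <- try(solve(H), silent = TRUE)
    if (!inherits(Hi, "try-error") && all(diag(Hi) > 0)) {
      sds <- sqrt(diag(Hi))
    } else converged <- FALSE
  } else converged <- FALSE
  sds[is.na(sds)] <- 10  # wide-SD convention for flat directions
  theta <- stats::setNames(best$par, info$names)
  structure(list(variant = variant,
                 theta = theta,
                 theta_sd = stats::setNames(sds, info$names),
                 par = info$to_natural(theta),
                 objective = best$value,
                 nll = nll_choice(info$to_natural(theta), data, variant,
                                  basis, sigma_rew, E),
                 converged = converged,
                 sigma_rew = sigma_rew),
            class = "subject_fit")
}

#' Hierarchical (empirical-Bayes) population fit
#'
#' Alternates between (a) MAP fits of every subject under the current
#' population prior and (b) re-estimation of the population mean and SD in
#' transformed space from the subject posteriors (SD pools the dispersion of
#' the modes with the mean posterior variance, floored at \code{sd_floor}).
#' Individual estimates are thereby shrunk toward the population, as in
#' multilevel regression. Iteration stops when no population mean moves by
#' more than \code{tol}.
#'
#' @param data multi-subject trial table with a \code{subject} column.
#' @param variant model variant.
#' @param basis a \code{\link{build_basis}} object.
#' @param prior initial population prior; default \code{\link{default_prior}}.
#' @param max_iter maximum outer iterations.
#' @param tol absolute parameter-change tolerance for the outer loop.
#' @param sd_floor lower bound for population SDs.
#' @param n_starts restarts for first-iteration subject fits; later
#'   iterations warm-start from the previous modes.
#' @return object of class \code{"population_fit"}: \code{mean}, \code{sd}
#'   (transformed space), \code{subjects} (list of subject fits),
#'   \code{trace} (iteration history), \code{converged}, \code{group_par}
#'   (group means back-transformed to the natural scale).
#' @export
fit_population <- function(data, variant = c("selective", "full", "fixed_uv"),
                           basis, prior = NULL, max_iter = 50, tol = 1e-3,
                           sd_floor = 0.05, n_starts = 5) {
  variant <- match.arg(variant)
  info <- param_info(variant)
  if (is.null(prior)) prior <- default_prior(variant)
  ids <- unique(data$subject)
  if (length(ids) < 2) stop("need at least two subjects")
  E <- eligibility_matrix(basis)
  by_subj <- split(data, factor(data$subject, levels = ids))
  fits <- vector("list", length(ids))
  names(fits) <- as.character(ids)
  pop <- prior
  trace <- list()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (k in seq_along(ids)) {
      warm <- if (it > 1) fits[[k]]$theta else NULL
      fits[[k]] <- fit_subject(by_subj[[k]], variant, basis, prior = pop,
                               n_starts = if (it == 1) n_starts else 0,
                               start = if (is.null(warm)) NULL else warm,
                               E = E)
    }
    modes <- do.call(rbind, lapply(fits, `[[`, "theta"))
    vars <- do.call(rbind, lapply(fits, function(f) f$theta_sd^2))
    new_mean <- colMeans(modes)
    new_sd <- pmax(sqrt(apply(modes, 2, stats::var) + colMeans(vars)),
                   sd_floor)
    delta <- max(abs(new_mean - pop$mean))
    trace[[it]] <- data.frame(iter = it, t(new_mean), delta = delta)
    pop <- list(mean = new_mean, sd = new_sd)
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(variant = variant, mean = pop$mean, sd = pop$sd,
                 subjects = fits,
                 trace = do.call(rbind, trace),
                 converged = converged,
                 group_par = info$to_natural(pop$mean)),
            class = "population_fit")
}

#' @exportS3Method base::print
print.population_fit <- function(x, ...) {
  cat(sprintf("hierarchical %s fit, %d subjects, %s\n", x$variant,
              length(x$subjects),
              if (x$converged) "converged" else "NOT converged"))
  print(round(rbind(`mean (transformed)` = x$mean, sd = x$sd), 3))
  cat("group-mean parameters (natural scale):\n")
  print(round(x$group_par, 4))
  invisible(x)
}

#' Recompute every subject's trajectory at the group-mean parameters
#'
#' Replays each subject's observed choices through the model with the shared
#' group-mean parameters (no free parameters), so that latent signals are on
#' a common scale across subjects and downstream regression coefficients are
#' comparable.
#'
#' @param data multi-subject trial table.
#' @param popfit a \code{\link{fit_population}} result.
#' @param basis a \code{\link{build_basis}} object.
#' @return single data.frame of trajectories for all subjects.
#' @export
refit_group_means <- function(data, popfit, basis) {
  par <- as.list(popfit$group_par)
  if (popfit$variant == "fixed_uv" && is.null(par$sigma_rew))
    par$sigma_rew <- reference_reward_sd(data)
  out <- lapply(split(data, data$subject), sceptic_trajectory, basis = basis,
                params = par, variant = popfit$variant)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$subject, res$run, res$trial), , drop = FALSE]
}

#' Simulate-and-refit parameter recovery harness
#'
#' Generates a synthetic population, simulates the experiment, fits the
#' hierarchical model, and reports truth-versus-estimate agreement per
#' parameter (Pearson correlation on the transformed scale, bias and RMSE of
#' the transformed population mean and of subject-level estimates).
#'
#' @param pop_spec a \code{\link{population_spec}}.
#' @param variant fitted model variant (also used as the generative model).
#' @param basis a \code{\link{build_basis}} object.
#' @param max_iter,n_starts passed to \code{\link{fit_population}}.
#' @return list: \code{fit} (the population fit), \code{truth} (generating
#'   parameter table), \code{report} (per-parameter data.frame with
#'   \code{cor}, \code{bias}, \code{rmse}, \code{pop_mean_true},
#'   \code{pop_mean_est}, \code{pop_mean_se}).
#' @export
recover_parameters <- function(pop_spec, variant = "selective", basis,
                               max_iter = 10, n_starts = 5) {
  info <- param_info(variant)
  truth <- gen_population(pop_spec)
  sim <- simulate_experiment(truth, basis = basis, variant = variant,
                             schedule = pop_spec$schedule,
                             seed = pop_spec$seed + 1L)
  fit <- fit_population(sim$trials, variant, basis, max_iter = max_iter,
                        n_starts = n_starts)
  modes <- do.call(rbind, lapply(fit$subjects, `[[`, "theta"))
  rows <- lapply(info$names, function(p) {
    tcol <- paste0(p, "_t")
    tr <- truth[[tcol]]
    est <- modes[, p]
    data.frame(param = p,
               cor = suppressWarnings(stats::cor(tr, est)),
               bias = mean(est - tr),
               rmse = sqrt(mean((est - tr)^2)),
               pop_mean_true = mean(tr),
               pop_mean_est = fit$mean[[p]],
               # SE of the estimated population mean: fitted population SD
               # (dispersion of modes pooled with posterior variance) / sqrt(n)
               pop_mean_se = fit$sd[[p]] / sqrt(length(est)))
  })
  list(fit = fit, truth = truth, trials = sim$trials,
       report = do.call(rbind, rows))
}
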