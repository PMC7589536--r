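#' Specification of a synthetic subject population
#'
#' Subject-level parameters are drawn from independent normal distributions in
#' the transformed space used for fitting (logit for rates, log for the
#' temperature, identity for the uncertainty weight), mirroring the
#' hierarchical estimation model. Defaults describe a study-scale cohort:
#' 70 subjects, 8 runs of 50 trials on a 4-s interval, the four monotone
#' contingencies counterbalanced two runs each, moderate learning rates
#' (median alpha 0.1), mild selective decay (median gamma 0.2), temperature
#' around 20 points, and mild uncertainty aversion (tau centered on -0.5).
#'
#' @param n_subjects number of subjects.
#' @param means,sds named numeric vectors over \code{alpha}, \code{gamma},
#'   \code{beta}, \code{tau}: generating means/SDs in transformed space.
#' @param n_runs,n_trials task schedule shape.
#' @param kinds contingency kinds cycled over runs.
#' @param seed master seed; every generator derives its stream from it.
#' @return list of class \code{"population_spec"}.
#' @export
population_spec <- function(n_subjects = 70,
                            means = c(alpha = stats::qlogis(0.1),
                                      gamma = stats::qlogis(0.2),
                                      beta = log(20), tau = -0.5),
                            sds = c(alpha = 0.5, gamma = 0.5,
                                    beta = 0.4, tau = 0.3),
                            n_runs = 8, n_trials = 50,
                            kinds = c("IEV", "DEV", "CEV", "CEVR"),
                            seed = 1L) {
  stopifnot(n_subjects >= 1, all(sds >= 0))
  structure(list(n_subjects = n_subjects, means = means, sds = sds,
                 schedule = list(n_runs = n_runs, n_trials = n_trials,
                                 kinds = kinds),
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Draw a table of subject parameters
#'
#' @param spec a \code{\link{population_spec}}.
#' @return data.frame with one row per subject: natural-scale \code{alpha},
#'   \code{gamma}, \code{beta}, \code{tau} and their transformed-space values
#'   (suffix \code{_t}).
#' @export
gen_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  withr_seed(spec$seed, {
    n <- spec$n_subjects
    draw <- function(p) stats::rnorm(n, spec$means[[p]], spec$sds[[p]])
    at <- draw("alpha"); gt <- draw("gamma"); bt <- draw("beta")
    tt <- draw("tau")
    data.frame(subject = seq_len(n),
               alpha = stats::plogis(at), gamma = stats::plogis(gt),
               beta = exp(bt), tau = tt,
               alpha_t = at, gamma_t = gt, beta_t = bt, tau_t = tt)
  })
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Simulate the clock task for a population of model agents
#'
#' Each subject plays the full schedule with its own parameters: on every
#' trial the agent evaluates its decision function (value, or value plus
#' tau-weighted uncertainty for the Kalman variant), samples a response bin by
#' softmax, receives a probabilistic outcome from the run's contingency, and
#' updates. Inter-trial intervals are exponential (mean 2.5 s) truncated to
#' [1, 10] s. Latent signals are appended by deterministic replay
#' (\code{\link{sceptic_trajectory}}), so they equal the agent's own
#' trajectory exactly.
#'
#' @param params data.frame from \code{\link{gen_population}} (columns
#'   \code{subject, alpha, gamma, beta, tau}).
#' @param basis a \code{\link{build_basis}} object.
#' @param variant generative model variant.
#' @param schedule list with \code{n_runs}, \code{n_trials}, \code{kinds};
#'   contingency kinds are cycled across runs in a per-subject shuffled
#'   order.
#' @param seed integer seed.
#' @param feedback_s feedback display duration, s.
#' @param iti_mean_s,iti_range_s ITI distribution (exponential, truncated).
#' @return list: \code{trials} (trial table with outcomes, onsets and latent
#'   signals) and \code{params}.
#' @export
simulate_experiment <- function(params, basis, variant = "selective",
                                schedule = list(n_runs = 8, n_trials = 50,
                                                kinds = c("IEV", "DEV",
                                                          "CEV", "CEVR")),
                                seed = 1L, feedback_s = 0.9,
                                iti_mean_s = 2.5, iti_range_s = c(1, 10)) {
  E <- eligibility_matrix(basis)
  withr_seed(seed, {
    out <- vector("list", nrow(params))
    for (si in seq_len(nrow(params))) {
      p <- params[si, ]
      run_kinds <- rep_len(sample(schedule$kinds), schedule$n_runs)
      runs <- vector("list", schedule$n_runs)
      for (r in seq_len(schedule$n_runs)) {
        cont <- make_contingency(run_kinds[r])
        sigma_rew <- if (variant == "fixed_uv")
          reference_reward_sd(contingency = cont) else NA_real_
        runs[[r]] <- simulate_run(p, basis, E, cont, variant,
                                  schedule$n_trials, sigma_rew,
                                  feedback_s, iti_mean_s, iti_range_s)
        runs[[r]]$run <- r
        runs[[r]]$contingency <- run_kinds[r]
      }
      tab <- do.call(rbind, runs)
      tab$subject <- p$subject
      par_list <- list(alpha = p$alpha, gamma = p$gamma, beta = p$beta,
                       tau = p$tau,
                       sigma_rew = if (variant == "fixed_uv")
                         stats::sd(tab$reward) else NULL)
      out[[si]] <- sceptic_trajectory(
        tab[c("subject", "run", "trial", "contingency", "rt_ms", "rewarded",
              "reward", "magnitude", "probability", "iti_s",
              "onset_clock_s", "onset_feedback_s")],
        basis, par_list, variant)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    list(trials = res, params = params)
  })
}

simulate_run <- function(p, basis, E, cont, variant, n_trials, sigma_rew,
                         feedback_s, iti_mean_s, iti_range_s) {
  B <- basis$n_basis
  w <- numeric(B)                       # weights or KF means
  sig <- rep(sigma_rew, B)              # KF sigmas
  rows <- vector("list", n_trials)
  t_clock <- 0
  for (i in seq_len(n_trials)) {
    v <- drop(crossprod(w, basis$phi))
    dec <- if (variant == "fixed_uv")
      v + p$tau * drop(crossprod(sig, basis$phi)) else v
    bin <- sample.int(basis$n_grid, 1L, prob = softmax_prob(dec, p$beta))
    rt <- basis$grid[bin]
    outc <- sample_outcome(cont, rt)
    e <- E[, bin]
    if (variant == "fixed_uv") {
      gain <- sig^2 / (sig^2 + sigma_rew^2)
      w <- w + e * p$alpha * (outc$reward - w)
      sig <- (1 - e * gain) * sig
    } else {
      wn <- w + e * p$alpha * (outc$reward - w)
      if (variant == "selective") wn <- wn - p$gamma * (1 - e) * w
      w <- wn
    }
    iti <- min(max(stats::rexp(1, 1 / iti_mean_s), iti_range_s[1]),
               iti_range_s[2])
    rows[[i]] <- data.frame(trial = i, rt_ms = rt, rewarded = outc$rewarded,
                            reward = outc$reward,
                            magnitude = outc$magnitude,
                            probability = outc$probability, iti_s = iti,
                            onset_clock_s = t_clock,
                            onset_feedback_s = t_clock + rt / 1000)
    t_clock <- t_clock + rt / 1000 + feedback_s + iti
  }
  do.call(rbind, rows)
}

#' Generate synthetic subject-level "brain beta" covariates
#'
#' Each beta is a linear combination of transformed agent parameters plus
#' Gaussian noise, then standardized: a plantable brain-behavior coupling for
#' testing moderator recovery. Zero coupling weights yield betas independent
#' of behavior.
#'
#' @param params table from \code{\link{gen_population}}.
#' @param coupling named list; each element is a named numeric vector of
#'   weights over transformed-parameter columns, e.g.
#'   \code{list(PH = c(beta_t = 1), AH = c(gamma_t = 1))}.
#' @param noise_sd named vector (or scalar) of noise SDs per beta, on the SD
#'   scale of the coupled combination.
#' @param seed integer seed.
#' @return data.frame with \code{subject} and one standardized column per
#'   beta.
#' @export
gen_betas <- function(params,
                      coupling = list(PH = c(beta_t = 1),
                                      AH = c(gamma_t = 1)),
                      noise_sd = 0.5, seed = 1L) {
  if (length(noise_sd) == 1L)
    noise_sd <- stats::setNames(rep(noise_sd, length(coupling)),
                                names(coupling))
  withr_seed(seed, {
    out <- data.frame(subject = params$subject)
    for (nm in names(coupling)) {
      w <- coupling[[nm]]
      lin <- numeric(nrow(params))
      for (cn in names(w)) lin <- lin + w[[cn]] * params[[cn]]
      s <- stats::sd(lin)
      if (s > 0) lin <- lin / s
      val <- lin + stats::rnorm(nrow(params), 0, noise_sd[[nm]])
      out[[nm]] <- as.numeric(scale(val))
    }
    out
  })
}

#' Generate an elongated synthetic voxel mask
#'
#' A voxel cloud stretched along a line in the sagittal (y-z) plane at a
#' requested clockwise angle from the AC-PC axis, with Gaussian thickness
#' perpendicular to the axis; a stand-in geometry for testing the long-axis
#' rotation and binning machinery.
#'
#' @param angle_deg clockwise rotation of the long axis from AC-PC, degrees.
#' @param n_voxels exact number of voxels in the mask.
#' @param length_mm extent along the axis.
#' @param thickness_mm SD of the perpendicular spread.
#' @param voxel_mm isotropic voxel size (affine scale).
#' @param hemisphere label, \code{"L"} or \code{"R"}.
#' @param seed integer seed.
#' @return object of class \code{"voxel_mask"}: data.frame \code{i,j,k}
#'   (integer grid), \code{prob}, \code{hemi}; attribute \code{affine}.
#' @export
gen_mask <- function(angle_deg, n_voxels = 400, length_mm = 40,
                     thickness_mm = 3, voxel_mm = 2.3,
                     hemisphere = "L", seed = 1L) {
  theta <- angle_deg * pi / 180
  u <- c(cos(theta), -sin(theta))   # anterior-inferior direction in (y, z)
  withr_seed(seed, {
    vox <- NULL
    n_try <- n_voxels
    while (is.null(vox) || nrow(vox) < n_voxels) {
      n_try <- n_try * 2
      a <- stats::runif(n_try, -length_mm / 2, length_mm / 2)
      # elliptical envelope: thickness tapers toward the tips, so the
      # extreme-voxel centroids used for rotation recovery lie on the axis
      taper <- sqrt(pmax(0, 1 - (2 * a / length_mm)^2))
      perp <- stats::rnorm(n_try, 0, thickness_mm) * taper
      y <- a * u[1] - perp * u[2]
      z <- a * u[2] + perp * u[1]
      x <- stats::rnorm(n_try, if (hemisphere == "L") -28 else 28, 2)
      ijk <- unique(round(cbind(x, y, z) / voxel_mm))
      vox <- ijk
    }
    # keep the n_voxels closest to the axis so the count is exact
    world <- vox * voxel_mm
    a_par <- world[, 2] * u[1] + world[, 3] * u[2]
    d_perp <- abs(world[, 2] * -u[2] + world[, 3] * u[1])
    keep <- order(d_perp)[seq_len(n_voxels)]
    vox <- vox[keep, , drop = FALSE]
    df <- data.frame(i = vox[, 1], j = vox[, 2], k = vox[, 3],
                     prob = 1, hemi = hemisphere)
    affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
    structure(df, affine = affine, class = c("voxel_mask", "data.frame"))
  })
}

#' Generate synthetic event-locked activity time courses
#'
#' A 1 s-sampled series containing a planted response shape around each
#' event: \code{"ramp"} rises linearly over the 4 s before the event and
#' peaks 1 s before it, \code{"onoff"} is a 0-2 s box after the event,
#' \code{"delayed"} is a sustained 2-8 s plateau after the event. Gaussian
#' noise is added on top.
#'
#' @param events event onset times, s.
#' @param shape response shape preset.
#' @param noise_sd SD of additive Gaussian noise.
#' @param total_s series length (default: covers last event + 15 s).
#' @param seed integer seed.
#' @return list: \code{time} (s), \code{value}, \code{events}.
#' @export
gen_timecourses <- function(events, shape = c("ramp", "onoff", "delayed"),
                            noise_sd = 0, total_s = NULL, seed = 1L) {
  shape <- match.arg(shape)
  if (is.null(total_s)) total_s <- max(events) + 15
  tm <- seq(0, total_s, by = 1)
  kern <- switch(shape,
    ramp    = function(dt) ifelse(dt >= -5 & dt <= -1, (dt + 5) / 4,
                                  ifelse(dt > -1 & dt < 1, 1 - (dt + 1) / 2,
                                         0)),
    onoff   = function(dt) as.numeric(dt >= 0 & dt <= 2),
    delayed = function(dt) as.numeric(dt >= 2 & dt <= 8))
  val <- numeric(length(tm))
  for (ev in events) val <- val + kern(tm - ev)
  withr_seed(seed, {
    val <- val + stats::rnorm(length(tm), 0, noise_sd)
  })
  list(time = tm, value = val, events = events)
}
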