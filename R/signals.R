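#' Extract trial-level decision signals for regressor construction
#'
#' Collects the model-derived signals from a trajectory table together with
#' the event timing needed for convolution. The reward prediction error is
#' aligned with the feedback phase; entropy, uncertainty percentile, the
#' global-maximum location and the chosen value are aligned with the clock
#' (decision) phase. The trial-to-trial shift of the global maximum,
#' \code{delta_rt_vmax}, is the within-run first difference of
#' \code{rt_vmax} (NA on the first trial of a run).
#'
#' @param traj a \code{\link{sceptic_trajectory}} table with onset columns
#'   (\code{onset_clock_s}, \code{onset_feedback_s}) as produced by
#'   \code{\link{simulate_experiment}}.
#' @param feedback_s feedback duration, s.
#' @return data.frame: identifiers, onsets/durations for both phases, and the
#'   signal columns (\code{rpe}, \code{entropy}, \code{rt_vmax},
#'   \code{delta_rt_vmax}, \code{v_chosen}, and \code{u_percentile} when
#'   present).
#' @export
extract_trial_signals <- function(traj, feedback_s = 0.9) {
  need <- c("run", "trial", "rt_ms", "onset_clock_s", "onset_feedback_s",
            "rpe", "entropy", "rt_vmax")
  miss <- setdiff(need, names(traj))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- traj
  out$clock_onset_s <- traj$onset_clock_s
  out$clock_duration_s <- traj$rt_ms / 1000
  out$feedback_onset_s <- traj$onset_feedback_s
  out$feedback_duration_s <- feedback_s
  out$delta_rt_vmax <- stats::ave(out$rt_vmax, out$subject %||% 1, out$run,
                                  FUN = function(x) c(NA, diff(x)))
  out
}

#' Canonical double-gamma hemodynamic response function
#'
#' The conventional two-gamma kernel: a positive lobe peaking near 5-6 s
#' (gamma with shape 6, scale 1) minus an undershoot near 16 s (shape 16)
#' scaled by \code{undershoot_ratio}; the kernel is normalized to peak at 1.
#'
#' @param t time grid in seconds (nonnegative).
#' @param peak_shape,undershoot_shape,scale_s,undershoot_ratio gamma
#'   parameters of the two lobes.
#' @return numeric kernel values at \code{t}.
#' @export
double_gamma_hrf <- function(t, peak_shape = 6, undershoot_shape = 16,
                             scale_s = 1, undershoot_ratio = 1 / 6) {
  h <- stats::dgamma(t, peak_shape, scale = scale_s) -
    undershoot_ratio * stats::dgamma(t, undershoot_shape, scale = scale_s)
  h / max(h)
}

#' Duration-modulated, peak-renormalized convolved regressor
#'
#' For each trial a unit-height boxcar spanning the aligned phase (clock
#' onset to response for clock-aligned signals; the feedback display for
#' \code{rpe}) is convolved with the HRF and its peak renormalized to 1, so
#' that the per-trial response amplitude encodes the model signal rather than
#' the phase duration. The renormalized response is multiplied by the
#' (per-run mean-centered) signal value and the per-trial responses are
#' summed, then resampled from the 0.1 s internal grid to the 1 s repetition
#' time.
#'
#' @param signals table from \code{\link{extract_trial_signals}} (one
#'   subject).
#' @param which signal column name, e.g. \code{"rpe"} or \code{"entropy"}.
#' @param tr_s output sampling interval (repetition time), s.
#' @param dt_s internal oversampled convolution step, s.
#' @param center mean-center the signal within run before convolution
#'   (default TRUE; disable for raw task-structure regressors).
#' @param pad_s padding after the last event, s.
#' @return data.frame of class \code{"regressor"}: \code{run}, \code{time_s},
#'   \code{value}.
#' @export
build_dm_regressor <- function(signals, which, tr_s = 1, dt_s = 0.1,
                               center = TRUE, pad_s = 20) {
  stopifnot(which %in% names(signals))
  align <- if (which == "rpe") "feedback" else "clock"
  runs <- split(signals, signals$run)
  out <- lapply(runs, function(df) {
    onset <- if (align == "feedback") df$feedback_onset_s else
      df$clock_onset_s
    dur <- if (align == "feedback") df$feedback_duration_s else
      df$clock_duration_s
    if (any(dur < 0)) stop("negative durations")
    sig <- df[[which]]
    sig[is.na(sig)] <- 0
    if (center) sig <- sig - mean(sig)
    # common grid per run regardless of alignment, so clock- and
    # feedback-aligned regressors are directly comparable
    t_end <- max(df$feedback_onset_s + df$feedback_duration_s,
                 df$clock_onset_s + df$clock_duration_s) + pad_s
    grid <- seq(0, t_end, by = dt_s)
    hrf <- double_gamma_hrf(seq(0, 32, by = dt_s))
    acc <- numeric(length(grid))
    for (i in seq_len(nrow(df))) {
      box <- as.numeric(grid >= onset[i] & grid < onset[i] + dur[i])
      conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(grid)]
      pk <- max(abs(conv))
      if (pk > 0) conv <- conv / pk   # peak renormalization
      acc <- acc + conv * sig[i]
    }
    keep <- seq(1, length(grid), by = round(tr_s / dt_s))
    data.frame(run = df$run[1], time_s = grid[keep], value = acc[keep])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("regressor", "data.frame")
  res
}

#' Gaussian-weighted running-line high-pass filter
#'
#' Removes fluctuations slower than \code{cutoff_hz} by subtracting, at every
#' time point, the fit of a locally weighted linear trend. The Gaussian
#' weight SD is set so that the cutoff is the half-amplitude frequency of
#' the underlying smoother, \eqn{\sigma = \sqrt{\ln 2}/(\sqrt{2}\pi f_c)}
#' (about 23 s at the default 0.008 Hz cutoff, i.e. a 125 s period). Slower
#' drifts are removed nearly completely while task-band fluctuations pass
#' essentially unchanged.
#'
#' @param x numeric series, regularly sampled.
#' @param tr_s sampling interval, s.
#' @param cutoff_hz high-pass cutoff frequency.
#' @return filtered series of the same length. If the series is shorter than
#'   one cutoff period a warning is issued and the input is returned
#'   unchanged.
#' @export
highpass <- function(x, tr_s = 1, cutoff_hz = 0.008) {
  n <- length(x)
  period_s <- 1 / cutoff_hz
  if (n * tr_s < period_s) {
    warning("series shorter than one filter window; returning unfiltered")
    return(x)
  }
  sigma <- sqrt(log(2)) / (sqrt(2) * pi * cutoff_hz) / tr_s  # in samples
  half <- ceiling(4 * sigma)
  idx <- seq_len(n)
  fitted <- numeric(n)
  for (i in idx) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    d <- (lo:hi) - i
    w <- exp(-d^2 / (2 * sigma^2))
    y <- x[lo:hi]
    sw <- sum(w); swd <- sum(w * d); swd2 <- sum(w * d^2)
    swy <- sum(w * y); swdy <- sum(w * d * y)
    denom <- sw * swd2 - swd^2
    fitted[i] <- if (denom > 0) (swy * swd2 - swd * swdy) / denom else
      swy / sw
  }
  x - fitted
}

#' Run-level correlation between two regressors, pooled across subjects
#'
#' Pearson correlation per run, then a pooled mean on the Fisher-z scale with
#' a hierarchical interval: run z-values are first averaged within subject
#' and the 95% interval is a t-interval over subject means (falling back to
#' runs when no subject grouping is given). Zero-variance runs are flagged
#' and excluded.
#'
#' @param regA,regB \code{\link{build_dm_regressor}} tables on identical
#'   run/time grids.
#' @param subject optional vector of subject ids, one per run (in the order
#'   of \code{unique(regA$run)}); or a column \code{subject} present in the
#'   tables.
#' @return list: \code{per_run} (data.frame run, r), \code{mean_r},
#'   \code{ci} (95%), \code{n_dropped}.
#' @export
regressor_correlation <- function(regA, regB, subject = NULL) {
  key_a <- interaction(regA$run, regA$time_s, drop = TRUE)
  key_b <- interaction(regB$run, regB$time_s, drop = TRUE)
  if (!identical(levels(key_a), levels(key_b)) || nrow(regA) != nrow(regB))
    stop("regressors must share the same run/time grid")
  if (is.null(subject) && !is.null(regA$subject))
    subject <- tapply(regA$subject, regA$run, `[`, 1)
  runs <- unique(regA$run)
  r <- vapply(runs, function(rr) {
    a <- regA$value[regA$run == rr]
    b <- regB$value[regB$run == rr]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, 0)
  per_run <- data.frame(run = runs, r = r)
  ok <- !is.na(r)
  z <- atanh(pmin(pmax(r[ok], -1 + 1e-12), 1 - 1e-12))
  grp <- if (!is.null(subject)) subject[ok] else seq_along(z)
  zm <- tapply(z, grp, mean)
  mean_r <- tanh(mean(zm))
  se <- stats::sd(zm) / sqrt(length(zm))
  ci <- tanh(mean(zm) + c(-1, 1) * stats::qt(0.975, max(1, length(zm) - 1)) *
               se)
  list(per_run = per_run, mean_r = mean_r, ci = ci, n_dropped = sum(!ok))
}
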