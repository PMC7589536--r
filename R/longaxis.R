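#' World (mm) coordinates of mask voxels
#'
#' Applies the mask's affine to the integer grid indices.
#'
#' @param mask a \code{"voxel_mask"} (see \code{\link{gen_mask}} or
#'   \code{\link{read_voxel_mask}}).
#' @return matrix with columns x, y, z in mm.
#' @export
voxel_world <- function(mask) {
  aff <- attr(mask, "affine")
  ijk1 <- cbind(mask$i, mask$j, mask$k, 1)
  w <- ijk1 %*% t(aff)
  colnames(w) <- c("x", "y", "z", "one")
  w[, 1:3, drop = FALSE]
}

#' Read a probabilistic mask from a NIfTI volume
#'
#' Thresholds a probability image and returns the surviving voxels with the
#' volume's affine. Requires the RNifti package.
#'
#' @param path NIfTI file.
#' @param threshold probability threshold (voxels with value >= threshold
#'   are kept).
#' @param hemisphere label attached to the voxels (split laterally by the
#'   sign of world x when \code{"auto"}).
#' @return a \code{"voxel_mask"}.
#' @export
read_voxel_mask <- function(path, threshold = 0.5, hemisphere = "auto") {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required to read NIfTI masks")
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  idx <- which(arr >= threshold, arr.ind = TRUE)
  aff <- structure(RNifti::xform(img), class = "matrix")
  df <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L, k = idx[, 3] - 1L,
                   prob = arr[idx], hemi = hemisphere)
  m <- structure(df, affine = unclass(aff),
                 class = c("voxel_mask", "data.frame"))
  if (identical(hemisphere, "auto")) {
    w <- voxel_world(m)
    m$hemi <- ifelse(w[, 1] < 0, "L", "R")
  }
  m
}

#' Long-axis rotation angle from paired hemisphere masks
#'
#' Identifies the \code{n_extreme} most anteroinferior and posterosuperior
#' voxels of each hemisphere (by default scored along the direction
#' anterior-and-inferior, i.e. +y together with -z in mm space), takes the
#' centroid of each extreme set, computes the per-hemisphere slope of the
#' line connecting the centroids in the sagittal (y-z) plane, averages the
#' two slopes, and returns the clockwise angle of that average line relative
#' to the AC-PC axis (zero slope).
#'
#' @param maskL,maskR \code{"voxel_mask"} objects (one may be NULL).
#' @param n_extreme voxels per extreme set.
#' @param key direction in the (y, z) plane used to order voxels on the
#'   first pass (anteroinferior scored positive); default \code{c(1, -1)}.
#' @param refine number of refinement passes in which the scoring direction
#'   is re-aligned with the estimated axis; with 0 the anatomical key is
#'   used as-is. Refinement removes the corner bias the fixed key induces
#'   when it is misaligned with the true axis.
#' @return angle in degrees, clockwise from AC-PC, with attribute
#'   \code{"slopes"} (per hemisphere).
#' @export
long_axis_rotation <- function(maskL, maskR = NULL, n_extreme = 10,
                               key = c(1, -1), refine = 3) {
  masks <- Filter(Negate(is.null), list(maskL, maskR))
  one_pass <- function(k) {
    slopes <- vapply(masks, function(m) {
      w <- voxel_world(m)
      if (nrow(w) < 2 * n_extreme)
        stop("need at least ", 2 * n_extreme, " voxels per hemisphere")
      score <- w[, 2] * k[1] + w[, 3] * k[2]
      ai <- w[order(score, decreasing = TRUE)[seq_len(n_extreme)], ,
              drop = FALSE]
      ps <- w[order(score)[seq_len(n_extreme)], , drop = FALSE]
      dy <- mean(ai[, 2]) - mean(ps[, 2])
      dz <- mean(ai[, 3]) - mean(ps[, 3])
      if (abs(dy) < 1e-9) stop("degenerate mask: no anteroposterior extent")
      dz / dy
    }, 0)
    slopes
  }
  slopes <- one_pass(key)
  for (it in seq_len(refine)) {
    th <- atan(-mean(slopes))
    slopes <- one_pass(c(cos(th), -sin(th)))
  }
  ang <- atan(-mean(slopes)) * 180 / pi
  attr(ang, "slopes") <- slopes
  ang
}

#' Quantile bins along the rotated long axis
#'
#' Projects voxel coordinates onto the rotated axis and cuts them into
#' \code{n_bins} quantile bins of (approximately) equal voxel counts,
#' separately within each hemisphere; counts per bin differ by at most one.
#' Bin 1 is the most posterior(-superior), bin \code{n_bins} the most
#' anterior(-inferior).
#'
#' @param mask a \code{"voxel_mask"} (may contain both hemispheres).
#' @param angle_deg rotation angle from \code{\link{long_axis_rotation}}.
#' @param n_bins number of bins (default 12).
#' @return the mask data.frame with appended \code{axis_mm} (position along
#'   the rotated axis) and integer \code{bin}.
#' @export
quantile_bins <- function(mask, angle_deg, n_bins = 12) {
  w <- voxel_world(mask)
  theta <- angle_deg * pi / 180
  axis_mm <- w[, 2] * cos(theta) - w[, 3] * sin(theta)
  out <- as.data.frame(mask)
  out$axis_mm <- axis_mm
  out$bin <- NA_integer_
  for (h in unique(out$hemi)) {
    sel <- which(out$hemi == h)
    n <- length(sel)
    if (n < n_bins) stop("fewer voxels than bins in hemisphere ", h)
    sizes <- rep(n %/% n_bins, n_bins)
    extra <- n %% n_bins
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    ord <- sel[order(out$axis_mm[sel], sel)]
    out$bin[ord] <- rep(seq_len(n_bins), times = sizes)
  }
  attr(out, "affine") <- attr(mask, "affine")
  attr(out, "angle_deg") <- angle_deg
  class(out) <- c("voxel_mask", "data.frame")
  out
}

#' Bin-wise aggregation of a voxelwise statistic map
#'
#' @param statmap numeric vector of per-voxel statistics aligned with the
#'   rows of \code{bins}.
#' @param bins a \code{\link{quantile_bins}} result.
#' @param pool_hemispheres average over hemispheres (default) or keep them
#'   separate.
#' @return data.frame with \code{bin} (and \code{hemi} if not pooled) and
#'   \code{mean_stat}.
#' @export
binwise_stat <- function(statmap, bins, pool_hemispheres = TRUE) {
  stopifnot(length(statmap) == nrow(bins), !anyNA(bins$bin))
  if (pool_hemispheres) {
    agg <- stats::aggregate(list(mean_stat = statmap),
                            by = list(bin = bins$bin), FUN = mean)
    agg[order(agg$bin), , drop = FALSE]
  } else {
    agg <- stats::aggregate(list(mean_stat = statmap),
                            by = list(hemi = bins$hemi, bin = bins$bin),
                            FUN = mean)
    agg[order(agg$hemi, agg$bin), , drop = FALSE]
  }
}

#' Event-locked trial time courses with censoring
#'
#' Interpolates a 1 s-sampled activity series onto an evenly spaced grid
#' aligned to each event (linear interpolation; when events fall on grid
#' points this is the identity). Samples beyond the series support are
#' missing, and samples at or after the next trial's onset are censored to
#' missing, never imputed.
#'
#' @param series list with \code{time} (s) and \code{value} (as from
#'   \code{\link{gen_timecourses}}), or a data.frame with those columns.
#' @param events event onset times, s.
#' @param window c(lo, hi) offsets around each event, s (default feedback
#'   window -1 to +10 s).
#' @param next_onsets optional vector, one per event: censoring boundary
#'   (e.g. next trial onset).
#' @param step_s grid step, s.
#' @return matrix of trials x time offsets (dimnames give offsets in s).
#' @export
timelock_trials <- function(series, events, window = c(-1, 10),
                            next_onsets = NULL, step_s = 1) {
  offs <- seq(window[1], window[2], by = step_s)
  out <- matrix(NA_real_, length(events), length(offs),
                dimnames = list(NULL, offs))
  for (i in seq_along(events)) {
    tt <- events[i] + offs
    ok <- tt >= min(series$time) & tt <= max(series$time)
    if (any(ok))
      out[i, ok] <- stats::approx(series$time, series$value,
                                  xout = tt[ok])$y
    if (!is.null(next_onsets) && is.finite(next_onsets[i]))
      out[i, tt >= next_onsets[i]] <- NA_real_
  }
  out
}

#' Per-(time, bin) regression of event-locked activity with FDR control
#'
#' Descriptive companion to \code{\link{timelock_trials}}: regresses
#' trial-wise activity at every time offset on a trial-level predictor and
#' adjusts the p-values across all models with the Benjamini-Yekutieli
#' procedure (valid under arbitrary dependence) at rate \code{q}.
#'
#' @param tc matrix from \code{\link{timelock_trials}}.
#' @param predictor numeric vector, one value per trial.
#' @param q false discovery rate.
#' @return data.frame: \code{time_s}, \code{estimate}, \code{se}, \code{p},
#'   \code{p_adj}, \code{significant}.
#' @export
timecourse_regression <- function(tc, predictor, q = 0.05) {
  stopifnot(nrow(tc) == length(predictor))
  res <- lapply(colnames(tc), function(cn) {
    y <- tc[, cn]
    ok <- !is.na(y)
    if (sum(ok) < 3 || stats::sd(predictor[ok]) == 0)
      return(data.frame(time_s = as.numeric(cn), estimate = NA, se = NA,
                        p = NA))
    f <- stats::lm(y[ok] ~ predictor[ok])
    s <- summary(f)$coefficients
    data.frame(time_s = as.numeric(cn), estimate = s[2, 1], se = s[2, 2],
               p = s[2, 4])
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BY")
  out$significant <- !is.na(out$p_adj) & out$p_adj < q
  out
}
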