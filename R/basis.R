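#' Gaussian temporal basis over the decision interval
#'
#' Value over the continuous 4-s response interval is approximated by a set of
#' unnormalized Gaussian radial basis functions
#' \deqn{\phi_b(t) = \exp[-(t - \mu_b)^2 / (2 s_b^2)],}
#' with centers \eqn{\mu_b} spaced evenly across the closed interval and a
#' shared width \eqn{s_b^2}. The width is solved numerically so that the
#' distributional overlap of adjacent elements (the overlap coefficient:
#' integral of the pointwise minimum of the two normalized densities) equals
#' \code{overlap_target}, 0.5 by default.
#'
#' @param n_basis number of elements (default 24).
#' @param interval_ms decision interval length in ms (default 4000).
#' @param overlap_target desired adjacent-element overlap coefficient in (0,1).
#' @param n_grid number of evaluation bins; value functions and the softmax
#'   choice rule operate on the centers of \code{n_grid} bins of width
#'   \code{interval_ms / n_grid} (default 40 bins of 100 ms).
#' @param gen_width_sq generalization width \eqn{s_g^2} used by
#'   \code{\link{eligibility}}; defaults to the solved \eqn{s_b^2}.
#' @param edge_renormalize if \code{TRUE}, each element is rescaled so that its
#'   area inside \code{[0, interval_ms]} equals the area of an untruncated
#'   element, compensating mass lost by edge elements. Off by default:
#'   elements are plain Gaussians evaluated on the grid.
#' @return an object of class \code{"temporal_basis"}: \code{n_basis},
#'   \code{centers}, \code{width_sq}, \code{gen_width_sq}, \code{interval_ms},
#'   \code{grid} (bin-center times), and \code{phi}, the
#'   \code{n_basis x n_grid} matrix of basis values at the grid.
#' @examples
#' b <- build_basis()
#' adjacent_overlap(b)  # ~0.5
#' @export
build_basis <- function(n_basis = 24, interval_ms = 4000,
                        overlap_target = 0.5, n_grid = 40,
                        gen_width_sq = NULL, edge_renormalize = FALSE) {
  stopifnot(n_basis >= 2, n_grid >= 2, interval_ms > 0)
  n_basis <- as.integer(n_basis)
  n_grid <- as.integer(n_grid)
  if (overlap_target <= 0 || overlap_target >= 1)
    stop("overlap_target must lie in (0, 1)")
  centers <- seq(0, interval_ms, length.out = n_basis)
  d <- centers[2] - centers[1]
  # overlap of two equal-width normal densities distance d apart is
  # 2*pnorm(-d/(2s)); solve for s by root finding
  f <- function(s) 2 * stats::pnorm(-d / (2 * s)) - overlap_target
  s <- stats::uniroot(f, lower = d * 1e-4, upper = d * 1e4, tol = 1e-12)$root
  width_sq <- s^2
  if (is.null(gen_width_sq)) gen_width_sq <- width_sq
  stopifnot(gen_width_sq > 0)
  bin_ms <- interval_ms / n_grid
  grid <- (seq_len(n_grid) - 0.5) * bin_ms
  phi <- outer(centers, grid, function(mu, t) exp(-(t - mu)^2 / (2 * width_sq)))
  if (edge_renormalize) {
    mass_in <- stats::pnorm(interval_ms, centers, s) - stats::pnorm(0, centers, s)
    phi <- phi / mass_in
  }
  structure(list(n_basis = n_basis, centers = centers, width_sq = width_sq,
                 gen_width_sq = gen_width_sq, interval_ms = interval_ms,
                 grid = grid, bin_ms = bin_ms, n_grid = n_grid, phi = phi,
                 edge_renormalize = edge_renormalize),
            class = "temporal_basis")
}

#' @exportS3Method base::print
print.temporal_basis <- function(x, ...) {
  cat(sprintf("temporal basis: %d Gaussian elements on [0, %d] ms, sd %.1f ms\n",
              x$n_basis, x$interval_ms, sqrt(x$width_sq)))
  cat(sprintf("  adjacent overlap coefficient %.3f; %d-bin choice grid\n",
              adjacent_overlap(x), x$n_grid))
  invisible(x)
}

#' Overlap coefficient between adjacent basis elements
#'
#' Integral of the pointwise minimum of the normalized densities of two
#' neighboring elements; equals \code{2*pnorm(-d/(2*s))} for equal widths.
#'
#' @param basis a \code{\link{build_basis}} object.
#' @return scalar overlap coefficient in (0, 1).
#' @export
adjacent_overlap <- function(basis) {
  d <- basis$centers[2] - basis$centers[1]
  2 * stats::pnorm(-d / (2 * sqrt(basis$width_sq)))
}

#' Eligibility of each basis element for a given response time
#'
#' Temporal generalization: feedback at RT \eqn{t} spreads to nearby times via
#' a normalized Gaussian kernel of variance \eqn{s_g^2} centered on \eqn{t}.
#' Each element's eligibility is the area under the product of that kernel with
#' the element's receptive field, taken over the decision interval, and then
#' divided by the perfect-overlap value so that an RT exactly at an element's
#' center with \eqn{s_g^2 = s_b^2} yields eligibility 1.
#'
#' The integral has a closed form (a Gaussian product identity times a normal
#' CDF difference for the interval truncation), used here; numerical
#' quadrature agrees to well below 1e-8.
#'
#' @param basis a \code{\link{build_basis}} object.
#' @param rt_ms response time in ms within the interval.
#' @param truncate integrate over \code{[0, interval_ms]} (default) rather
#'   than the whole real line.
#' @return numeric vector of length \code{n_basis}, each entry in [0, 1].
#' @export
eligibility <- function(basis, rt_ms, truncate = TRUE) {
  stopifnot(inherits(basis, "temporal_basis"), length(rt_ms) == 1L)
  if (rt_ms < 0 || rt_ms > basis$interval_ms)
    stop("rt_ms outside the decision interval")
  sb2 <- basis$width_sq
  sg2 <- basis$gen_width_sq
  mu <- basis$centers
  tot <- sg2 + sb2
  raw <- sqrt(sb2 / tot) * exp(-(rt_ms - mu)^2 / (2 * tot))
  if (truncate) {
    v <- sg2 * sb2 / tot
    m <- (rt_ms * sb2 + mu * sg2) / tot
    raw <- raw * (stats::pnorm((basis$interval_ms - m) / sqrt(v)) -
                    stats::pnorm(-m / sqrt(v)))
  }
  # perfect-overlap (rt at center, untruncated) reference value
  raw / sqrt(sb2 / tot)
}

#' Eligibility matrix over the choice grid
#'
#' Stacks \code{\link{eligibility}} vectors for each grid bin center into an
#' \code{n_basis x n_grid} matrix; used by the fast likelihood and simulation
#' routines, which address it by observed response bin.
#'
#' @inheritParams eligibility
#' @return matrix of eligibilities, elements by grid bins.
#' @export
eligibility_matrix <- function(basis, truncate = TRUE) {
  vapply(basis$grid, function(t) eligibility(basis, t, truncate),
         numeric(basis$n_basis))
}

#' Evaluate the value function implied by a weight vector
#'
#' The temporally varying expected value is the product of the element weights
#' with the basis: \eqn{V = w \phi}, evaluated at the grid bin centers.
#'
#' @param weights numeric vector, one weight per basis element, in points.
#' @param basis a \code{\link{build_basis}} object.
#' @return object of class \code{"value_function"}: \code{grid} (ms) and
#'   \code{values} (points).
#' @export
eval_value <- function(weights, basis) {
  stopifnot(inherits(basis, "temporal_basis"))
  if (length(weights) != basis$n_basis)
    stop("weights length must equal n_basis")
  structure(list(grid = basis$grid,
                 values = drop(crossprod(weights, basis$phi))),
            class = "value_function")
}

#' Response time of the global value maximum
#'
#' Returns the grid time with the highest value; ties are broken in favor of
#' the earliest time, so a flat (e.g., all-zero) function returns the first
#' grid point.
#'
#' @param vf a \code{\link{eval_value}} result (or any list with \code{grid}
#'   and \code{values}).
#' @return time in ms.
#' @export
rt_vmax <- function(vf) {
  vf$grid[which.max(vf$values)]
}

#' Softmax choice over the response grid
#'
#' Samples a response bin with probability proportional to
#' \eqn{\exp(V_j/\beta)}. Higher temperatures \eqn{\beta} flatten the choice
#' distribution toward uniform.
#'
#' @param vf value (or decision) function on the grid.
#' @param beta softmax temperature, > 0.
#' @return a list: \code{bin} (1-based index) and \code{rt_ms} (bin center).
#' @export
choose_rt <- function(vf, beta) {
  p <- softmax_prob(vf$values, beta)
  bin <- sample.int(length(p), 1L, prob = p)
  list(bin = bin, rt_ms = vf$grid[bin])
}

#' Softmax probabilities (internal helper, exported for diagnostics)
#' @param values numeric vector of values.
#' @param beta temperature > 0.
#' @return probability vector summing to 1.
#' @export
softmax_prob <- function(values, beta) {
  if (beta <= 0) stop("beta must be positive")
  z <- values / beta
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
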