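#' Dominant quartet topology probability for a branch length
#'
#' Under the multi-species coalescent, an internal branch of length `d`
#' coalescent units induces the matching (dominant) quartet topology in a
#' gene tree with probability `theta = 1 - (2/3) exp(-d)`; each alternative
#' has probability `exp(-d) / 3`.
#'
#' @param d Branch length(s) in coalescent units, non-negative.
#' @return Probability in [1/3, 1).
#' @export
theta_from_length <- function(d) {
  if (any(d < 0)) stop("branch length must be non-negative", call. = FALSE)
  1 - (2 / 3) * exp(-d)
}

#' Branch length from the dominant quartet topology probability
#'
#' Inverse of [theta_from_length()]: `d = -log(3/2 (1 - theta))`. Values of
#' `theta` below 1/3 (possible for empirical frequencies) are clamped to
#' length 0 with a warning; `theta = 1` maps to `Inf`.
#'
#' @param theta Probability in [1/3, 1] (values in [0, 1/3) clamp to 0).
#' @return Branch length(s) in coalescent units.
#' @export
length_from_theta <- function(theta) {
  if (any(theta > 1)) stop("theta must be <= 1", call. = FALSE)
  if (any(theta < 0)) stop("theta must be >= 0", call. = FALSE)
  if (any(theta < 1 / 3)) {
    warning("theta below 1/3 clamped to branch length 0", call. = FALSE)
    theta <- pmax(theta, 1 / 3)
  }
  -log(1.5 * (1 - theta))
}

#' Yule-process prior density of the dominant topology probability
#'
#' When species-tree branch lengths are exponential with rate `lambda` (the
#' Yule speciation process in coalescent-unit time), the implied prior
#' density of the dominant quartet probability t on [1/3, 1] is
#' `lambda * (3 (1 - t) / 2)^(2 lambda - 1)`. Each of the three topologies
#' is equally likely a priori, so this density integrates to 1/3;
#' `lambda = 1/2` gives the flat density 1/2.
#'
#' @param t Probability value(s) in [1/3, 1].
#' @param lambda Positive Yule rate; default 1/2.
#' @return Density value(s).
#' @export
yule_prior_density <- function(t, lambda = 0.5) {
  stopifnot(lambda > 0)
  if (any(t < 1 / 3 | t > 1)) stop("t must lie in [1/3, 1]", call. = FALSE)
  lambda * (3 * (1 - t) / 2)^(2 * lambda - 1)
}

#' Log of the posterior weight function h
#'
#' `h(x) = B(x + 1, n - x + 2 lambda) (1 - I_{1/3}(x + 1, n - x + 2 lambda))`
#' where B is the beta function and I the regularized incomplete beta.
#' Evaluated in log space, with the complement computed as
#' `I_{2/3}(n - x + 2 lambda, x + 1)` to avoid catastrophic cancellation
#' when the incomplete beta is near 1 (large x). Non-integer x is supported:
#' averaged quartet frequencies are generally fractional.
#'
#' @param x Quartet frequency, `0 <= x <= n` (vectorized).
#' @param n Effective number of genes (positive real).
#' @param lambda Yule prior rate.
#' @return `log h(x)`, finite for all valid inputs.
#' @export
log_h <- function(x, n, lambda = 0.5) {
  if (any(x > n + 1e-9)) stop("x must not exceed n", call. = FALSE)
  if (any(x < 0)) stop("x must be non-negative", call. = FALSE)
  x <- pmin(x, n)
  a <- x + 1
  b <- n - x + 2 * lambda
  lbeta(a, b) + stats::pbeta(2 / 3, b, a, log.p = TRUE)
}

#' Local posterior probabilities of the three resolutions of a branch
#'
#' Closed-form local posterior probability that each of the three possible
#' resolutions around a branch is the true one, given averaged quartet
#' frequencies `z = (z1, z2, z3)` out of `n` effective genes, under the Yule
#' prior with rate `lambda`:
#' `pp_j` proportional to `2^{z_j} h(z_j)`, computed entirely in log space.
#' Component 1 corresponds to the resolution being scored (the species-tree
#' branch).
#'
#' @param z Numeric length-3 vector of quartet frequencies, each in [0, n].
#' @param n Effective number of genes; `n <= 0` yields a flagged no-signal
#'   result of `c(NA, NA, NA)`.
#' @param lambda Yule prior rate (default 1/2, the flat prior).
#' @return Numeric length-3 vector summing to 1 (or all `NA`).
#' @export
local_pp <- function(z, n, lambda = 0.5) {
  stopifnot(length(z) == 3L, lambda > 0)
  if (is.na(n) || n <= 0) return(c(NA_real_, NA_real_, NA_real_))
  if (any(z < 0)) stop("quartet frequencies must be non-negative", call. = FALSE)
  if (sum(z) > n * (1 + 1e-9) + 1e-9) {
    stop("z1 + z2 + z3 exceeds n", call. = FALSE)
  }
  lw <- z * log(2) + log_h(z, n, lambda)
  w <- exp(lw - max(lw))
  unname(w / sum(w))
}

#' Local posterior probabilities by numeric integration (oracle)
#'
#' Independent evaluation of the local posterior: for each topology j the
#' unnormalized posterior mass is the integral over t in [1/3, 1] of
#' `t^{z_j} ((1 - t)/2)^{n - z_j}` times the Yule prior density, computed by
#' adaptive quadrature on a common log scale and normalized across the three
#' topologies. Agrees with the closed form [local_pp()] to ~1e-6.
#'
#' @inheritParams local_pp
#' @return Numeric length-3 vector summing to 1 (or all `NA`).
#' @export
local_pp_numeric <- function(z, n, lambda = 0.5) {
  stopifnot(length(z) == 3L, lambda > 0)
  if (is.na(n) || n <= 0) return(c(NA_real_, NA_real_, NA_real_))
  loglik <- function(t, zj) zj * log(t) + (n - zj) * log((1 - t) / 2)
  grid <- seq(1 / 3 + 1e-12, 1 - 1e-12, length.out = 512)
  shift <- max(vapply(z, function(zj) max(loglik(grid, zj)), numeric(1)))
  mass <- vapply(z, function(zj) {
    stats::integrate(function(t) exp(loglik(t, zj) - shift) * yule_prior_density(t, lambda),
                     lower = 1 / 3, upper = 1,
                     rel.tol = 1e-10, abs.tol = 0, subdivisions = 400L)$value
  }, numeric(1))
  unname(mass / sum(mass))
}

#' ML and MAP branch length in coalescent units
#'
#' Given the dominant quartet frequency `z1` out of `n` genes, the
#' maximum-likelihood length is `-log(3/2 (1 - z1/n))` when `z1 >= n/3` and
#' 0 otherwise; the maximum-a-posteriori length under the Yule prior
#' replaces `n` by `n + 2 lambda`. `z1 = n` gives an infinite ML estimate,
#' which is reported capped (default 10 coalescent units) with a flag so
#' that downstream newick output stays finite.
#'
#' @param z1 Dominant-topology quartet frequency, `0 <= z1 <= n`.
#' @param n Effective number of genes (positive real).
#' @param lambda Yule prior rate.
#' @param cap Finite value substituted for an infinite estimate; use
#'   `cap = Inf` to disable.
#' @return A list with `ml`, `map` (non-negative, possibly capped) and
#'   `capped` (logical).
#' @export
branch_length_estimates <- function(z1, n, lambda = 0.5, cap = 10) {
  if (is.na(n) || n <= 0) return(list(ml = NA_real_, map = NA_real_, capped = FALSE))
  stopifnot(z1 >= 0, z1 <= n * (1 + 1e-12))
  z1 <- min(z1, n)
  ml <- if (z1 <= n / 3) 0 else -log(1.5 * (1 - z1 / n))
  nmap <- n + 2 * lambda
  map <- if (z1 <= nmap / 3) 0 else -log(1.5 * (1 - z1 / nmap))
  capped <- is.infinite(ml) || is.infinite(map) || ml > cap || map > cap
  list(ml = min(ml, cap), map = min(map, cap), capped = capped)
}
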