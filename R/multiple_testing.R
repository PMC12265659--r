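#' Discreteness correction for sampled OU excursion probabilities
#'
#' The excursion approximation for the maximum of an OU process holds for the
#' continuous-path process; when the process is only observed on a grid, the
#' crossing intensity is damped by a factor \code{nu(y)} with
#' \code{y = z * sqrt(2 * theta * delta)}. The two-term rational
#' approximation of Siegmund is used:
#' \deqn{\nu(y) \approx \frac{(2/y)(\Phi(y/2) - 1/2)}{(y/2)\Phi(y/2) + \phi(y/2)}}
#' with \code{nu(0) = 1} by continuity. An infinite-series form
#' \code{nu(y) = (2/y^2) exp(-2 sum_k Phi(-y sqrt(k)/2)/k)} exists and serves
#' as the independent oracle in the test suite.
#'
#' @param y non-negative argument (vectorized).
#' @return Value in (0, 1].
#' @export
nu <- function(y) {
  if (any(y < 0)) stop("nu is defined for y >= 0")
  out <- numeric(length(y))
  z <- y == 0
  out[z] <- 1
  yy <- y[!z]
  if (length(yy)) {
    num <- (2 / yy) * (pnorm(yy / 2) - 0.5)
    den <- (yy / 2) * pnorm(yy / 2) + dnorm(yy / 2)
    out[!z] <- num / den
  }
  out
}

#' Family-wise exceedance probability of the scan maximum
#'
#' Discrete-spacing excursion approximation for the probability that the
#' maximum of the standardized difference track exceeds z under the null OU
#' model:
#' \deqn{P(\max_m Z_m \ge z) \approx 1 - \exp\{-C(1 - \Phi(z))
#'   - \theta L z \phi(z) \nu(z\sqrt{2\theta\delta})\}}
#' for genome length L Morgans, C chromosomes, decay theta per Morgan and test
#' spacing delta Morgans. With theta = 0 this reduces to the chromosome
#' end-point term alone.
#'
#' @param z critical value(s), z > 0.
#' @param theta decay parameter per Morgan, theta >= 0.
#' @param layout a \code{genome_layout}.
#' @return Approximate exceedance probability in (0, 1).
#' @export
fwer_approx <- function(z, theta, layout) {
  if (any(z <= 0)) stop("z must be positive")
  if (theta < 0) stop("theta must be >= 0")
  stopifnot(inherits(layout, "genome_layout"))
  expo <- layout$C * pnorm(z, lower.tail = FALSE) +
    theta * layout$L * z * dnorm(z) * nu(z * sqrt(2 * theta * layout$delta))
  1 - exp(-expo)
}

threshold_result <- function(alpha, alpha_star, z_star, method, theta = NA_real_,
                             rho = NA_real_, layout = NULL, n_sims = NA_integer_,
                             seed = NA_integer_) {
  structure(list(alpha = alpha, alpha_star = alpha_star, z_star = z_star,
                 method = method, theta = theta, rho = rho, layout = layout,
                 n_sims = n_sims, seed = seed),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("%s threshold: alpha = %g, alpha* = %.6g, z* = %.4f\n",
              x$method, x$alpha, x$alpha_star, x$z_star))
  invisible(x)
}

#' Discrete-spacing analytic genome-wide threshold
#'
#' Solves \code{fwer_approx(z, theta, layout) = alpha} for z by bracketed
#' root-finding on \[1, 10\] (expanded to \[0.1, 20\] if the root is not
#' bracketed), then reports the per-test significance level
#' \code{alpha_star = 1 - Phi(z_star)}.
#'
#' @param alpha family-wise error level in (0, 1).
#' @param theta decay parameter per Morgan, theta > 0.
#' @param layout a \code{genome_layout}.
#' @return A \code{threshold_result}.
#' @export
analytic_threshold <- function(alpha, theta, layout) {
  stopifnot(alpha > 0, alpha < 1, theta > 0)
  f <- function(z) fwer_approx(z, theta, layout) - alpha
  bracket <- c(1, 10)
  if (f(bracket[1]) * f(bracket[2]) > 0) bracket <- c(0.1, 20)
  if (f(bracket[1]) * f(bracket[2]) > 0)
    stop("no sign change in root bracket [0.1, 20]; review alpha/theta/layout")
  root <- uniroot(f, bracket, tol = 1e-14)
  z_star <- root$root
  threshold_result(alpha, pnorm(z_star, lower.tail = FALSE), z_star,
                   "analytic", theta = theta, layout = layout)
}

#' Bonferroni threshold
#'
#' @param alpha family-wise level.
#' @param M number of tests.
#' @return A \code{threshold_result} with \code{alpha_star = alpha / M}.
#' @export
bonferroni <- function(alpha, M) {
  stopifnot(alpha > 0, alpha < 1, M >= 1)
  alpha_star <- alpha / M
  threshold_result(alpha, alpha_star, qnorm(alpha_star, lower.tail = FALSE),
                   "bonferroni")
}

#' Simulation-based genome-wide threshold
#'
#' Simulates \code{n_sims} independent null genomes as cross-correlated
#' two-dimensional OU processes, forms the restandardized difference track of
#' each (exactly as the scan does), and returns the empirical (1 - alpha)
#' quantile of the genome-wide maxima as the critical value. The quantile is
#' the conservative upper order statistic \code{ceiling((1 - alpha) * n_sims)}
#' and never interpolates downward.
#'
#' @param alpha family-wise level.
#' @param theta1,theta0 decay parameters of the case and control tracks.
#' @param rho case-control cross-correlation in \[-1, 1\].
#' @param layout a \code{genome_layout}.
#' @param n_sims number of simulated genomes (>= 100; default 1000).
#' @param seed integer seed; the same seed yields the identical threshold.
#' @param two_sided use maxima of \code{|Z|} instead of Z.
#' @return A \code{threshold_result} carrying the simulated \code{maxima}
#'   as an attribute.
#' @export
simulation_threshold <- function(alpha, theta1, theta0 = theta1, rho = 0,
                                 layout, n_sims = 1000L, seed = 1L,
                                 two_sided = FALSE) {
  stopifnot(alpha > 0, alpha < 1, n_sims >= 100L)
  if (!is.finite(rho) || abs(rho) > 1) stop("rho must be in [-1, 1]")
  maxima <- with_seed(seed, {
    vapply(seq_len(n_sims), function(i) {
      pair <- simulate_ou_2d(theta1, theta0, rho, layout, seed = NULL)
      max_difference_statistic(pair$path1, pair$path0, two_sided = two_sided)
    }, numeric(1))
  })
  k <- ceiling((1 - alpha) * n_sims)
  z_star <- sort(maxima)[k]
  res <- threshold_result(alpha, pnorm(z_star, lower.tail = FALSE), z_star,
                          if (two_sided) "simulation-two-sided" else "simulation",
                          theta = c(theta1 = theta1, theta0 = theta0), rho = rho,
                          layout = layout, n_sims = as.integer(n_sims),
                          seed = as.integer(seed))
  attr(res, "maxima") <- maxima
  res
}

#' Two-sided genome-wide threshold
#'
#' Extends the one-sided scan to two tails. Two constructions are offered:
#' \code{method = "simulation"} (default) takes the (1 - alpha) quantile of
#' the simulated maxima of \code{|Z|}; \code{method = "analytic"} doubles both
#' exponent terms of the excursion approximation (both tails contribute) and
#' solves for z. For a symmetric process the two-sided level-alpha threshold
#' is close to the one-sided level-alpha/2 threshold.
#'
#' @param alpha family-wise level.
#' @param theta decay parameter per Morgan.
#' @param layout a \code{genome_layout}.
#' @param method "simulation" or "analytic".
#' @param rho,n_sims,seed passed to \code{\link{simulation_threshold}} when
#'   simulating.
#' @return A \code{threshold_result}.
#' @export
two_sided_threshold <- function(alpha, theta, layout,
                                method = c("simulation", "analytic"),
                                rho = 0, n_sims = 1000L, seed = 1L) {
  method <- match.arg(method)
  if (method == "simulation") {
    return(simulation_threshold(alpha, theta, theta, rho, layout,
                                n_sims = n_sims, seed = seed, two_sided = TRUE))
  }
  stopifnot(alpha > 0, alpha < 1, theta > 0)
  f <- function(z) {
    expo <- 2 * layout$C * pnorm(z, lower.tail = FALSE) +
      2 * theta * layout$L * z * dnorm(z) * nu(z * sqrt(2 * theta * layout$delta))
    (1 - exp(-expo)) - alpha
  }
  bracket <- c(1, 10)
  if (f(bracket[1]) * f(bracket[2]) > 0) bracket <- c(0.1, 20)
  if (f(bracket[1]) * f(bracket[2]) > 0)
    stop("no sign change in root bracket [0.1, 20]; review alpha/theta/layout")
  z_star <- uniroot(f, bracket, tol = 1e-14)$root
  threshold_result(alpha, pnorm(z_star, lower.tail = FALSE), z_star,
                   "analytic-two-sided", theta = theta, layout = layout)
}
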