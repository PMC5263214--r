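#' Haldane mapping function
#'
#' Converts a recombination frequency into a map distance under the
#' assumption of no crossover interference, \eqn{d = -0.5 \log(1 - 2\rho)}.
#' Distances are returned in Morgans; multiply by 100 for centiMorgans.
#'
#' @param rho Recombination frequency (or frequencies), in `[0, 0.5)`.
#' @return Map distance(s) in Morgans, `>= 0`.
#' @seealso [haldane_inverse()]
#' @examples
#' haldane(0.25)            # 0.3466 M = 34.66 cM
#' haldane_inverse(haldane(0.1))
#' @export
haldane <- function(rho) {
  if (any(rho < 0 | rho >= 0.5, na.rm = TRUE))
    stop("recombination frequency must lie in [0, 0.5)")
  -0.5 * log(1 - 2 * rho)
}

#' Inverse Haldane mapping function
#'
#' @param d Map distance(s) in Morgans, `>= 0`.
#' @return Recombination frequency in `[0, 0.5)`.
#' @export
haldane_inverse <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("map distance must be non-negative")
  (1 - exp(-2 * d)) / 2
}

#' Parameterize an ordered marker triplet
#'
#' Describes an ordered triplet of marker loci M1--M2--M3 on a chromosome of
#' a doubled-haploid (or RIL) population: the true recombination frequencies
#' of the two adjacent intervals and a locus-specific genotyping error rate
#' for each marker.  The non-adjacent recombination frequency follows from
#' the no-interference assumption:
#' \eqn{\theta_{13} = \theta_{12} + \theta_{23} - 2\theta_{12}\theta_{23}}.
#'
#' @param theta12,theta23 True recombination frequencies of the adjacent
#'   intervals, each in `(0, 0.5)`.
#' @param eps1,eps2,eps3 Genotyping error rates of the three loci: the
#'   probability that the observed allele is the opposite of the true one.
#'   Each in `[0, 0.5)`.
#' @return An object of class `triplet_model`.
#' @examples
#' m <- triplet_model(0.1, 0.2, eps2 = 0.05)
#' m$theta13
#' @export
triplet_model <- function(theta12, theta23, eps1 = 0, eps2 = 0, eps3 = 0) {
  stopifnot(length(theta12) == 1, length(theta23) == 1)
  if (theta12 <= 0 || theta12 >= 0.5 || theta23 <= 0 || theta23 >= 0.5)
    stop("theta12 and theta23 must lie in (0, 0.5)")
  eps <- c(eps1, eps2, eps3)
  if (any(eps < 0 | eps >= 0.5))
    stop("error rates must lie in [0, 0.5)")
  structure(
    list(theta12 = theta12, theta23 = theta23,
         theta13 = theta12 + theta23 - 2 * theta12 * theta23,
         eps = eps),
    class = "triplet_model")
}

#' @export
print.triplet_model <- function(x, ...) {
  cat("Ordered marker triplet M1-M2-M3\n")
  cat(sprintf("  theta12 = %.4g, theta23 = %.4g (theta13 = %.4g)\n",
              x$theta12, x$theta23, x$theta13))
  cat(sprintf("  error rates: %.4g, %.4g, %.4g\n",
              x$eps[1], x$eps[2], x$eps[3]))
  invisible(x)
}

#' Genotypic (phenotype) frequencies of an ordered marker triplet
#'
#' Exact joint probabilities of the eight observable score patterns
#' `(m1, m2, m3)` in `{-1, +1}^3` for a doubled-haploid triplet.  The
#' error-free transmission chain (first allele -1/+1 with probability 0.5,
#' each subsequent locus flipping with the interval recombination frequency)
#' is composed with an independent per-locus error channel that flips the
#' observed score with the locus error rate.
#'
#' @param model A [triplet_model()].
#' @return A numeric vector of length 8 with names like `"-1,-1,+1"`, of
#'   class `triplet_distribution`; attribute `states` holds the 8 x 3 score
#'   matrix.  Probabilities are non-negative, sum to one, and are invariant
#'   under a global sign flip of all three scores.
#' @examples
#' d <- triplet_distribution(triplet_model(0.1, 0.2))
#' d[["-1,-1,-1"]]   # 0.36
#' sum(d)
#' @export
triplet_distribution <- function(model) {
  stopifnot(inherits(model, "triplet_model"))
  states <- as.matrix(expand.grid(m1 = c(-1, 1), m2 = c(-1, 1),
                                  m3 = c(-1, 1)))[, 1:3]
  # true-chain probabilities
  chain_prob <- function(g) {
    0.5 *
      (if (g[2] == g[1]) 1 - model$theta12 else model$theta12) *
      (if (g[3] == g[2]) 1 - model$theta23 else model$theta23)
  }
  ptrue <- apply(states, 1, chain_prob)
  # flip channel: P(observed | true) factorizes over loci
  p <- numeric(8)
  for (o in 1:8) {
    for (t in 1:8) {
      flip <- states[o, ] != states[t, ]
      p[o] <- p[o] + ptrue[t] *
        prod(ifelse(flip, model$eps, 1 - model$eps))
    }
  }
  names(p) <- apply(states, 1, function(s)
    paste(ifelse(s > 0, "+1", "-1"), collapse = ","))
  structure(p, states = states, class = "triplet_distribution")
}

#' Expected marker-pair correlation under genotyping error
#'
#' For markers scored -1/+1 the pairwise correlation equals
#' \eqn{E[M_i M_j]}, and genotyping error attenuates it multiplicatively:
#' \eqn{r = (1 - 2\theta)(1 - 2\varepsilon_i)(1 - 2\varepsilon_j)}.
#'
#' @param theta True recombination frequency between the two loci, `(0, 0.5)`.
#' @param eps_i,eps_j Genotyping error rates of the two loci, `[0, 0.5)`.
#' @return Expected correlation, in `(-1, 1)`.
#' @examples
#' expected_correlation(0.1)             # 0.8
#' expected_correlation(0.1, 0.1, 0)     # 0.64
#' @export
expected_correlation <- function(theta, eps_i = 0, eps_j = 0) {
  if (any(theta <= 0 | theta >= 0.5))
    stop("theta must lie in (0, 0.5)")
  if (any(c(eps_i, eps_j) < 0 | c(eps_i, eps_j) >= 0.5))
    stop("error rates must lie in [0, 0.5)")
  (1 - 2 * theta) * (1 - 2 * eps_i) * (1 - 2 * eps_j)
}

#' Expected observed recombination frequency under genotyping error
#'
#' Genotyping errors inflate the observed recombination frequency between a
#' pair of loci: with combined error \eqn{e = \varepsilon_i + \varepsilon_j
#' - 2\varepsilon_i\varepsilon_j} (exactly one of the two scores flipped),
#' \eqn{\rho = \theta(1 - e) + (1 - \theta)e}.
#'
#' @inheritParams expected_correlation
#' @return Expected observed recombination frequency, in `(0, 0.5)`.
#' @examples
#' expected_observed_rf(0.1, 0.05, 0)     # 0.14
#' expected_observed_rf(0.1, 0.05, 0.05)  # 0.176
#' @export
expected_observed_rf <- function(theta, eps_i = 0, eps_j = 0) {
  if (any(theta <= 0 | theta >= 0.5))
    stop("theta must lie in (0, 0.5)")
  if (any(c(eps_i, eps_j) < 0 | c(eps_i, eps_j) >= 0.5))
    stop("error rates must lie in [0, 0.5)")
  e <- eps_i + eps_j - 2 * eps_i * eps_j
  theta * (1 - e) + (1 - theta) * e
}

#' First-order partial correlation
#'
#' Correlation between two variables after removing the linear effect of a
#' third: \eqn{\rho_{ij|k} = (r_{ij} - r_{ik} r_{jk}) /
#' (\sqrt{1 - r_{ik}^2}\,\sqrt{1 - r_{jk}^2})}.  In a marker chain without
#' genotyping error the partial correlation of two non-adjacent markers
#' given the intervening marker is exactly zero, which is the basis for
#' skeleton estimation.
#'
#' @param r_ij,r_ik,r_jk Pairwise correlations; conditioning correlations
#'   must satisfy `|r| < 1`.
#' @return Partial correlation in `[-1, 1]`.
#' @examples
#' partial_correlation(0.48, 0.8, 0.6)   # 0: non-adjacent pair, clean chain
#' @export
partial_correlation <- function(r_ij, r_ik, r_jk) {
  if (any(abs(c(r_ik, r_jk)) >= 1))
    stop("degenerate conditioning: |r_ik| or |r_jk| equals 1")
  (r_ij - r_ik * r_jk) / (sqrt(1 - r_ik^2) * sqrt(1 - r_jk^2))
}

#' Theoretical nearest-neighbour stress of the middle marker
#'
#' N.N.Stress of M2 given its flanks is the excess of the summed flanking
#' Haldane distances over the distance between the flanks,
#' \eqn{d_{12} + d_{23} - d_{13}}, computed from the *observed*
#' recombination frequencies.  In closed form it depends only on the middle
#' marker's error rate: \eqn{-\log(1 - 2\varepsilon_2)}, and vanishes when
#' M2 is error-free regardless of the flanking error rates.
#'
#' @param model A [triplet_model()].
#' @return Stress in Morgans (`>= 0`); multiply by 100 for cM.
#' @examples
#' theoretical_nn_stress(triplet_model(0.1, 0.2, eps2 = 0.05))  # -log(0.9)
#' @export
theoretical_nn_stress <- function(model) {
  stopifnot(inherits(model, "triplet_model"))
  e <- model$eps
  rho12 <- expected_observed_rf(model$theta12, e[1], e[2])
  rho23 <- expected_observed_rf(model$theta23, e[2], e[3])
  rho13 <- expected_observed_rf(model$theta13, e[1], e[3])
  haldane(rho12) + haldane(rho23) - haldane(rho13)
}
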