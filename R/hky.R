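#' Substitution model parameters for one partition
#'
#' HKY with optional discrete-Gamma rate variation and an invariant-site
#' class. The rate matrix is normalised so that one unit of branch
#' distance equals one expected substitution per site at stationarity,
#' and the Gamma+Invariant mixture is rescaled to mean rate 1, so the
#' strict-clock rate keeps its units of substitutions/site/year.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param freqs stationary base frequencies, in order A, C, G, T.
#' @param gamma_shape shape of the discrete Gamma over site rates, or
#'   `NA` for no Gamma component (e.g. the tRNA partition, HKY+I).
#' @param n_categories number of discrete Gamma categories.
#' @param p_inv proportion of invariant sites, in `[0, 1)`.
#' @param relative_rate partition-specific rate multiplier; across the
#'   partitions of one analysis these are constrained to column-count
#'   weighted mean 1.
#' @return a `substitution_params` list.
#' @export
substitution_params <- function(kappa = 2, freqs = rep(0.25, 4),
                                gamma_shape = NA_real_, n_categories = 4L,
                                p_inv = 0, relative_rate = 1) {
  stopifnot(kappa > 0, length(freqs) == 4L, all(freqs > 0),
            abs(sum(freqs) - 1) < 1e-12,
            is.na(gamma_shape) || gamma_shape > 0,
            n_categories >= 1L, p_inv >= 0, p_inv < 1, relative_rate > 0)
  structure(list(kappa = kappa, freqs = as.numeric(freqs),
                 gamma_shape = gamma_shape, n_categories = as.integer(n_categories),
                 p_inv = p_inv, relative_rate = relative_rate),
            class = "substitution_params")
}

#' HKY transition probability matrix
#'
#' Closed-form transition probabilities of the HKY model for a branch of
#' the given expected number of substitutions per site. The generator is
#' normalised to mean rate 1 at stationarity, rows are in the order
#' A, C, G, T.
#'
#' @param params a [substitution_params()] object (only `kappa` and
#'   `freqs` are used).
#' @param distance branch distance in expected substitutions/site (>= 0).
#' @return 4x4 row-stochastic matrix `P` with `P[i, j]` the probability
#'   of ending in state j having started in state i.
#' @examples
#' p <- substitution_params(kappa = 2, freqs = c(0.3, 0.2, 0.2, 0.3))
#' rowSums(hky_transition_matrix(p, 0.1))
#' @export
hky_transition_matrix <- function(params, distance) {
  if (distance < 0) stop("negative branch distance")
  f <- params$freqs
  kappa <- params$kappa
  piA <- f[1]; piC <- f[2]; piG <- f[3]; piT <- f[4]
  piR <- piA + piG; piY <- piC + piT
  # normalisation: mean rate 1 at stationarity
  beta <- 1 / (2 * kappa * (piA * piG + piC * piT) + 2 * piR * piY)
  t <- distance
  e2 <- exp(-beta * t)
  eR <- exp(-beta * t * (piR * kappa + piY))  # group rate factor, purines
  eY <- exp(-beta * t * (piY * kappa + piR))
  P <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  grp <- c(piR, piY, piR, piY)     # group frequency of each state
  egrp <- c(eR, eY, eR, eY)
  for (i in 1:4) for (j in 1:4) {
    same_group <- (grp[i] == grp[j]) && ((i %% 2) == (j %% 2))
    if (i == j) {
      P[i, j] <- f[j] + f[j] * (1 / grp[j] - 1) * e2 +
        ((grp[j] - f[j]) / grp[j]) * egrp[j]
    } else if (same_group) {
      P[i, j] <- f[j] + f[j] * (1 / grp[j] - 1) * e2 - (f[j] / grp[j]) * egrp[j]
    } else {
      P[i, j] <- f[j] * (1 - e2)
    }
  }
  P
}

# HKY generator matrix, normalised to mean rate 1 (oracle/testing aid)
hky_rate_matrix <- function(params) {
  f <- params$freqs; kappa <- params$kappa
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  transition <- matrix(FALSE, 4, 4)
  transition[1, 3] <- transition[3, 1] <- TRUE  # A<->G
  transition[2, 4] <- transition[4, 2] <- TRUE  # C<->T
  for (i in 1:4) for (j in 1:4) if (i != j)
    Q[i, j] <- f[j] * (if (transition[i, j]) kappa else 1)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(f * diag(Q))
  Q / mu
}

#' Discrete Gamma + invariant-sites rate mixture
#'
#' Builds the site-rate mixture used by the HKY+Gamma+Invariant model:
#' one invariant category (rate 0, weight `p_inv`) plus `n_categories`
#' equal-weight Gamma categories whose rates are the within-bin means of
#' a Gamma(shape, rate = shape) over equal-probability quantile bins.
#' The whole mixture is rescaled so its mean rate is exactly 1.
#'
#' @inheritParams substitution_params
#' @return data frame with columns `rate` and `weight`.
#' @examples
#' site_rate_mixture(gamma_shape = NA, p_inv = 0.5)  # HKY+I: rates 0 and 2
#' @export
site_rate_mixture <- function(gamma_shape = NA_real_, n_categories = 4L, p_inv = 0) {
  m <- rate_mixture_fast(gamma_shape, n_categories, p_inv)
  data.frame(rate = m$rate, weight = m$weight)
}

# allocation-light core used directly in the MCMC hot loop
rate_mixture_fast <- function(gamma_shape, n_categories, p_inv) {
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must be in [0, 1)")
  if (is.na(gamma_shape)) {
    rates <- 1
    weights <- 1
  } else {
    if (gamma_shape <= 0) stop("gamma_shape must be positive")
    n <- n_categories
    q <- stats::qgamma(seq.int(0L, n) / n, shape = gamma_shape,
                       rate = gamma_shape)
    # mean of Gamma(a, a) within each equal-probability bin:
    # n * (F_{a+1}(q_hi) - F_{a+1}(q_lo)), since E[X] = 1
    cdf <- stats::pgamma(q, shape = gamma_shape + 1, rate = gamma_shape)
    rates <- n * diff(cdf)
    weights <- rep.int(1 / n, n)
  }
  if (p_inv > 0) {
    rates <- c(0, rates)
    weights <- c(p_inv, (1 - p_inv) * weights)
  }
  list(rate = rates / sum(rates * weights), weight = weights)
}

rate_mixture_of <- function(params) {
  site_rate_mixture(params$gamma_shape, params$n_categories, params$p_inv)
}
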