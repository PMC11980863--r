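#' Demographic models for the coalescent tree prior
#'
#' Either a constant effective size, or a skygrid-style piecewise-constant
#' trajectory: `K` epoch boundaries (years BP, strictly increasing) and
#' `K + 1` sizes, where `sizes[1]` applies between the present and the
#' first boundary and `sizes[K + 1]` beyond the last. Sizes are on the
#' haploid-lineage scale, in years of pairwise coalescence time (no
#' generation-time conversion). Grid mode carries the precision `tau` of
#' the Gaussian random-walk smoothing prior on log sizes.
#'
#' @param Ne constant effective size (> 0), years of pairwise coalescence.
#' @param boundaries epoch boundaries in years BP (grid mode).
#' @param sizes epoch sizes, length `length(boundaries) + 1` (grid mode).
#' @param tau GMRF precision (> 0, grid mode).
#' @return a `demographic_model` list with `mode` either `"constant"` or
#'   `"grid"`.
#' @export
demographic_model <- function(Ne = NULL, boundaries = NULL, sizes = NULL,
                              tau = 1) {
  if (!is.null(Ne)) {
    stopifnot(Ne > 0)
    return(structure(list(mode = "constant", Ne = Ne),
                     class = "demographic_model"))
  }
  stopifnot(!is.null(boundaries), !is.null(sizes),
            length(sizes) == length(boundaries) + 1L,
            all(sizes > 0), all(diff(boundaries) > 0), all(boundaries > 0),
            tau > 0)
  structure(list(mode = "grid", boundaries = as.numeric(boundaries),
                 sizes = as.numeric(sizes), tau = tau),
            class = "demographic_model")
}

# Ne as a step function of time before present
ne_at <- function(demog, t) {
  if (demog$mode == "constant") return(rep(demog$Ne, length(t)))
  idx <- findInterval(t, demog$boundaries) + 1L  # t == boundary -> older epoch
  demog$sizes[idx]
}

# integral of 1/Ne(u) du over [t0, t1], piecewise exact
inv_ne_integral <- function(demog, t0, t1) {
  stopifnot(t1 >= t0)
  if (demog$mode == "constant") return((t1 - t0) / demog$Ne)
  cuts <- c(t0, demog$boundaries[demog$boundaries > t0 & demog$boundaries < t1], t1)
  mids <- (cuts[-1L] + cuts[-length(cuts)]) / 2
  sum(diff(cuts) / ne_at(demog, mids))
}

#' Simulate a heterochronous coalescent genealogy
#'
#' Standard serially sampled coalescent: going back in time, lineages
#' become active at their sampling ages and, while `k` lineages are
#' active, pairs coalesce with hazard `k (k - 1) / (2 Ne(t))`. Under a
#' grid model the waiting time is drawn exactly by stepping the
#' cumulative hazard across epoch boundaries.
#'
#' @param sampling_ages numeric vector (length >= 2) of tip ages in years
#'   BP; names become tip labels (defaults `t1, t2, ...`).
#' @param demog a [demographic_model()].
#' @param seed integer RNG seed (required).
#' @return a [time_tree()].
#' @examples
#' tr <- simulate_genealogy(c(a = 0, b = 0, c = 5000),
#'                          demographic_model(Ne = 1e4), seed = 1)
#' @export
simulate_genealogy <- function(sampling_ages, demog, seed) {
  if (missing(seed)) stop("an explicit integer seed is required")
  n <- length(sampling_ages)
  if (n < 2L) stop("need at least 2 tips")
  stopifnot(inherits(demog, "demographic_model"), all(sampling_ages >= 0))
  set.seed(seed)
  labels <- names(sampling_ages)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  ages <- numeric(2L * n - 1L)
  ages[seq_len(n)] <- as.numeric(sampling_ages)
  ord <- order(sampling_ages)
  pending <- ord                    # tip indices not yet active, youngest first
  active <- integer(0)
  edges <- matrix(0L, 0L, 2L)
  next_internal <- n + 1L
  t <- sampling_ages[pending[1L]]
  repeat {
    while (length(pending) && ages[pending[1L]] <= t) {
      active <- c(active, pending[1L]); pending <- pending[-1L]
    }
    k <- length(active)
    if (k >= 2L) {
      horizon <- if (length(pending)) ages[pending[1L]] else Inf
      w <- coalescent_waiting_time(demog, t, k)
      if (t + w <= horizon) {
        t <- t + w
        pair <- sample(k, 2L)
        node <- next_internal; next_internal <- next_internal + 1L
        ages[node] <- t
        edges <- rbind(edges, c(node, active[pair[1L]]), c(node, active[pair[2L]]))
        active <- c(active[-pair], node)
        if (length(active) == 1L && !length(pending)) break
        next
      }
      t <- horizon
    } else {
      if (!length(pending)) break
      t <- ages[pending[1L]]
    }
  }
  # relabel internals so the root is n + 1 (ape convention)
  root_old <- next_internal - 1L
  map <- seq_len(2L * n - 1L)
  internals <- seq(n + 1L, 2L * n - 1L)
  map[root_old] <- n + 1L
  others <- setdiff(internals, root_old)
  map[others] <- n + 1L + seq_along(others)
  new_ages <- numeric(2L * n - 1L)
  new_ages[map] <- ages
  edges[] <- map[edges]
  time_tree(edges, labels, new_ages)
}

# exact waiting time to next coalescence from time t0 with k lineages
coalescent_waiting_time <- function(demog, t0, k) {
  target <- stats::rexp(1L)
  rate_mult <- k * (k - 1) / 2
  if (demog$mode == "constant") return(target * demog$Ne / rate_mult)
  t <- t0
  repeat {
    ne <- ne_at(demog, t)
    bnd <- demog$boundaries[demog$boundaries > t]
    epoch_end <- if (length(bnd)) bnd[1L] else Inf
    hazard_here <- rate_mult * (epoch_end - t) / ne
    if (hazard_here >= target || !is.finite(epoch_end))
      return(t + target * ne / rate_mult - t0)
    target <- target - hazard_here
    t <- epoch_end
  }
}

#' Log-density of a dated tree under the coalescent
#'
#' Standard heterochronous coalescent density: over each inter-event
#' interval with `k` active lineages the cumulative hazard is
#' `k (k - 1) / 2 * integral of 1/Ne(t)`, and each coalescence event
#' contributes `log(1 / Ne(t))`. Grid models integrate the
#' piecewise-constant trajectory exactly across epoch boundaries.
#'
#' @param tree a [time_tree()].
#' @param demog a [demographic_model()].
#' @return the log-density.
#' @export
coalescent_log_density <- function(tree, demog) {
  stopifnot(inherits(tree, "time_tree"), inherits(demog, "demographic_model"))
  coalescent_log_density_ages(tree$age, tree$n_tip, demog)
}

# vectorised core working directly on the node-age vector (MCMC hot path)
coalescent_log_density_ages <- function(age, n, demog) {
  type <- c(rep(0L, n), rep(1L, n - 1L))      # 0 = sampling, 1 = coalescence
  ord <- order(age, type)                     # ties: samplings first
  ts <- age[ord]
  ty <- type[ord]
  k <- cumsum(1L - 2L * ty)                   # lineages after each event
  if (any(ty == 1L & c(0L, k[-length(k)]) < 2L))
    stop("tree/demography inconsistency: coalescence with <2 lineages")
  m <- length(ts)
  kk <- k[-m]
  dLambda <- inv_ne_cumulative(demog, ts)
  -sum(kk * (kk - 1) / 2 * (dLambda[-1L] - dLambda[-m])) -
    sum(log(ne_at(demog, ts[ty == 1L])))
}

# Lambda(t) = integral_0^t 1/Ne(u) du, vectorised over t
inv_ne_cumulative <- function(demog, t) {
  if (demog$mode == "constant") return(t / demog$Ne)
  knots <- c(0, demog$boundaries)
  seg <- c(diff(knots), 0) / demog$sizes      # full-segment integrals
  base <- c(0, cumsum(seg))[seq_along(knots)]
  idx <- findInterval(t, demog$boundaries) + 1L
  base[idx] + (t - knots[idx]) / demog$sizes[idx]
}

#' Gaussian random-walk (GMRF) prior of a grid demographic model
#'
#' First-order Gaussian random walk on the log effective sizes with
#' precision `tau`, plus (optionally) a Gamma hyperprior on `tau`.
#'
#' @param demog a grid-mode [demographic_model()].
#' @param tau_shape,tau_rate Gamma hyperprior parameters for `tau`.
#' @param include_tau_prior include the hyperprior term.
#' @return the log-density.
#' @export
gmrf_log_prior <- function(demog, tau_shape = 0.001, tau_rate = 0.001,
                           include_tau_prior = TRUE) {
  if (demog$mode != "grid") stop("GMRF prior applies to grid models only")
  d <- diff(log(demog$sizes))
  ld <- sum(stats::dnorm(d, mean = 0, sd = 1 / sqrt(demog$tau), log = TRUE))
  if (include_tau_prior)
    ld <- ld + stats::dgamma(demog$tau, shape = tau_shape, rate = tau_rate,
                             log = TRUE)
  ld
}
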