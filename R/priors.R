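#' Vague priors on substitution, clock and demographic parameters
#'
#' Defaults: log-normal(meanlog 1, sdlog 1.25) on kappa; exponential
#' (mean 0.5) on the Gamma shape; uniform(0, 1) on the invariant
#' proportion; bounded scale-uniform (density proportional to 1/x) on the
#' clock rate and on effective sizes; Gamma(0.001, 0.001) on the GMRF
#' precision. Relative partition rates are flat on their weighted-mean-1
#' constraint surface.
#'
#' @param kappa_meanlog,kappa_sdlog log-normal hyperparameters for kappa.
#' @param alpha_rate exponential rate for the Gamma shape (mean `1/rate`).
#' @param clock_bounds,ne_bounds support of the 1/x priors.
#' @param tau_shape,tau_rate Gamma hyperprior on the GMRF precision.
#' @return a `parameter_priors` list.
#' @export
parameter_priors <- function(kappa_meanlog = 1, kappa_sdlog = 1.25,
                             alpha_rate = 2,
                             clock_bounds = c(1e-12, 1e-4),
                             ne_bounds = c(1, 1e10),
                             tau_shape = 0.001, tau_rate = 0.001) {
  structure(list(kappa_meanlog = kappa_meanlog, kappa_sdlog = kappa_sdlog,
                 alpha_rate = alpha_rate, clock_bounds = clock_bounds,
                 ne_bounds = ne_bounds, tau_shape = tau_shape,
                 tau_rate = tau_rate),
            class = "parameter_priors")
}

#' Calibration priors for a dating analysis
#'
#' @param root_median real-space median of the log-normal root (outgroup
#'   divergence) calibration, years BP; `NULL` disables the calibration.
#' @param root_sdlog log-scale standard deviation of the calibration.
#' @param tip_priors named list mapping undated sample ids to
#'   `c(lo, hi)` uniform age bounds in years BP.
#' @return a `calibration_priors` list.
#' @export
calibration_priors <- function(root_median = 5.3e6, root_sdlog = 0.05,
                               tip_priors = list()) {
  if (!is.null(root_median)) stopifnot(root_median > 0, root_sdlog > 0)
  for (b in tip_priors) stopifnot(length(b) == 2L, b[1] < b[2], b[1] >= 0)
  structure(list(root_median = root_median, root_sdlog = root_sdlog,
                 tip_priors = tip_priors),
            class = "calibration_priors")
}

# log(1/x) prior on [lo, hi]; unnormalised outside interest, -Inf off support
log_scale_uniform <- function(x, bounds) {
  if (x < bounds[1] || x > bounds[2]) return(-Inf)
  -log(x)
}

#' Joint log-prior of a tip-dating model state
#'
#' Sum of the coalescent tree density, the GMRF smoothing prior (grid
#' demography only), the log-normal root calibration, the uniform tip-age
#' priors (0 inside bounds, `-Inf` outside — an out-of-bounds tip age is
#' a rejected state, not an error), and vague priors on the free
#' substitution/clock parameters. When `shared_subst = TRUE` (one linked
#' set of substitution parameters across partitions) the kappa, Gamma
#' shape and invariant-proportion terms are counted once.
#'
#' @param tree a [time_tree()].
#' @param subst named list of [substitution_params()], one per partition.
#' @param clock_rate strict-clock rate.
#' @param demog a [demographic_model()].
#' @param calibrations a [calibration_priors()].
#' @param priors a [parameter_priors()].
#' @param shared_subst are substitution parameters linked across
#'   partitions?
#' @return the joint log-prior (possibly `-Inf`).
#' @export
state_log_prior <- function(tree, subst, clock_rate, demog, calibrations,
                            priors = parameter_priors(), shared_subst = TRUE) {
  # hard bounds first: uniform tip priors
  tp <- calibrations$tip_priors
  if (length(tp)) {
    ages <- tip_ages(tree)
    for (id in names(tp)) {
      a <- ages[[id]]
      if (a < tp[[id]][1] || a > tp[[id]][2]) return(-Inf)
    }
  }
  lp <- log_scale_uniform(clock_rate, priors$clock_bounds)
  if (!is.finite(lp)) return(-Inf)
  sets <- if (shared_subst) subst[1] else subst
  for (s in sets) {
    lp <- lp + stats::dlnorm(s$kappa, priors$kappa_meanlog, priors$kappa_sdlog,
                             log = TRUE)
    if (s$p_inv < 0 || s$p_inv >= 1) return(-Inf)
  }
  shapes <- unique(stats::na.omit(vapply(sets, `[[`, numeric(1), "gamma_shape")))
  for (a in shapes)
    lp <- lp + stats::dexp(a, rate = priors$alpha_rate, log = TRUE)
  if (any(vapply(subst, `[[`, numeric(1), "relative_rate") <= 0)) return(-Inf)
  if (demog$mode == "constant") {
    lp <- lp + log_scale_uniform(demog$Ne, priors$ne_bounds)
  } else {
    for (s in demog$sizes) {
      v <- log_scale_uniform(s, priors$ne_bounds)
      if (!is.finite(v)) return(-Inf)
      lp <- lp + v
    }
    lp <- lp + gmrf_log_prior(demog, priors$tau_shape, priors$tau_rate)
  }
  if (!is.finite(lp)) return(-Inf)
  lp <- lp + coalescent_log_density(tree, demog)
  if (!is.null(calibrations$root_median))
    lp <- lp + stats::dlnorm(root_age(tree), log(calibrations$root_median),
                             calibrations$root_sdlog, log = TRUE)
  lp
}

#' @rdname state_log_prior
#' @param aln a [partitioned_alignment()] whose live partitions match
#'   `names(subst)`.
#' @return `state_log_posterior()` returns a list with components
#'   `log_prior`, `log_likelihood` (sum over partitions) and
#'   `log_posterior`.
#' @export
state_log_posterior <- function(tree, aln, subst, clock_rate, demog,
                                calibrations, priors = parameter_priors(),
                                shared_subst = TRUE) {
  lp <- state_log_prior(tree, subst, clock_rate, demog, calibrations, priors,
                        shared_subst)
  if (!is.finite(lp))
    return(list(log_prior = lp, log_likelihood = NA_real_,
                log_posterior = -Inf))
  ld <- likelihood_data(aln, tree$tip_label)
  ll <- sum(all_partition_loglik(tree, ld, subst, clock_rate))
  list(log_prior = lp, log_likelihood = ll, log_posterior = lp + ll)
}
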