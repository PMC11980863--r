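#' Effective sample size of an MCMC series
#'
#' Initial-positive-sequence autocorrelation estimator: sample
#' autocorrelations are summed in adjacent pairs (lags 0/1, 2/3, ...)
#' until a pair sum turns non-positive, giving the integrated
#' autocorrelation time `tau = 1 + 2 * sum(rho_k)`; `ESS = N / tau`.
#'
#' @param series numeric vector of at least 100 retained samples.
#' @return the effective sample size.
#' @examples
#' effective_sample_size(rnorm(1000))
#' @export
effective_sample_size <- function(series) {
  n <- length(series)
  if (n < 100L) stop("need at least 100 samples for an ESS estimate")
  if (stats::var(series) == 0) stop("constant series has no defined ESS")
  max_lag <- min(n - 1L, 2000L)
  rho <- stats::acf(series, lag.max = max_lag, plot = FALSE)$acf[, 1, 1]
  # rho[1] is lag 0; pair rho_{2m-1} + rho_{2m} (Geyer initial positive)
  s <- 0
  m <- 1L
  while (2L * m <= max_lag) {
    g <- rho[2L * m] + rho[2L * m + 1L]
    if (g <= 0) break
    s <- s + g
    m <- m + 1L
  }
  tau <- max(1, 1 + 2 * s)      # 1 + 2*(rho_1 + rho_2 + ...) via pair sums
  n / tau
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval over the sorted samples containing
#' `ceiling(mass * N)` points; ties in width resolve to the lowest lower
#' endpoint.
#'
#' @param samples numeric vector (>= 20 samples).
#' @param mass interval probability mass, in (0, 1).
#' @return numeric `c(lo, hi)`.
#' @examples
#' hpd_interval(rnorm(10000))
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  n <- length(samples)
  if (n < 20L) stop("need at least 20 samples for an HPD interval")
  x <- sort(samples)
  m <- ceiling(mass * n)
  widths <- x[m:n] - x[seq_len(n - m + 1L)]
  i <- which.min(widths)              # which.min takes the first (lowest lo)
  c(lo = x[i], hi = x[i + m - 1L])
}

#' Convergence check between a pair of chains
#'
#' The study design runs two independent chains per dating analysis.
#' A parameter passes when both chains reach ESS > `min_ess` (the study
#' threshold is 200) and the split-chain potential scale reduction
#' statistic (split R-hat over the four half-chains) is below
#' `max_psrf`.
#'
#' @param trace_a,trace_b trace data frames (see [read_trace()]).
#' @param parameter trace column to check.
#' @param min_ess per-chain ESS threshold.
#' @param max_psrf split R-hat threshold.
#' @return list with `pass`, `ess` (per chain), `psrf`.
#' @export
check_convergence <- function(trace_a, trace_b, parameter,
                              min_ess = 200, max_psrf = 1.05) {
  for (tr in list(trace_a, trace_b))
    if (!parameter %in% names(tr)) stop("parameter not in trace: ", parameter)
  a <- trace_a[[parameter]]; b <- trace_b[[parameter]]
  ess <- c(effective_sample_size(a), effective_sample_size(b))
  psrf <- split_rhat(list(a, b))
  list(pass = all(ess > min_ess) && psrf < max_psrf,
       ess = ess, psrf = psrf)
}

# classic potential scale reduction over split half-chains
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2L
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(x) x[seq_len(n)])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Unimodality check of a posterior sample
#'
#' Kernel-density mode count with Silverman's rule-of-thumb bandwidth;
#' local maxima below 10% of the global density maximum are ignored.
#' A sample is unimodal when exactly one mode remains. (The study
#' requires every reported tip date to have converged to a unimodal
#' posterior.)
#'
#' @param samples numeric vector (>= 100 samples).
#' @param min_mode_fraction relative density height below which a local
#'   maximum is not counted.
#' @return logical flag.
#' @export
unimodality_check <- function(samples, min_mode_fraction = 0.1) {
  if (length(samples) < 100L) stop("need at least 100 samples")
  if (stats::var(samples) == 0) return(TRUE)
  d <- stats::density(samples, bw = "nrd0")
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  if (y[1] > y[2]) peaks <- c(1L, peaks)
  ny <- length(y)
  if (y[ny] > y[ny - 1L]) peaks <- c(peaks, ny)
  sum(y[peaks] >= min_mode_fraction * max(y)) == 1L
}
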