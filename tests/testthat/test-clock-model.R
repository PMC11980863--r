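test_that("HKY transition matrices match the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  set.seed(14)
  for (i in 1:20) {
    p <- random_subst_params()
    d <- stats::runif(1, 0, 2)
    P <- hky_transition_matrix(p, d)
    Q <- tipdater:::hky_rate_matrix(p)
    P_oracle <- as.matrix(Matrix::expm(Q * d))
    expect_lt(max(abs(P - P_oracle)), 1e-10)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    expect_true(all(P >= 0))
    # detailed balance: pi_i P_ij = pi_j P_ji
    flux <- p$freqs * P
    expect_lt(max(abs(flux - t(flux))), 1e-10)
  }
  p <- substitution_params(kappa = 2, freqs = c(0.3, 0.2, 0.2, 0.3))
  expect_equal(hky_transition_matrix(p, 0), diag(4), ignore_attr = TRUE)
  P50 <- hky_transition_matrix(p, 50)
  expect_lt(max(abs(sweep(P50, 2, p$freqs))), 1e-8)
  expect_error(hky_transition_matrix(p, -1), "negative")
})

test_that("the Gamma+Invariant mixture has the stated category structure", {
  # HKY+I limit: categories (0, p) and (2, 1-p) for p = 0.5
  m <- site_rate_mixture(gamma_shape = NA, p_inv = 0.5)
  expect_equal(m$rate, c(0, 2))
  expect_equal(m$weight, c(0.5, 0.5))

  # degenerate Gamma: Gamma(a, a) tends to a point mass at 1, so the
  # category rates collapse onto 1; at shape a the quartile-bin means sit
  # +-1.27 / sqrt(a) from 1 (normal limit), which the computed rates match
  m2 <- site_rate_mixture(1e8, 4, 0)
  expect_lt(max(abs(m2$rate - 1)), 2e-4)
  expect_equal(max(m2$rate) - 1, 1.27 / sqrt(1e8), tolerance = 0.02)
  expect_lt(max(abs(site_rate_mixture(1e10, 4, 0)$rate - 1)), 2e-5)

  # alpha = 0.5: quantile-bin means match a numeric integration oracle
  a <- 0.5; n <- 4
  q <- stats::qgamma(seq(0, 1, length.out = n + 1), shape = a, rate = a)
  oracle <- vapply(seq_len(n), function(i) {
    stats::integrate(function(x) x * stats::dgamma(x, a, rate = a),
                     q[i], q[i + 1], rel.tol = 1e-12)$value * n
  }, numeric(1))
  m3 <- site_rate_mixture(a, n, 0)
  expect_lt(max(abs(m3$rate - oracle / mean(oracle))), 1e-8)
  expect_lt(abs(sum(m3$rate * m3$weight) - 1), 1e-12)
  # mixture mean is 1 with the invariant class included
  m4 <- site_rate_mixture(0.8, 4, 0.3)
  expect_lt(abs(sum(m4$rate * m4$weight) - 1), 1e-12)
  expect_error(site_rate_mixture(0.5, 4, 1), "p_inv")
})

test_that("pruning equals brute-force enumeration on small trees", {
  set.seed(15)
  for (i in 1:15) {
    n <- sample(3:5, 1)
    tr <- random_time_tree(n)
    params <- random_subst_params(with_gamma = i %% 2 == 0)
    clock <- stats::runif(1, 0.01, 0.2)
    cols <- random_columns(tr$tip_label, 12)
    expect_lt(abs(partition_log_likelihood(tr, cols, params, clock) -
                    brute_force_loglik(tr, cols, params, clock)), 1e-10)
  }
  # fully ambiguous site: likelihood 1
  tr2 <- time_tree(rbind(c(3L, 1L), c(3L, 2L)), c("a", "b"), c(0, 0, 1))
  colsN <- matrix("N", 2, 1, dimnames = list(c("a", "b"), NULL))
  expect_equal(partition_log_likelihood(tr2, colsN, substitution_params(),
                                        0.1), 0)
  # matching bases at zero distance: log pi
  colsA <- matrix("A", 2, 1, dimnames = list(c("a", "b"), NULL))
  expect_equal(partition_log_likelihood(tr2, colsA, substitution_params(),
                                        0), log(0.25))
  expect_error(partition_log_likelihood(
    tr2, matrix("A", 2, 1, dimnames = list(c("a", "z"), NULL)),
    substitution_params(), 0.1), "lacks")
})

test_that("likelihood is invariant to site order and pattern compression", {
  set.seed(16)
  tr <- random_time_tree(5)
  params <- random_subst_params()
  cols <- random_columns(tr$tip_label, 40)
  cols <- cols[, c(seq_len(20), seq_len(20))]   # force duplicate patterns
  base <- partition_log_likelihood(tr, cols, params, 0.1)
  shuf <- partition_log_likelihood(tr, cols[, sample(40)], params, 0.1)
  expect_equal(base, shuf, tolerance = 1e-12)
})

test_that("two-tip likelihoods reduce to the Jukes-Cantor closed form", {
  tr <- time_tree(rbind(c(3L, 1L), c(3L, 2L)), c("a", "b"), c(0, 0, 0.5))
  p <- substitution_params(kappa = 1, freqs = rep(0.25, 4))
  d <- 2 * 0.5 * 0.1                          # total path, clock 0.1
  same <- 0.25 * (0.25 + 0.75 * exp(-4 * d / 3))
  diff <- 0.25 * (0.25 - 0.25 * exp(-4 * d / 3))
  colsAA <- matrix(c("A", "A"), 2, 1, dimnames = list(c("a", "b"), NULL))
  colsAC <- matrix(c("A", "C"), 2, 1, dimnames = list(c("a", "b"), NULL))
  expect_lt(abs(partition_log_likelihood(tr, colsAA, p, 0.1) - log(same)),
            1e-10)
  expect_lt(abs(partition_log_likelihood(tr, colsAC, p, 0.1) - log(diff)),
            1e-10)
})

test_that("coalescent densities match closed forms and the integrator", {
  tr <- time_tree(rbind(c(3L, 1L), c(3L, 2L)), c("a", "b"), c(0, 0, 5000))
  d <- demographic_model(Ne = 2000)
  expect_equal(coalescent_log_density(tr, d), -log(2000) - 5000 / 2000)

  # grid with equal sizes reduces exactly to constant
  g <- demographic_model(boundaries = c(1000, 3000),
                         sizes = rep(2000, 3))
  expect_identical(coalescent_log_density(tr, g),
                   coalescent_log_density(tr, d))

  # 5-tip heterochronous tree on a 4-epoch grid vs numeric integration
  tr5 <- simulate_genealogy(
    stats::setNames(c(0, 500, 1200, 3000, 7000), paste0("s", 1:5)),
    demographic_model(Ne = 3000), seed = 7)
  gg <- demographic_model(boundaries = c(800, 2500, 6000),
                          sizes = c(1000, 4000, 2500, 6000))
  expect_lt(abs(coalescent_log_density(tr5, gg) -
                  integrator_coalescent_logdens(tr5, gg)), 1e-10)
  expect_lt(abs(coalescent_log_density(tr5, d) -
                  integrator_coalescent_logdens(tr5, d)), 1e-10)
})

test_that("the GMRF smoothing prior has the stated closed form", {
  # two epochs, tau = 1, one unit log step
  g <- demographic_model(boundaries = 1000, sizes = c(1000, 1000 * exp(1)),
                         tau = 1)
  expect_equal(gmrf_log_prior(g, include_tau_prior = FALSE),
               -0.5 - 0.5 * log(2 * pi))
  # flat trajectories maximise the random-walk term for given tau
  flat <- demographic_model(boundaries = c(1e3, 2e3), sizes = rep(500, 3),
                            tau = 2)
  best <- gmrf_log_prior(flat, include_tau_prior = FALSE)
  set.seed(17)
  for (i in 1:20) {
    wob <- demographic_model(boundaries = c(1e3, 2e3),
                             sizes = 500 * exp(rnorm(3, 0, 0.5)), tau = 2)
    expect_lte(gmrf_log_prior(wob, include_tau_prior = FALSE), best)
  }
  # product-of-normal-increments oracle on random grids
  for (i in 1:20) {
    K <- sample(2:6, 1)
    sizes <- exp(rnorm(K + 1, 8, 1))
    tau <- rexp(1) + 0.1
    g <- demographic_model(boundaries = sort(runif(K, 1, 1e4)),
                           sizes = sizes, tau = tau)
    oracle <- sum(stats::dnorm(diff(log(sizes)), 0, 1 / sqrt(tau),
                               log = TRUE)) +
      stats::dgamma(tau, 0.001, rate = 0.001, log = TRUE)
    expect_lt(abs(gmrf_log_prior(g) - oracle), 1e-12)
  }
  expect_error(gmrf_log_prior(demographic_model(Ne = 5)), "grid")
})

test_that("the joint prior stacks its components as stated", {
  set.seed(18)
  tr <- random_time_tree(4, max_tip_age = 2e5, Ne = 1e5)
  # force an undated tip inside bounds
  subst <- list(part1 = substitution_params(kappa = 8, gamma_shape = 0.5,
                                            p_inv = 0.2))
  demog <- demographic_model(Ne = 2e5)
  pri <- parameter_priors()
  calib <- calibration_priors(root_median = root_age(tr), root_sdlog = 0.1,
                              tip_priors = list(s1 = c(1e3, 2e6)))
  tr$age[1] <- 5e5                       # tip s1, inside bounds
  tr <- tipdater:::repair_node_ages(tr)
  got <- state_log_prior(tr, subst, 1e-8, demog, calib, pri)
  oracle <- coalescent_log_density(tr, demog) +
    stats::dlnorm(root_age(tr), log(calib$root_median), 0.1, log = TRUE) +
    -log(1e-8) +
    stats::dlnorm(8, pri$kappa_meanlog, pri$kappa_sdlog, log = TRUE) +
    stats::dexp(0.5, pri$alpha_rate, log = TRUE) +
    -log(2e5)
  expect_lt(abs(got - oracle), 1e-12)

  # undated tip outside its uniform bounds: rejected state, not an error
  tr_bad <- tr; tr_bad$age[1] <- 500
  expect_identical(state_log_prior(tr_bad, subst, 1e-8, demog, calib, pri),
                   -Inf)

  # root exactly at the log-normal median contributes the median density
  calib2 <- calibration_priors(root_median = root_age(tr),
                               root_sdlog = 0.05)
  base <- state_log_prior(tr, subst, 1e-8, demog,
                          calibration_priors(root_median = NULL), pri)
  expect_equal(state_log_prior(tr, subst, 1e-8, demog, calib2, pri) - base,
               stats::dlnorm(root_age(tr), log(root_age(tr)), 0.05,
                             log = TRUE))

  # posterior = prior + summed partition likelihoods
  ds <- tiny_dataset(seed = 41, n_cal = 4, L = 300)
  aln <- ds$alignment
  parts <- setdiff(unique(aln$partition), c("masked", "unassigned"))
  subst_all <- stats::setNames(lapply(parts, function(p)
    substitution_params(kappa = 6, gamma_shape = 0.5, p_inv = 0.1)), parts)
  calib3 <- calibration_priors(tip_priors = list(und01 = c(1e3, 2e6)))
  post <- state_log_posterior(ds$tree, aln, subst_all, 2.5e-8, demog,
                              calib3)
  ll_oracle <- sum(vapply(parts, function(p)
    partition_log_likelihood(ds$tree,
                             aln$seqs[, aln$partition == p, drop = FALSE],
                             subst_all[[p]], 2.5e-8), numeric(1)))
  expect_lt(abs(post$log_likelihood - ll_oracle), 1e-9)
  expect_equal(post$log_posterior, post$log_prior + post$log_likelihood)
})
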