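# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: likelihoods by exhaustive enumeration
# of internal states, coalescent densities by adaptive numeric integration,
# transition kernels by matrix exponentials.

# exhaustive-state-enumeration log-likelihood (trees small enough to sum
# over all 4^(n-1) internal-node state assignments)
brute_force_loglik <- function(tree, cols, params, clock) {
  mix <- site_rate_mixture(params$gamma_shape, params$n_categories,
                           params$p_inv)
  n <- tree$n_tip
  internals <- setdiff(seq_len(2 * n - 1), seq_len(n))
  Pcat <- lapply(seq_len(nrow(mix)), function(ci) {
    lapply(seq_len(nrow(tree$edge)), function(e) {
      d <- clock * params$relative_rate * mix$rate[ci] *
        (tree$age[tree$edge[e, 1]] - tree$age[tree$edge[e, 2]])
      hky_transition_matrix(params, d)
    })
  })
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
  obs_all <- cols[tree$tip_label, , drop = FALSE]
  total <- 0
  for (s in seq_len(ncol(cols))) {
    obs <- obs_all[, s]
    site <- 0
    for (ci in seq_len(nrow(mix))) {
      P <- Pcat[[ci]]
      lik <- 0
      for (g in seq_len(nrow(grid))) {
        st <- integer(2 * n - 1)
        st[internals] <- grid[g, ]
        pr <- params$freqs[st[n + 1]]
        for (e in seq_len(nrow(tree$edge))) {
          par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
          if (ch <= n) {
            o <- obs[ch]
            if (!(o %in% c("N", "-")))
              pr <- pr * P[[e]][st[par], match(o, c("A", "C", "G", "T"))]
          } else {
            pr <- pr * P[[e]][st[par], st[ch]]
          }
        }
        lik <- lik + pr
      }
      site <- site + mix$weight[ci] * lik
    }
    total <- total + log(site)
  }
  total
}

# heterochronous coalescent log-density by numeric integration of the
# piecewise hazard (independent of the package's interval sweep)
integrator_coalescent_logdens <- function(tree, demog) {
  nefun <- function(t) vapply(t, function(x) tipdater:::ne_at(demog, x),
                              numeric(1))
  n <- tree$n_tip
  ev <- data.frame(t = tree$age, type = c(rep(0, n), rep(1, n - 1)))
  ev <- ev[order(ev$t, ev$type), ]
  k <- 0; ld <- 0; tprev <- ev$t[1]
  for (i in seq_len(nrow(ev))) {
    if (ev$t[i] > tprev) {
      if (k >= 2)
        ld <- ld - k * (k - 1) / 2 *
          stats::integrate(function(u) 1 / nefun(u), tprev, ev$t[i],
                           rel.tol = 1e-12, subdivisions = 2000L)$value
      tprev <- ev$t[i]
    }
    if (ev$type[i] == 0) k <- k + 1
    else { ld <- ld - log(nefun(ev$t[i])); k <- k - 1 }
  }
  ld
}

# random dated tree helper
random_time_tree <- function(n, max_tip_age = 3, Ne = 2, seed = NULL) {
  if (is.null(seed)) seed <- sample.int(1e8, 1)
  ages <- stats::setNames(stats::runif(n, 0, max_tip_age), paste0("s", seq_len(n)))
  simulate_genealogy(ages, demographic_model(Ne = Ne), seed = seed)
}

random_subst_params <- function(with_gamma = TRUE) {
  f <- stats::runif(4, 0.1, 1); f <- f / sum(f)
  substitution_params(
    kappa = stats::runif(1, 1, 12), freqs = f,
    gamma_shape = if (with_gamma) stats::runif(1, 0.2, 2) else NA_real_,
    p_inv = stats::runif(1, 0, 0.4))
}

# small alignment of random columns over the full alphabet
random_columns <- function(tip_labels, n_sites) {
  m <- matrix(sample(c("A", "C", "G", "T", "N", "-"),
                     length(tip_labels) * n_sites, replace = TRUE,
                     prob = c(0.22, 0.22, 0.22, 0.22, 0.06, 0.06)),
              nrow = length(tip_labels))
  rownames(m) <- tip_labels
  m
}

# tiny study dataset used by protocol tests
tiny_dataset <- function(seed = 21, n_cal = 8, n_und = 1, L = 400) {
  make_study_dataset(
    study_config(n_calibrated = n_cal, n_undated = n_und, n_outgroup = 2,
                 L = L),
    seed = seed)
}
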