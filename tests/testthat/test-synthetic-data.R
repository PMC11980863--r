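test_that("coalescent genealogies match analytic expectations", {
  set.seed(5)
  Ne <- 1000
  # 2 isochronous tips: E[TMRCA] = Ne
  t2 <- replicate(2000, root_age(
    simulate_genealogy(c(a = 0, b = 0), demographic_model(Ne = Ne),
                       seed = sample.int(1e8, 1))))
  se <- sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - Ne), 3 * se)

  # 10 isochronous tips: E[TMRCA] = 2 Ne (1 - 1/10)
  t10 <- replicate(2000, root_age(
    simulate_genealogy(stats::setNames(rep(0, 10), paste0("s", 1:10)),
                       demographic_model(Ne = Ne),
                       seed = sample.int(1e8, 1))))
  se10 <- sd(t10) / sqrt(length(t10))
  expect_lt(abs(mean(t10) - 2 * Ne * 0.9), 3 * se10)

  # heterochronous: the root is always older than the oldest tip
  roots <- replicate(200, root_age(
    simulate_genealogy(c(a = 0, b = 5000), demographic_model(Ne = Ne),
                       seed = sample.int(1e8, 1))))
  expect_true(all(roots >= 5000))

  expect_error(simulate_genealogy(c(a = 0), demographic_model(Ne = 1),
                                  seed = 1), "2 tips")
  expect_error(demographic_model(Ne = -1))
})

test_that("two-tip TMRCA follows Exponential(1/Ne) (KS, alpha = 0.01)", {
  set.seed(6)
  Ne <- 1500
  draws <- replicate(5000, root_age(
    simulate_genealogy(c(a = 0, b = 0), demographic_model(Ne = Ne),
                       seed = sample.int(1e8, 1))))
  expect_gt(stats::ks.test(draws, stats::pexp, 1 / Ne)$p.value, 0.01)
})

test_that("sequence simulation reproduces closed-form distances", {
  # JC-like settings: expected substitutions/site 0.1 between two tips
  tr <- time_tree(rbind(c(3L, 1L), c(3L, 2L)), c("a", "b"), c(0, 0, 0.05))
  mod <- substitution_params(kappa = 1, freqs = rep(0.25, 4))
  aln <- simulate_alignment(tr, rep("control_region", 1e5),
                            list(control_region = mod), clock_rate = 1,
                            seed = 9)
  p_obs <- mean(aln$seqs[1, ] != aln$seqs[2, ])
  p_jc <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  se <- sqrt(p_jc * (1 - p_jc) / 1e5)
  expect_lt(abs(p_obs - p_jc), 3 * se)

  # zero clock rate: all sequences identical to the root draw
  aln0 <- simulate_alignment(tr, rep("control_region", 500),
                             list(control_region = mod), clock_rate = 0,
                             seed = 10)
  expect_identical(aln0$seqs[1, ], aln0$seqs[2, ])

  # base composition converges to the stationary frequencies
  f <- c(0.4, 0.3, 0.2, 0.1)
  modf <- substitution_params(kappa = 5, freqs = f)
  alnf <- simulate_alignment(tr, rep("control_region", 4e4),
                             list(control_region = modf), clock_rate = 1,
                             seed = 11)
  counts <- table(factor(alnf$seqs, levels = c("A", "C", "G", "T")))
  n <- sum(counts)
  for (i in 1:4) {
    se_i <- sqrt(f[i] * (1 - f[i]) / n)
    expect_lt(abs(counts[[i]] / n - f[i]), 4 * se_i)
  }
})

test_that("site patterns on a 3-tip tree match pruning predictions", {
  # dual route: simulated pattern counts vs probabilities computed by the
  # likelihood machinery (chi-squared goodness of fit, alpha = 0.01)
  tr <- simulate_genealogy(c(a = 0, b = 0.3, c = 0.8),
                           demographic_model(Ne = 1), seed = 12)
  mod <- substitution_params(kappa = 4, freqs = c(0.3, 0.25, 0.25, 0.2),
                             gamma_shape = 0.6, p_inv = 0.2)
  L <- 1e5
  aln <- simulate_alignment(tr, rep("rRNA", L), list(rRNA = mod),
                            clock_rate = 0.15, seed = 13)
  pat <- apply(aln$seqs[c("a", "b", "c"), ], 2, paste, collapse = "")
  obs <- table(pat)
  bases <- c("A", "C", "G", "T")
  all_pat <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  probs <- vapply(all_pat, function(pp) {
    cols <- matrix(strsplit(pp, "")[[1]], ncol = 1,
                   dimnames = list(c("a", "b", "c"), NULL))
    exp(partition_log_likelihood(tr, cols, mod, 0.15))
  }, numeric(1))
  expect_equal(sum(probs), 1, tolerance = 1e-8)
  counts <- stats::setNames(rep(0, length(all_pat)), all_pat)
  counts[names(obs)] <- as.numeric(obs)
  keep <- probs * L >= 5      # standard chi-squared validity pooling
  chi <- sum((counts[keep] - L * probs[keep])^2 / (L * probs[keep])) +
    (sum(counts[!keep]) - L * sum(probs[!keep]))^2 /
    max(L * sum(probs[!keep]), 1e-9)
  df <- sum(keep)             # conservative
  expect_gt(stats::pchisq(chi, df, lower.tail = FALSE), 0.01)
})

test_that("study datasets are bookkept correctly and deterministic", {
  cfg <- study_config(n_calibrated = 20, n_undated = 1, n_outgroup = 2,
                      L = 600)
  ds <- make_study_dataset(cfg, seed = 11)
  expect_identical(nrow(ds$alignment$seqs), 23L)
  expect_identical(sum(ds$samples$age_status == "undated"), 1L)
  expect_identical(ds$samples$prior_lo[ds$samples$age_status == "undated"],
                   1e3)
  expect_identical(ds$samples$prior_hi[ds$samples$age_status == "undated"],
                   2e6)
  # calibrated tip ages in the table equal the generating ages exactly
  cal <- ds$samples$age_status == "calibrated_fixed"
  expect_identical(ds$samples$fixed_age[cal],
                   ds$truth$true_age[match(ds$samples$sample_id[cal],
                                           ds$truth$sample_id)])
  # undated truth is hidden from the sample table
  expect_true(all(is.na(ds$samples$fixed_age[ds$samples$age_status ==
                                               "undated"])))
  # tree tips agree with the truth table
  expect_equal(tip_ages(ds$tree)[ds$truth$sample_id],
               stats::setNames(ds$truth$true_age, ds$truth$sample_id))
  # outgroup split near the calibration law, older than both subtrees
  expect_gt(attr(ds$truth, "root_split_age"), 4e6)
  expect_lt(attr(ds$truth, "root_split_age"), 7e6)
  expect_identical(root_age(ds$tree), attr(ds$truth, "root_split_age"))

  ds2 <- make_study_dataset(cfg, seed = 11)
  expect_identical(ds$alignment$seqs, ds2$alignment$seqs)
  expect_identical(ds$tree$age, ds2$tree$age)
  ds3 <- make_study_dataset(cfg, seed = 12)
  expect_false(identical(ds$alignment$seqs, ds3$alignment$seqs))
})
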