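test_that("ESS estimates match analytic autocorrelation structure", {
  set.seed(19)
  # iid normal: ESS near N
  x <- rnorm(10000)
  expect_lt(abs(effective_sample_size(x) - 10000) / 10000, 0.15)
  # AR(1), rho = 0.9: ESS ~ N (1 - rho) / (1 + rho)
  n <- 100000; rho <- 0.9
  ar <- as.numeric(stats::arima.sim(list(ar = rho), n))
  want <- n * (1 - rho) / (1 + rho)
  expect_lt(abs(effective_sample_size(ar) - want) / want, 0.2)
  expect_error(effective_sample_size(rep(1, 500)), "constant")
  expect_error(effective_sample_size(rnorm(50)), "at least 100")
})

test_that("HPD intervals are the shortest windows over order statistics", {
  expect_equal(hpd_interval(rep(3.5, 25)), c(lo = 3.5, hi = 3.5))
  # 1..100 at mass 0.95: brute force over all contiguous windows
  x <- 1:100
  m <- ceiling(0.95 * 100)
  widths <- vapply(seq_len(100 - m + 1), function(i) x[i + m - 1] - x[i],
                   numeric(1))
  i <- which.min(widths)
  expect_equal(hpd_interval(x, 0.95),
               c(lo = x[i], hi = x[i + m - 1]))
  expect_equal(unname(hpd_interval(x, 0.95)), c(1, 95))  # ties -> lowest lo
  set.seed(20)
  z <- rnorm(100000)
  h <- hpd_interval(z)
  expect_lt(abs(h[["lo"]] + 1.96), 0.05)
  expect_lt(abs(h[["hi"]] - 1.96), 0.05)
  # brute-force agreement on skewed samples
  y <- rexp(501)
  m <- ceiling(0.95 * length(y)); ys <- sort(y)
  widths <- ys[m:length(y)] - ys[seq_len(length(y) - m + 1)]
  expect_equal(unname(hpd_interval(y, 0.95)[2] - hpd_interval(y, 0.95)[1]),
               min(widths))
  expect_error(hpd_interval(z, 1.2), "mass")
  expect_error(hpd_interval(z[1:5]), "20")
})

test_that("chain-pair convergence gates on ESS and split R-hat", {
  set.seed(21)
  mk <- function(x) data.frame(iteration = seq_along(x),
                               log_posterior = 0, log_likelihood = 0,
                               log_prior = 0, theta = x)
  a <- mk(rnorm(2000)); b <- mk(rnorm(2000))
  r <- check_convergence(a, b, "theta")
  expect_true(r$pass)
  expect_true(all(r$ess > 200))
  expect_lt(r$psrf, 1.05)
  # chains far apart fail on R-hat
  r2 <- check_convergence(a, mk(rnorm(2000, mean = 10)), "theta")
  expect_false(r2$pass)
  expect_gt(r2$psrf, 1.05)
  # low ESS fails regardless of agreement
  slow <- mk(as.numeric(stats::arima.sim(list(ar = 0.999), 2000)))
  slow$theta <- slow$theta / sd(slow$theta)
  r3 <- check_convergence(a, slow, "theta")
  expect_false(r3$pass)
  expect_error(check_convergence(a, b, "missing_par"), "not in trace")
})

test_that("unimodality is detected by mode counting", {
  set.seed(22)
  expect_true(unimodality_check(rnorm(2000)))
  expect_false(unimodality_check(c(rnorm(1000, 0), rnorm(1000, 6))))
  expect_true(unimodality_check(rep(2, 200)))
  # tiny spurious modes below 10% of the maximum are ignored
  expect_true(unimodality_check(c(rnorm(2000, 0), rnorm(20, 12))))
})

test_that("MCC trees equal exhaustive scoring on a constructed sample", {
  # three topologies on four isochronous tips, frequencies 0.6/0.3/0.1
  mk_tree <- function(split) {
    # split: list of two pairs of tip labels; node 6 age 1, node 7 age 2
    labs <- c("a", "b", "c", "d")
    idx <- match(unlist(split), labs)
    edge <- rbind(c(5L, 6L), c(6L, idx[1]), c(6L, idx[2]),
                  c(5L, 7L), c(7L, idx[3]), c(7L, idx[4]))
    time_tree(edge, labs, c(0, 0, 0, 0, 3, 1, 2))
  }
  t1 <- mk_tree(list(c("a", "b"), c("c", "d")))
  t2 <- mk_tree(list(c("a", "c"), c("b", "d")))
  t3 <- mk_tree(list(c("a", "d"), c("b", "c")))
  sample_trees <- c(rep(list(t1), 6), rep(list(t2), 3), rep(list(t3), 1))
  res <- mcc_tree(sample_trees)
  # exhaustive oracle: score every distinct topology by clade frequencies
  freq <- table(unlist(lapply(sample_trees, function(tr)
    tipdater:::clade_keys(tr)[-(1:4)])))
  scores <- vapply(list(t1, t2, t3), function(tr)
    sum(log(as.numeric(freq[tipdater:::clade_keys(tr)[-(1:4)]]) / 10)),
    numeric(1))
  expect_identical(tipdater:::clade_keys(res$tree),
                   tipdater:::clade_keys(list(t1, t2, t3)[[which.max(scores)]]))
  expect_equal(res$log_clade_credibility, max(scores))
  # all trees identical: that tree with support 1 everywhere
  res1 <- mcc_tree(rep(list(t2), 5))
  expect_true(all(res1$annotations$support == 1))
  # annotated root-height mean is the arithmetic mean of root heights
  expect_equal(res$annotations$height_mean[res$annotations$node == 5], 3)
  expect_error(mcc_tree(list(t1, time_tree(rbind(c(3L, 1L), c(3L, 2L)),
                                           c("x", "y"), c(0, 0, 1)))),
               "inconsistent")
})

test_that("chains are reproducible and behave sanely on synthetic data", {
  ds <- tiny_dataset(seed = 23, n_cal = 6, L = 400)
  dc <- dating_config(topology = "fixed", fixed_tree = ds$tree,
                      n_iterations = 1500, thin = 10)
  dat <- list(alignment = ds$alignment, samples = ds$samples)
  ch1 <- run_chain(dat, dc, seed = 5)
  ch2 <- run_chain(dat, dc, seed = 5)
  expect_identical(ch1$trace, ch2$trace)
  ch3 <- run_chain(dat, dc, seed = 6)
  expect_false(identical(ch3$trace, ch1$trace))
  expect_error(run_chain(dat, dc), "seed")

  # finite log-posterior at every retained state; iterations increasing
  expect_true(all(is.finite(ch1$trace$log_posterior)))
  expect_true(all(diff(ch1$trace$iteration) > 0))
  # acceptance rates strictly inside (0, 1) for the workhorse moves
  for (mv in c("clock", "updown", "node", "tip_window")) {
    a <- ch1$acceptance[[mv]]
    expect_gt(a$accepted, 0)
    expect_lt(a$accepted, a$proposed)
  }
  # undated tip ages respect their prior bounds throughout
  expect_true(all(ch1$trace$age_und01 >= 1e3 & ch1$trace$age_und01 <= 2e6))

  # topology sampling keeps valid trees (smoke, stores trees)
  dc2 <- dating_config(topology = "sample", n_iterations = 800, thin = 20,
                       store_trees = TRUE)
  ch4 <- run_chain(dat, dc2, seed = 7)
  for (tr in ch4$trees) expect_silent(tipdater:::validate_time_tree(tr))
})

test_that("two seeds agree on the posterior root age (MH smoke test)", {
  ds <- tiny_dataset(seed = 29, n_cal = 3, n_und = 0, L = 300)
  dc <- dating_config(topology = "fixed", fixed_tree = ds$tree,
                      n_iterations = 6000, thin = 10)
  dat <- list(alignment = ds$alignment, samples = ds$samples)
  ch1 <- run_chain(dat, dc, seed = 31)
  ch2 <- run_chain(dat, dc, seed = 32)
  m1 <- mean(ch1$trace$root_age); m2 <- mean(ch2$trace$root_age)
  se <- sqrt(sd(ch1$trace$root_age)^2 /
               effective_sample_size(ch1$trace$root_age) +
             sd(ch2$trace$root_age)^2 /
               effective_sample_size(ch2$trace$root_age))
  expect_lt(abs(m1 - m2), 3 * se)
})
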