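# Desk-scale protocol runs: tiny alignments and short chains keep this file
# fast; statistical quality of the estimates is exercised in the acceptance
# suite.

quick_config <- function(...) {
  dating_config(topology = "fixed", n_iterations = 2500, thin = 10, ...)
}

test_that("single-sample dating enforces its contracts", {
  ds <- tiny_dataset(seed = 33, n_cal = 6, L = 400)
  expect_error(single_sample_date(ds$alignment, ds$samples, "cal01",
                                  quick_config(), seeds = c(1, 2),
                                  true_tree = ds$tree), "not undated")
  expect_error(single_sample_date(ds$alignment, ds$samples, "nope",
                                  quick_config(), seeds = c(1, 2),
                                  true_tree = ds$tree), "unknown")
  est <- single_sample_date(ds$alignment, ds$samples, "und01",
                            quick_config(), seeds = c(11, 12),
                            true_tree = ds$tree)
  expect_identical(est$sample_id, "und01")
  expect_true(est$hpd_lo <= est$mean && est$mean <= est$hpd_hi)
  expect_true(est$hpd_lo >= 1e3 && est$hpd_hi <= 2e6)
  expect_true(is.logical(est$unimodal) && is.logical(est$converged))
  prov <- attr(est, "provenance")
  expect_identical(prov$seeds, c(11, 12))

  # identical chain seeds: averaging is idempotent, estimate == either chain
  est2 <- single_sample_date(ds$alignment, ds$samples, "und01",
                             quick_config(), seeds = c(11, 11),
                             true_tree = ds$tree)
  pc <- attr(est2, "per_chain")
  expect_equal(est2$mean, pc[[1]]$mean)
  expect_equal(est2$hpd_lo, pc[[1]]$hpd_lo)
  expect_equal(est2$hpd_hi, pc[[1]]$hpd_hi)
})

test_that("single-sample estimates ignore other undated samples", {
  # by construction the other undated tips are excluded; dating und01 in a
  # 2-undated dataset must match dating it after deleting und02 entirely
  ds <- tiny_dataset(seed = 34, n_cal = 6, n_und = 2, L = 400)
  est_a <- single_sample_date(ds$alignment, ds$samples, "und01",
                              quick_config(), seeds = c(21, 22),
                              true_tree = ds$tree)
  keep <- ds$samples$sample_id != "und02"
  aln2 <- ds$alignment
  aln2$seqs <- aln2$seqs[ds$samples$sample_id[keep], , drop = FALSE]
  est_b <- single_sample_date(aln2, ds$samples[keep, ], "und01",
                              quick_config(),
                              seeds = c(21, 22),
                              true_tree = prune_time_tree(ds$tree,
                                ds$samples$sample_id[keep]))
  expect_equal(est_a$mean, est_b$mean)
  expect_equal(est_a$hpd_lo, est_b$hpd_lo)
})

test_that("multi-sample dating extracts every focal tip from one run", {
  ds <- tiny_dataset(seed = 35, n_cal = 6, n_und = 3, L = 400)
  ids <- c("und01", "und02", "und03")
  est <- multi_sample_date(ds$alignment, ds$samples, ids, quick_config(),
                           seeds = c(41, 42), true_tree = ds$tree)
  expect_identical(est$sample_id, ids)
  expect_identical(nrow(est), 3L)
  expect_true(all(est$hpd_lo >= 1e3 & est$hpd_hi <= 2e6))
  expect_error(multi_sample_date(ds$alignment, ds$samples, character(0),
                                 quick_config(), seeds = c(1, 2)),
               "at least one")
  expect_error(multi_sample_date(ds$alignment, ds$samples,
                                 c("und01", "cal01"), quick_config(),
                                 seeds = c(1, 2), true_tree = ds$tree),
               "undated")
})

test_that("the bias experiment is bookkept correctly", {
  gen <- study_config(n_calibrated = 5, n_undated = 2, n_outgroup = 2,
                      L = 300)
  res <- bias_experiment(gen, m_values = 1:2, replicates = 2,
                         config = dating_config(topology = "fixed",
                                                n_iterations = 1200,
                                                thin = 10),
                         seed = 51)
  expect_identical(nrow(res), 2L * (1L + 2L))     # replicates x sum(m)
  expect_true(all(res$m %in% 1:2))
  expect_true(all(c("single_mean", "multi_mean", "true_age") %in%
                    names(res)))
  # at m = 1 single and multi estimate the same quantity on the same tip
  m1 <- res[res$m == 1, ]
  expect_true(all(abs(m1$single_mean - m1$multi_mean) <
                    0.9 * (2e6 - 1e3)))           # same support, same scale
  expect_error(bias_experiment(gen, m_values = 1:3, replicates = 1,
                               seed = 1), "at least")
})

test_that("held-out validation reports coverage and impossibility", {
  ds <- tiny_dataset(seed = 36, n_cal = 8, L = 400)
  v <- validate_known_age(ds$alignment, ds$samples, c("cal01", "cal02"),
                          quick_config(), seed = 61, true_tree = ds$tree)
  expect_identical(nrow(v$table), 2L)
  expect_true(all(!v$table$impossible))
  expect_true(v$coverage >= 0 && v$coverage <= 1)
  # a held-out tip whose true age is outside the prior bounds is flagged
  expect_warning(
    v2 <- validate_known_age(ds$alignment, ds$samples, "cal03",
                             quick_config(), seed = 62,
                             true_tree = ds$tree,
                             bounds = c(1e6, 2e6)),
    "impossible")
  expect_true(v2$table$impossible[1])
  expect_true(is.na(v2$coverage))
  expect_error(validate_known_age(ds$alignment, ds$samples, "ghost",
                                  quick_config(), seed = 1), "not in")
})

test_that("the joint phylogeny honours fixed tips and refuses bad input", {
  ds <- tiny_dataset(seed = 37, n_cal = 5, L = 400)
  est <- data.frame(sample_id = "und01", mean = 4e5, hpd_lo = 4e5,
                    hpd_hi = 4e5, ess = 500, unimodal = TRUE,
                    converged = TRUE, reliable = TRUE)
  cfg <- dating_config(topology = "sample", n_iterations = 1500, thin = 15)
  jp <- joint_phylogeny(ds$alignment, ds$samples, est, cfg,
                        seeds = c(71, 72))
  # zero-width uncertainty: the tip is fixed at its estimate in every tree
  ages <- tip_ages(jp$tree)
  expect_equal(ages[["und01"]], 4e5)
  expect_setequal(names(ages), ds$samples$sample_id)
  fixed <- ds$samples$sample_id[ds$samples$age_status == "calibrated_fixed"]
  expect_equal(ages[fixed],
               stats::setNames(ds$samples$fixed_age[match(fixed,
                 ds$samples$sample_id)], fixed))
  expect_true(all(jp$annotations$support > 0 & jp$annotations$support <= 1))

  expect_error(joint_phylogeny(ds$alignment, ds$samples,
                               est[0, ], cfg, seeds = c(1, 2)),
               "no estimate")
  flagged <- est; flagged$reliable <- FALSE
  expect_error(joint_phylogeny(ds$alignment, ds$samples, flagged, cfg,
                               seeds = c(1, 2)), "force")
  # force pushes through flagged estimates
  jp2 <- joint_phylogeny(ds$alignment, ds$samples, flagged, cfg,
                         seeds = c(73, 74), force = TRUE)
  expect_identical(jp2$tree$n_tip, ds$tree$n_tip)
})
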