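#' Prune a dated tree to a subset of tips
#'
#' Drops all other tips; internal nodes left with one child collapse away
#' (their branch durations merge), preserving all remaining node ages.
#'
#' @param tree a [time_tree()].
#' @param keep tip labels to retain (>= 2).
#' @return the pruned [time_tree()].
#' @export
prune_time_tree <- function(tree, keep) {
  stopifnot(all(keep %in% tree$tip_label))
  if (setequal(keep, tree$tip_label)) return(tree)
  phy <- as_phylo(tree)
  phy2 <- ape::drop.tip(phy, setdiff(tree$tip_label, keep))
  as_time_tree(phy2, tip_ages(tree)[phy2$tip.label])
}

# derive k reproducible sub-seeds from one master seed
derive_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

chain_pair <- function(dataset, config, seeds) {
  stopifnot(length(seeds) >= 2L)
  list(run_chain(dataset, config, seed = seeds[1]),
       run_chain(dataset, config, seed = seeds[2]))
}

# per-sample estimate from a pair of chains. Default follows the study's
# averaging rule: final mean and HPD endpoints are the averages of the two
# chains'. pool_chains = TRUE instead summarises the pooled trace, which is
# statistically preferable when desk-scale chains fall short of the ESS bar
# (averaged endpoints of two disagreeing chains understate the posterior
# spread).
summarize_tip_estimate <- function(chain_a, chain_b, sample_id,
                                   min_ess = 200, pool_chains = FALSE) {
  col <- paste0("age_", sample_id)
  for (tr in list(chain_a$trace, chain_b$trace))
    if (!col %in% names(tr)) stop("no sampled ages for ", sample_id)
  a <- chain_a$trace[[col]]; b <- chain_b$trace[[col]]
  per_chain <- lapply(list(a, b), function(x) {
    h <- hpd_interval(x)
    list(mean = mean(x), hpd_lo = h[[1]], hpd_hi = h[[2]],
         ess = effective_sample_size(x))
  })
  conv <- check_convergence(chain_a$trace, chain_b$trace, col,
                            min_ess = min_ess)
  uni <- unimodality_check(c(a, b))
  if (pool_chains) {
    h <- hpd_interval(c(a, b))
    est_mean <- mean(c(a, b)); est_lo <- h[[1]]; est_hi <- h[[2]]
  } else {
    est_mean <- mean(vapply(per_chain, `[[`, numeric(1), "mean"))
    est_lo <- mean(vapply(per_chain, `[[`, numeric(1), "hpd_lo"))
    est_hi <- mean(vapply(per_chain, `[[`, numeric(1), "hpd_hi"))
  }
  est <- data.frame(
    sample_id = sample_id,
    mean = est_mean, hpd_lo = est_lo, hpd_hi = est_hi,
    ess = min(vapply(per_chain, `[[`, numeric(1), "ess")),
    unimodal = uni, converged = conv$pass,
    reliable = conv$pass && uni,
    stringsAsFactors = FALSE)
  attr(est, "per_chain") <- per_chain
  attr(est, "psrf") <- conv$psrf
  est
}

protocol_provenance <- function(config, seeds) {
  list(config_hash = config_hash(config[setdiff(names(config), "fixed_tree")]),
       seeds = seeds)
}

# reference subset for dating runs: calibrated + outgroup + the focal tips
dating_subset <- function(samples, focal_ids) {
  keep <- samples$age_status %in% c("calibrated_fixed", "outgroup_modern") |
    samples$sample_id %in% focal_ids
  samples[keep, , drop = FALSE]
}

prepare_run <- function(alignment, samples, config, true_tree) {
  aln <- alignment
  aln$seqs <- aln$seqs[samples$sample_id, , drop = FALSE]
  if (config$topology == "fixed") {
    if (is.null(config$fixed_tree)) {
      if (is.null(true_tree))
        stop("fixed-topology dating needs true_tree or config$fixed_tree")
      config$fixed_tree <- prune_time_tree(true_tree, samples$sample_id)
    } else {
      config$fixed_tree <- prune_time_tree(config$fixed_tree,
                                           samples$sample_id)
    }
  }
  list(dataset = list(alignment = aln, samples = samples), config = config)
}

#' Single-sample molecular-clock dating
#'
#' Dates one undated sample against the calibrated reference set: the
#' focal sample is merged with all calibrated and outgroup samples (all
#' other undated samples are excluded by construction), two independent
#' MCMC chains are run, and the estimate passes only if both chains reach
#' ESS > 200, the chain pair converges, and the pooled age posterior is
#' unimodal. The final mean is the average of the two chain means and the
#' final 95% HPD endpoints are the averages of the two chains' endpoints.
#' Failed diagnostics are propagated as flags, never dropped silently.
#'
#' @param alignment a [partitioned_alignment()].
#' @param samples sample table covering all alignment rows.
#' @param focal_id id of the undated sample to date.
#' @param config a [dating_config()].
#' @param seeds integer vector of two chain seeds.
#' @param true_tree optional [time_tree()] providing the fixed topology
#'   when `config$topology == "fixed"`.
#' @param pool_chains summarise the pooled trace of the chain pair instead
#'   of averaging the two chains' means and HPD endpoints (the study's
#'   rule, the default). Pooling is statistically preferable when
#'   desk-scale chains fall short of the ESS threshold.
#' @return one-row data frame: `sample_id`, `mean`, `hpd_lo`, `hpd_hi`,
#'   `ess`, `unimodal`, `converged`, `reliable`; per-chain summaries in
#'   the `per_chain` attribute and provenance (config hash, seeds, psrf)
#'   in attributes.
#' @export
single_sample_date <- function(alignment, samples, focal_id, config, seeds,
                               true_tree = NULL, pool_chains = FALSE) {
  samples <- validate_sample_table(samples)
  row <- samples[samples$sample_id == focal_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown focal sample: ", focal_id)
  if (row$age_status != "undated")
    stop("focal sample is not undated: ", focal_id)
  sub <- dating_subset(samples, focal_id)
  pr <- prepare_run(alignment, sub, config, true_tree)
  chains <- chain_pair(pr$dataset, pr$config, seeds)
  est <- summarize_tip_estimate(chains[[1]], chains[[2]], focal_id,
                                pool_chains = pool_chains)
  attr(est, "provenance") <- protocol_provenance(config, seeds)
  attr(est, "traces") <- list(chains[[1]]$trace, chains[[2]]$trace)
  est
}

#' Multi-sample molecular-clock dating
#'
#' Dates several undated samples jointly in one MCMC (the design whose
#' age estimates are biased older as more old undated samples are
#' included; see [bias_experiment()]). Per-sample estimates are extracted
#' from the same chain pair with the same averaging and diagnostics as
#' [single_sample_date()].
#'
#' @inheritParams single_sample_date
#' @param focal_ids ids of the undated samples to date jointly.
#' @return data frame with one row per focal sample (columns as in
#'   [single_sample_date()]).
#' @export
multi_sample_date <- function(alignment, samples, focal_ids, config, seeds,
                              true_tree = NULL, pool_chains = FALSE) {
  samples <- validate_sample_table(samples)
  if (!length(focal_ids)) stop("need at least one focal sample")
  st <- samples$age_status[match(focal_ids, samples$sample_id)]
  if (anyNA(st)) stop("unknown focal sample(s)")
  if (!all(st == "undated")) stop("all focal samples must be undated")
  sub <- dating_subset(samples, focal_ids)
  pr <- prepare_run(alignment, sub, config, true_tree)
  chains <- chain_pair(pr$dataset, pr$config, seeds)
  out <- do.call(rbind, lapply(focal_ids, function(id)
    summarize_tip_estimate(chains[[1]], chains[[2]], id,
                           pool_chains = pool_chains)))
  attr(out, "provenance") <- protocol_provenance(config, seeds)
  attr(out, "traces") <- list(chains[[1]]$trace, chains[[2]]$trace)
  out
}

#' Sequential multi-sample dating-bias experiment
#'
#' Emulates the study's bias test: on each synthetic replicate the `m`
#' oldest undated tips (by true simulated age) are dated jointly
#' (multi-sample) and each one individually (single-sample), for each
#' `m` in `m_values`. The reported finding is a directional bias of the
#' multi-sample estimates toward older ages as `m` grows.
#'
#' @param gen_config a [study_config()] whose `n_undated` is at least
#'   `max(m_values)`.
#' @param m_values numbers of jointly dated old undated tips.
#' @param replicates number of synthetic replicates.
#' @param config a [dating_config()].
#' @param seed master seed; per-replicate dataset and chain seeds derive
#'   from it.
#' @return data frame with columns `replicate`, `m`, `sample_id`,
#'   `single_mean`, `multi_mean`, `true_age`.
#' @export
bias_experiment <- function(gen_config, m_values = 1:5, replicates = 10L,
                            config = dating_config(), seed) {
  if (missing(seed)) stop("an explicit integer seed is required")
  m_max <- max(m_values)
  if (gen_config$n_undated < m_max)
    stop("generator must produce at least max(m_values) undated tips")
  seeds <- derive_seeds(seed, replicates * (2L + 2L * m_max + 2L * length(m_values)))
  si <- 0L
  take <- function(k) { si <<- si + k; seeds[(si - k + 1L):si] }
  rows <- list()
  for (r in seq_len(replicates)) {
    ds <- make_study_dataset(gen_config, seed = take(1L))
    und <- ds$truth[grepl("^und", ds$truth$sample_id), ]
    und <- und[order(-und$true_age), ]
    oldest <- und$sample_id[seq_len(m_max)]
    singles <- lapply(oldest, function(id)
      single_sample_date(ds$alignment, ds$samples, id, config,
                         seeds = take(2L), true_tree = ds$tree))
    names(singles) <- oldest
    take(1L)  # reserved
    for (m in m_values) {
      ids <- oldest[seq_len(m)]
      multi <- multi_sample_date(ds$alignment, ds$samples, ids, config,
                                 seeds = take(2L), true_tree = ds$tree)
      for (id in ids) {
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, m = m, sample_id = id,
          single_mean = singles[[id]]$mean,
          multi_mean = multi$mean[multi$sample_id == id],
          true_age = und$true_age[und$sample_id == id])
      }
    }
  }
  do.call(rbind, rows)
}

#' Held-out-age validation of single-sample dating
#'
#' Mirrors the study's accuracy check: samples with known (calibrated)
#' ages are removed from the reference set, re-dated as if undated under
#' a uniform age prior, and the fraction whose known age falls inside the
#' final 95% HPD is reported. A held-out sample whose true age lies
#' outside the uniform prior bounds cannot be recovered and is flagged
#' `impossible` and excluded (with a warning) from the coverage fraction.
#'
#' @inheritParams single_sample_date
#' @param heldout_ids ids of calibrated samples to hold out.
#' @param bounds uniform prior bounds used for the held-out tips
#'   (years BP).
#' @param seed master seed (chain seeds derive from it).
#' @return list with `table` (per sample: `sample_id`, `true_age`,
#'   `mean`, `hpd_lo`, `hpd_hi`, `inside_hpd`, `reliable`, `impossible`)
#'   and `coverage` (fraction of non-impossible held-out samples whose
#'   true age is inside the HPD).
#' @export
validate_known_age <- function(alignment, samples, heldout_ids, config,
                               seed, bounds = c(1e3, 2e6),
                               true_tree = NULL) {
  if (missing(seed)) stop("an explicit integer seed is required")
  samples <- validate_sample_table(samples)
  idx <- match(heldout_ids, samples$sample_id)
  if (anyNA(idx)) stop("held-out id(s) not in the sample table")
  if (!all(samples$age_status[idx] == "calibrated_fixed"))
    stop("held-out samples must have known (calibrated) ages")
  true_ages <- samples$fixed_age[idx]
  masked <- samples
  masked$age_status[idx] <- "undated"
  masked$prior_lo[idx] <- bounds[1]; masked$prior_hi[idx] <- bounds[2]
  masked$fixed_age[idx] <- NA
  seeds <- derive_seeds(seed, 2L * length(heldout_ids))
  out <- list()
  for (i in seq_along(heldout_ids)) {
    id <- heldout_ids[i]
    truth <- true_ages[i]
    if (truth < bounds[1] || truth > bounds[2]) {
      warning("held-out sample ", id, " has true age outside the prior ",
              "bounds; flagged impossible and excluded")
      out[[i]] <- data.frame(sample_id = id, true_age = truth,
                             mean = NA_real_, hpd_lo = NA_real_,
                             hpd_hi = NA_real_, inside_hpd = NA,
                             reliable = NA, impossible = TRUE)
      next
    }
    est <- single_sample_date(alignment, masked, id, config,
                              seeds = seeds[(2L * i - 1L):(2L * i)],
                              true_tree = true_tree)
    out[[i]] <- data.frame(sample_id = id, true_age = truth,
                           mean = est$mean, hpd_lo = est$hpd_lo,
                           hpd_hi = est$hpd_hi,
                           inside_hpd = truth >= est$hpd_lo &
                             truth <= est$hpd_hi,
                           reliable = est$reliable, impossible = FALSE)
  }
  tab <- do.call(rbind, out)
  ok <- !tab$impossible
  list(table = tab,
       coverage = if (any(ok)) mean(tab$inside_hpd[ok]) else NA_real_)
}

#' Joint phylogeny with estimated tip dates as input
#'
#' The study's final tree: calibrated tips stay fixed, formerly undated
#' tips receive uniform age priors spanning their single-sample 95% HPD
#' (a zero-width interval fixes the tip at its mean), a joint MCMC pair
#' is run with tree sampling, and the pooled post-burn-in tree sample is
#' summarised as a maximum clade credibility tree with node-height mean
#' and 95% HPD annotations.
#'
#' @inheritParams single_sample_date
#' @param estimates data frame of tip-date estimates (as returned by
#'   [single_sample_date()]/[multi_sample_date()]) covering every undated
#'   sample.
#' @param force proceed even when some estimates carry failed-diagnostic
#'   flags.
#' @return the [mcc_tree()] summary list, with provenance attributes.
#' @export
joint_phylogeny <- function(alignment, samples, estimates, config, seeds,
                            force = FALSE, true_tree = NULL) {
  samples <- validate_sample_table(samples)
  und <- samples$sample_id[samples$age_status == "undated"]
  missing <- setdiff(und, estimates$sample_id)
  if (length(missing))
    stop("no estimate for undated sample(s): ", paste(missing, collapse = ", "))
  if (!force && "reliable" %in% names(estimates) &&
      !all(estimates$reliable[estimates$sample_id %in% und]))
    stop("some estimates carry failed diagnostics; rerun or use force = TRUE")
  tab <- samples
  for (id in und) {
    e <- estimates[estimates$sample_id == id, ]
    i <- which(tab$sample_id == id)
    if (e$hpd_lo >= e$hpd_hi) {       # zero-width: fix the tip
      tab$age_status[i] <- "calibrated_fixed"
      tab$fixed_age[i] <- e$mean
      tab$prior_lo[i] <- NA; tab$prior_hi[i] <- NA
    } else {
      tab$prior_lo[i] <- e$hpd_lo; tab$prior_hi[i] <- e$hpd_hi
    }
  }
  config$store_trees <- TRUE
  pr <- prepare_run(alignment, tab, config, true_tree)
  chains <- chain_pair(pr$dataset, pr$config, seeds)
  trees <- c(chains[[1]]$trees, chains[[2]]$trees)
  out <- mcc_tree(trees)
  attr(out, "provenance") <- protocol_provenance(config, seeds)
  attr(out, "chains") <- list(chains[[1]]$trace, chains[[2]]$trace)
  out
}
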