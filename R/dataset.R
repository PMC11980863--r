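#' Configuration of the synthetic study dataset
#'
#' The generator emulates a heterochronous mitogenome tip-dating dataset:
#' radiocarbon-calibrated ingroup tips spread over the last 50 kyr,
#' deep-time undated tips with true ages up to ~1.3 Ma, and a present-day
#' outgroup clade whose split from the ingroup is drawn from the same
#' log-normal law (real-space median 5.3 Ma) used as the root calibration
#' in the dating model. Sequences evolve under a strict clock with
#' six partitions (tRNA, rRNA, three codon positions, control region);
#' the tRNA partition is HKY+I, all others HKY+Gamma+I.
#'
#' @param n_calibrated,n_undated,n_outgroup tip counts.
#' @param L alignment length in bp.
#' @param calibrated_age_range,undated_age_range uniform ranges (years BP)
#'   for the true tip ages.
#' @param Ne,Ne_outgroup constant effective sizes (pairwise-coalescence
#'   years) of the ingroup and outgroup genealogies; `demog` may instead
#'   supply a full [demographic_model()] for the ingroup.
#' @param root_median,root_sdlog log-normal law of the outgroup split age.
#' @param clock_rate true strict-clock rate, substitutions/site/year.
#' @param kappa,gamma_shape,p_inv,n_categories substitution parameters
#'   shared by all partitions (the tRNA partition drops the Gamma).
#' @param relative_rates named per-partition rate multipliers; rescaled to
#'   column-count weighted mean 1 for the realised layout.
#' @param tip_prior_lo,tip_prior_hi uniform age-prior bounds written into
#'   the sample table for undated tips (study default 1 ka to 2 Ma).
#' @param demog optional ingroup [demographic_model()] overriding `Ne`.
#' @return a `study_config` list.
#' @export
study_config <- function(n_calibrated = 20L, n_undated = 1L, n_outgroup = 2L,
                         L = 16500L,
                         calibrated_age_range = c(0, 50e3),
                         undated_age_range = c(50e3, 1.3e6),
                         Ne = 250e3, Ne_outgroup = 500e3,
                         root_median = 5.3e6, root_sdlog = 0.05,
                         clock_rate = 2.5e-8,
                         kappa = 25, gamma_shape = 0.4, p_inv = 0.3,
                         n_categories = 4L,
                         relative_rates = c(tRNA = 0.5, rRNA = 0.6,
                                            codon1 = 0.7, codon2 = 0.35,
                                            codon3 = 2.2, control_region = 2.5),
                         tip_prior_lo = 1e3, tip_prior_hi = 2e6,
                         demog = NULL) {
  stopifnot(n_calibrated + n_undated >= 2L, n_outgroup >= 1L, L >= 60L,
            n_undated >= 0L, clock_rate > 0)
  if (is.null(demog)) demog <- demographic_model(Ne = Ne)
  structure(list(n_calibrated = n_calibrated, n_undated = n_undated,
                 n_outgroup = n_outgroup, L = as.integer(L),
                 calibrated_age_range = calibrated_age_range,
                 undated_age_range = undated_age_range,
                 demog = demog, Ne_outgroup = Ne_outgroup,
                 root_median = root_median, root_sdlog = root_sdlog,
                 clock_rate = clock_rate, kappa = kappa,
                 gamma_shape = gamma_shape, p_inv = p_inv,
                 n_categories = as.integer(n_categories),
                 relative_rates = relative_rates,
                 tip_prior_lo = tip_prior_lo, tip_prior_hi = tip_prior_hi),
            class = "study_config")
}

#' Default mitogenome-like annotation layout
#'
#' A six-partition annotation scaled to length `L`, mimicking a
#' mitochondrial genome: interleaved tRNA blocks, an rRNA block, two
#' large CDS blocks (codon phase anchored at each block's own start) and
#' a terminal control region containing a VNTR interval.
#'
#' @param L reference length in bp (>= 60).
#' @return annotation data frame (`feature_class`, `start`, `end`,
#'   `codon_phase_origin`).
#' @export
default_annotation <- function(L = 16500L) {
  stopifnot(L >= 60L)
  frac <- c(tRNA1 = 0.02, rRNA = 0.15, tRNA2 = 0.03, CDS1 = 0.34,
            tRNA3 = 0.02, CDS2 = 0.34, tRNA4 = 0.02, control_region = 0.08)
  ends <- round(cumsum(frac) / sum(frac) * L)
  starts <- c(1, utils::head(ends, -1) + 1)
  cls <- c("tRNA", "rRNA", "tRNA", "CDS", "tRNA", "CDS", "tRNA",
           "control_region")
  tab <- data.frame(feature_class = cls, start = starts, end = ends,
                    codon_phase_origin = ifelse(cls == "CDS", starts, NA),
                    stringsAsFactors = FALSE)
  # trim CDS blocks to whole codons
  for (i in which(tab$feature_class == "CDS")) {
    len <- tab$end[i] - tab$start[i] + 1
    tab$end[i] <- tab$start[i] + (len %/% 3) * 3 - 1
  }
  cr <- which(tab$feature_class == "control_region")
  vlen <- max(3, round(0.25 * (tab$end[cr] - tab$start[cr] + 1)))
  vstart <- tab$start[cr] + round(0.4 * (tab$end[cr] - tab$start[cr] + 1))
  tab <- rbind(tab, data.frame(feature_class = "VNTR", start = vstart,
                               end = min(tab$end[cr], vstart + vlen - 1),
                               codon_phase_origin = NA))
  validate_annotation(tab)
}

# column -> partition labels for a gap-free reference of length L
partition_layout <- function(annotation, L) {
  lab <- rep("unassigned", L)
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i, ]
    if (a$feature_class == "VNTR") next
    span <- a$start:a$end
    if (a$feature_class == "CDS") {
      lab[span] <- paste0("codon", (span - a$codon_phase_origin) %% 3 + 1)
    } else {
      lab[span] <- a$feature_class
    }
  }
  v <- annotation[annotation$feature_class == "VNTR", , drop = FALSE]
  for (i in seq_len(nrow(v))) lab[v$start[i]:v$end[i]] <- "masked"
  lab
}

# per-partition substitution models implied by a study_config and layout
study_models <- function(config, partition) {
  parts <- setdiff(unique(partition), c("masked", "unassigned"))
  ncol_part <- vapply(parts, function(p) sum(partition == p), numeric(1))
  rel <- config$relative_rates[parts]
  if (anyNA(rel)) stop("relative_rates must cover all partitions in the layout")
  rel <- rel * sum(ncol_part) / sum(rel * ncol_part)   # weighted mean 1
  models <- list()
  for (p in parts) {
    models[[p]] <- substitution_params(
      kappa = config$kappa, freqs = c(0.31, 0.26, 0.14, 0.29),
      gamma_shape = if (p == "tRNA") NA_real_ else config$gamma_shape,
      n_categories = config$n_categories,
      p_inv = config$p_inv, relative_rate = rel[[p]])
  }
  models
}

# graft two dated subtrees (or a subtree and nothing) under a new root
join_time_trees <- function(tree_a, tree_b, root_age) {
  na <- tree_a$n_tip; nb <- tree_b$n_tip
  n <- na + nb
  map_a <- c(seq_len(na), n + 1L + seq_len(na - 1L))
  map_b <- c(na + seq_len(nb),
             if (nb > 1L) n + na + seq_len(nb - 1L) else integer(0))
  edge <- rbind(cbind(map_a[tree_a$edge[, 1L]], map_a[tree_a$edge[, 2L]]),
                if (nb > 1L) cbind(map_b[tree_b$edge[, 1L]],
                                   map_b[tree_b$edge[, 2L]]))
  root_a <- map_a[na + 1L]
  root_b <- if (nb > 1L) map_b[nb + 1L] else map_b[1L]
  edge <- rbind(edge, c(n + 1L, root_a), c(n + 1L, root_b))
  age <- numeric(2L * n - 1L)
  age[map_a] <- tree_a$age
  age[map_b] <- tree_b$age
  age[n + 1L] <- root_age
  # the new root is n+1; remap so internal numbering is n+1..2n-1 (it is)
  time_tree(edge, c(tree_a$tip_label, tree_b$tip_label), age)
}

#' Generate a synthetic tip-dating study dataset with known truth
#'
#' Simulates a dated genealogy (ingroup coalescent + present-day outgroup
#' clade splitting near 5.3 Ma), evolves a partitioned alignment under a
#' strict clock, and returns the pieces a dating analysis consumes: the
#' alignment, a sample table in which the undated tips' true ages are
#' hidden behind the uniform prior bounds, the true tree, and a truth
#' table for recovery checks.
#'
#' @param config a [study_config()].
#' @param seed integer RNG seed (required).
#' @return list with elements `alignment` (a [partitioned_alignment()]),
#'   `samples` (sample-table data frame), `tree` (true [time_tree()]),
#'   `truth` (data frame of true tip ages, with the true model parameters
#'   attached as attributes `clock_rate`, `models`, `demog`,
#'   `root_split_age`) and `annotation`.
#' @export
make_study_dataset <- function(config = study_config(), seed) {
  if (missing(seed)) stop("an explicit integer seed is required")
  stopifnot(inherits(config, "study_config"))
  if (config$n_undated > config$n_undated + config$n_calibrated)
    stop("more undated tips than total ingroup tips")
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max, 8L)
  n_cal <- config$n_calibrated; n_und <- config$n_undated
  cal_ages <- stats::runif(n_cal, config$calibrated_age_range[1],
                           config$calibrated_age_range[2])
  und_ages <- stats::runif(n_und, config$undated_age_range[1],
                           config$undated_age_range[2])
  ing_labels <- c(sprintf("cal%02d", seq_len(n_cal)),
                  if (n_und) sprintf("und%02d", seq_len(n_und)))
  ing_ages <- stats::setNames(c(cal_ages, und_ages), ing_labels)
  ingroup <- simulate_genealogy(ing_ages, config$demog, seed = sub[1])
  og_labels <- sprintf("og%02d", seq_len(config$n_outgroup))
  outgroup <- if (config$n_outgroup > 1L) {
    simulate_genealogy(stats::setNames(rep(0, config$n_outgroup), og_labels),
                       demographic_model(Ne = config$Ne_outgroup),
                       seed = sub[2])
  } else {
    structure(list(edge = matrix(0L, 0L, 2L), tip_label = og_labels,
                   age = 0, n_tip = 1L), class = "time_tree_stub")
  }
  set.seed(sub[3])
  floor_age <- max(root_age(ingroup),
                   if (config$n_outgroup > 1L) root_age(outgroup) else 0)
  repeat {
    split_age <- stats::rlnorm(1, meanlog = log(config$root_median),
                               sdlog = config$root_sdlog)
    if (split_age > floor_age) break
  }
  og <- if (config$n_outgroup > 1L) outgroup else
    list(edge = matrix(0L, 0L, 2L), tip_label = og_labels, age = 0, n_tip = 1L)
  tree <- join_time_trees(ingroup, og, split_age)
  annotation <- default_annotation(config$L)
  partition <- partition_layout(annotation, config$L)
  models <- study_models(config, partition)
  aln <- simulate_alignment(tree, partition, models, config$clock_rate,
                            seed = sub[4], reference_row_id = og_labels[1])
  samples <- data.frame(
    sample_id = tree$tip_label,
    age_status = c(rep("calibrated_fixed", n_cal), rep("undated", n_und),
                   rep("outgroup_modern", config$n_outgroup)),
    fixed_age = c(cal_ages, rep(NA, n_und), rep(0, config$n_outgroup)),
    prior_lo = c(rep(NA, n_cal), rep(config$tip_prior_lo, n_und),
                 rep(NA, config$n_outgroup)),
    prior_hi = c(rep(NA, n_cal), rep(config$tip_prior_hi, n_und),
                 rep(NA, config$n_outgroup)),
    stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = tree$tip_label,
                      true_age = tree$age[seq_len(tree$n_tip)],
                      stringsAsFactors = FALSE)
  attr(truth, "clock_rate") <- config$clock_rate
  attr(truth, "models") <- models
  attr(truth, "demog") <- config$demog
  attr(truth, "root_split_age") <- split_age
  list(alignment = aln, samples = validate_sample_table(samples),
       tree = tree, truth = truth, annotation = annotation)
}
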