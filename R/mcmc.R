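#' Model and sampler settings for a tip-dating analysis
#'
#' Collects everything [run_chain()] needs beyond the data: which
#' parameters are free, the tree prior, calibrations, vague parameter
#' priors, chain length and thinning. The defaults are a desk-scale
#' stand-in for the study design (two chains of one hundred million BEAST
#' iterations are not reproducible on a laptop): 20,000
#' Metropolis-Hastings proposals, thinning 20, 10% burn-in.
#'
#' @param topology `"sample"` to sample tree topology (narrow-exchange
#'   moves) or `"fixed"` to keep the starting topology.
#' @param fixed_tree optional [time_tree()] used as the (fixed or
#'   initial) tree; undated tip ages are re-initialised at their prior
#'   midpoints.
#' @param share_subst link kappa, Gamma shape and invariant proportion
#'   across partitions.
#' @param estimate_pinv,estimate_rel_rates free or fixed nuisance
#'   parameters.
#' @param gamma_tRNA if `FALSE` the tRNA partition uses HKY+I (no Gamma),
#'   as in the study model.
#' @param n_categories discrete Gamma categories.
#' @param demog_mode `"constant"` or `"grid"` coalescent.
#' @param grid_boundaries epoch boundaries (years BP) for grid mode.
#' @param structured_root if `TRUE`, the coalescent applies within the
#'   ingroup and within the outgroup clade separately (each with its own
#'   effective size), and the ingroup/outgroup split is governed by the
#'   root calibration alone. This matches the biological reality that the
#'   outgroups are distinct species rather than members of one panmictic
#'   population, and removes the upward bias in ingroup node heights that
#'   a single coalescent spanning a multi-million-year stem induces.
#'   Requires outgroup-flagged samples and fixed topology (the outgroup
#'   must stay monophyletic). Default `FALSE`: the single unstructured
#'   coalescent of the original study design.
#' @param root_median,root_sdlog log-normal root calibration (`NULL`
#'   median disables it).
#' @param priors a [parameter_priors()].
#' @param n_iterations,thin,burn_in_fraction chain length controls.
#' @param sample_from_prior force the likelihood to zero (prior-sampling
#'   validation mode).
#' @param store_trees retain thinned tree samples in the result.
#' @return a `dating_config` list.
#' @export
dating_config <- function(topology = c("sample", "fixed"), fixed_tree = NULL,
                          share_subst = TRUE, estimate_pinv = TRUE,
                          estimate_rel_rates = TRUE, gamma_tRNA = FALSE,
                          n_categories = 4L,
                          demog_mode = c("constant", "grid"),
                          grid_boundaries = NULL, structured_root = FALSE,
                          root_median = 5.3e6, root_sdlog = 0.05,
                          priors = parameter_priors(),
                          n_iterations = 20000L, thin = 20L,
                          burn_in_fraction = 0.1,
                          sample_from_prior = FALSE, store_trees = FALSE,
                          fix_subst = NULL) {
  topology <- match.arg(topology)
  demog_mode <- match.arg(demog_mode)
  if (demog_mode == "grid" && is.null(grid_boundaries))
    stop("grid demography needs grid_boundaries")
  # topology == "fixed" with no fixed_tree keeps the starting (UPGMA) topology
  structure(list(topology = topology, fixed_tree = fixed_tree,
                 share_subst = share_subst, estimate_pinv = estimate_pinv,
                 estimate_rel_rates = estimate_rel_rates,
                 gamma_tRNA = gamma_tRNA,
                 n_categories = as.integer(n_categories),
                 demog_mode = demog_mode, grid_boundaries = grid_boundaries,
                 structured_root = structured_root,
                 root_median = root_median, root_sdlog = root_sdlog,
                 priors = priors, n_iterations = as.integer(n_iterations),
                 thin = as.integer(thin),
                 burn_in_fraction = burn_in_fraction,
                 sample_from_prior = sample_from_prior,
                 store_trees = store_trees, fix_subst = fix_subst),
            class = "dating_config")
}

# push every ancestor strictly above its children (used after resetting
# undated tip ages at prior midpoints)
repair_node_ages <- function(tree, margin = 1) {
  rows <- postorder_edges(tree)
  for (i in rows) {
    p <- tree$edge[i, 1L]; c <- tree$edge[i, 2L]
    if (tree$age[p] <= tree$age[c]) tree$age[p] <- tree$age[c] + margin
  }
  tree
}

# UPGMA-like starting tree honouring tip ages; internal slack scaled so the
# root lands near `root_target`
init_tree <- function(aln_matrix, tip_age_init, root_target) {
  ids <- names(tip_age_init)
  m <- aln_matrix[ids, , drop = FALSE]
  n <- length(ids)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    ok <- m[i, ] %in% c("A", "C", "G", "T") & m[j, ] %in% c("A", "C", "G", "T")
    d[i, j] <- d[j, i] <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0.5
  }
  dimnames(d) <- list(ids, ids)
  phy <- ape::as.phylo(stats::hclust(stats::as.dist(d), method = "average"))
  edge <- phy$edge
  age <- numeric(2L * n - 1L)
  age[seq_len(n)] <- tip_age_init[phy$tip.label]
  assign_ages <- function(lambda) {
    a <- age
    tmp <- time_tree_skeleton(edge, n)
    for (i in tmp$postorder) {
      p <- edge[i, 1L]; c <- edge[i, 2L]
      a[p] <- max(a[p], a[c] + lambda)
    }
    a
  }
  lo <- 1; hi <- max(root_target, max(age) + 10)
  for (it in 1:60) {
    mid <- sqrt(lo * hi)
    r <- assign_ages(mid)[n + 1L]
    if (r < root_target) lo <- mid else hi <- mid
  }
  time_tree(edge, phy$tip.label, assign_ages(sqrt(lo * hi)))
}

# postorder rows for a bare edge matrix (before a time_tree exists)
time_tree_skeleton <- function(edge, n) {
  fake <- structure(list(edge = edge, tip_label = paste0("x", seq_len(n)),
                         age = numeric(2L * n - 1L), n_tip = n),
                    class = "time_tree")
  list(postorder = postorder_edges(fake))
}

new_move_stats <- function(names) {
  stats::setNames(lapply(names, function(x)
    list(proposed = 0L, accepted = 0L, tune = NA_real_)), names)
}

#' Run one Metropolis-Hastings tip-dating chain
#'
#' Samples tip ages of undated samples, internal node heights, topology
#' (optionally), the strict-clock rate, substitution parameters and the
#' coalescent demography from their joint posterior. The move schedule is
#' fixed: log-space scale moves on rate-like scalars, uniform-window and
#' scale moves on undated tip ages, uniform node-height slides within
#' parent/child bounds, a root-height scale, a mass-preserving exchange
#' on relative partition rates, and narrow-exchange topology moves.
#' Proposal scales are tuned toward ~23% acceptance during burn-in only.
#' The returned trace starts after the burn-in.
#'
#' @param dataset list with `alignment` (a [partitioned_alignment()]) and
#'   `samples` (a sample table, see [read_sample_table()]).
#' @param config a [dating_config()].
#' @param seed integer RNG seed (required).
#' @return an object of class `tip_chain`: list with `trace` (data
#'   frame), `trees` (list of sampled [time_tree()]s if requested),
#'   `acceptance` (per-move statistics), `final_state`, `seed` and
#'   `config_hash`.
#' @export
run_chain <- function(dataset, config = dating_config(), seed) {
  if (missing(seed)) stop("an explicit integer seed is required")
  stopifnot(inherits(config, "dating_config"))
  aln <- dataset$alignment
  tab <- validate_sample_table(dataset$samples)
  if (!all(tab$sample_id %in% rownames(aln$seqs)))
    stop("sample table contains ids missing from the alignment")
  set.seed(seed)

  undated <- tab[tab$age_status == "undated", , drop = FALSE]
  fixed_age <- stats::setNames(tab$fixed_age, tab$sample_id)
  tip_init <- ifelse(tab$age_status == "undated",
                     (tab$prior_lo + tab$prior_hi) / 2, tab$fixed_age)
  names(tip_init) <- tab$sample_id
  root_target <- if (!is.null(config$root_median)) config$root_median else
    2 * max(tip_init) + 1e4

  if (!is.null(config$fixed_tree)) {
    tree <- config$fixed_tree
    if (!setequal(tree$tip_label, tab$sample_id))
      stop("fixed_tree tips do not match the sample table")
    tree$age[seq_len(tree$n_tip)] <- tip_init[tree$tip_label]
    tree <- repair_node_ages(tree)
  } else {
    tree <- init_tree(aln$seqs, tip_init, root_target)
  }
  sample_topology <- config$topology == "sample"

  lik_data <- likelihood_data(aln, tree$tip_label)
  parts <- lik_data$partitions
  calib <- calibration_priors(
    root_median = config$root_median, root_sdlog = config$root_sdlog,
    tip_priors = stats::setNames(
      lapply(seq_len(nrow(undated)), function(i)
        c(undated$prior_lo[i], undated$prior_hi[i])),
      undated$sample_id))

  # --- initial state ----------------------------------------------------
  par <- list(clock = 2e-8, kappa = 10, alpha = 0.5,
              p_inv = if (config$estimate_pinv) 0.2 else 0,
              rel = stats::setNames(rep(1, length(parts)), parts))
  fixed_subst <- config$fix_subst       # pin substitution nuisance (tests)
  for (nm in intersect(names(fixed_subst), c("kappa", "alpha", "p_inv")))
    par[[nm]] <- fixed_subst[[nm]]
  if (!is.null(fixed_subst$rel)) par$rel[] <- fixed_subst$rel[parts]
  par$clock <- min(max(1e-10, par$clock), config$priors$clock_bounds[2])
  ne_init <- min(max(root_age(tree) / 4, config$priors$ne_bounds[1]),
                 config$priors$ne_bounds[2])
  demog <- if (config$demog_mode == "constant") {
    demographic_model(Ne = ne_init)
  } else {
    demographic_model(boundaries = config$grid_boundaries,
                      sizes = rep(ne_init,
                                  length(config$grid_boundaries) + 1L),
                      tau = 1)
  }
  par$ne_og <- ne_init

  # structured tree prior: classify nodes by clade once (fixed topology)
  structured <- isTRUE(config$structured_root)
  og_tips <- integer(0); ing_tips <- seq_len(tree$n_tip)
  ing_internal <- og_internal <- integer(0)
  if (structured) {
    if (sample_topology)
      stop("structured_root requires topology = \"fixed\"")
    if (is.null(config$root_median))
      stop("structured_root requires a root calibration")
    og_ids <- tab$sample_id[tab$age_status == "outgroup_modern"]
    og_tips <- which(tree$tip_label %in% og_ids)
    if (!length(og_tips))
      stop("structured_root requires outgroup_modern samples")
    ing_tips <- setdiff(seq_len(tree$n_tip), og_tips)
    if (length(ing_tips) < 2L) stop("structured_root needs >= 2 ingroup tips")
    n_node <- 2L * tree$n_tip - 1L
    n_desc <- n_og_desc <- integer(n_node)
    n_desc[seq_len(tree$n_tip)] <- 1L
    n_og_desc[og_tips] <- 1L
    for (i in postorder_edges(tree)) {
      pp <- tree$edge[i, 1L]; cc <- tree$edge[i, 2L]
      n_desc[pp] <- n_desc[pp] + n_desc[cc]
      n_og_desc[pp] <- n_og_desc[pp] + n_og_desc[cc]
    }
    internal_ids <- seq(tree$n_tip + 1L, n_node)
    ing_internal <- internal_ids[n_og_desc[internal_ids] == 0L]
    og_internal <- internal_ids[n_og_desc[internal_ids] ==
                                  n_desc[internal_ids]]
    if (length(ing_internal) != length(ing_tips) - 1L ||
        length(og_internal) != length(og_tips) - 1L)
      stop("structured_root requires a monophyletic outgroup clade")
  }

  # fast evaluators: parameters linked across partitions (one kappa, one
  # Gamma shape, one invariant proportion; tRNA drops the Gamma)
  gamma_flag <- vapply(parts, function(pt)
    !(pt == "tRNA" && !config$gamma_tRNA), logical(1))
  any_gamma <- any(gamma_flag)
  freqs_list <- lik_data$freqs[parts]
  tips_list <- lik_data$tips[parts]
  weights_list <- lik_data$weights[parts]
  n_parts <- length(parts)
  pri <- config$priors
  n_und <- nrow(undated)
  und_idx <- match(undated$sample_id, tree$tip_label)
  calib_lo <- undated$prior_lo
  calib_hi <- undated$prior_hi
  root_meanlog <- if (!is.null(config$root_median)) log(config$root_median)
  eval_prior <- function(tree, par, demog) {
    if (n_und) {
      a <- tree$age[und_idx]
      if (any(a < calib_lo | a > calib_hi)) return(-Inf)
    }
    if (par$clock < pri$clock_bounds[1] || par$clock > pri$clock_bounds[2])
      return(-Inf)
    if (par$p_inv < 0 || par$p_inv >= 1) return(-Inf)
    lp <- -log(par$clock) +
      stats::dlnorm(par$kappa, pri$kappa_meanlog, pri$kappa_sdlog, log = TRUE)
    if (any_gamma)
      lp <- lp + stats::dexp(par$alpha, rate = pri$alpha_rate, log = TRUE)
    if (demog$mode == "constant") {
      if (demog$Ne < pri$ne_bounds[1] || demog$Ne > pri$ne_bounds[2])
        return(-Inf)
      lp <- lp - log(demog$Ne)
    } else {
      if (any(demog$sizes < pri$ne_bounds[1] | demog$sizes > pri$ne_bounds[2]))
        return(-Inf)
      lp <- lp - sum(log(demog$sizes)) +
        gmrf_log_prior(demog, pri$tau_shape, pri$tau_rate)
    }
    if (structured) {
      if (par$ne_og < pri$ne_bounds[1] || par$ne_og > pri$ne_bounds[2])
        return(-Inf)
      lp <- lp + coalescent_log_density_ages(
        tree$age[c(ing_tips, ing_internal)], length(ing_tips), demog)
      if (length(og_tips) >= 2L) {
        lp <- lp - log(par$ne_og) + coalescent_log_density_ages(
          tree$age[c(og_tips, og_internal)], length(og_tips),
          list(mode = "constant", Ne = par$ne_og))
        # the split itself is governed by the root calibration alone, but
        # both subtree roots must stay below it
        if (max(tree$age[c(ing_internal, og_internal)]) >=
            tree$age[tree$n_tip + 1L]) return(-Inf)
      }
    } else {
      lp <- lp + coalescent_log_density_ages(tree$age, tree$n_tip, demog)
    }
    if (!is.null(root_meanlog))
      lp <- lp + stats::dlnorm(tree$age[tree$n_tip + 1L], root_meanlog,
                               config$root_sdlog, log = TRUE)
    lp
  }
  post_rows <- postorder_edges(tree)
  zero_ll <- stats::setNames(rep(0, n_parts), parts)
  eval_loglik <- function(tree, par, rows) {
    if (config$sample_from_prior) return(zero_ll)
    mix_g <- rate_mixture_fast(par$alpha, config$n_categories, par$p_inv)
    mix_t <- if (!all(gamma_flag))
      rate_mixture_fast(NA_real_, config$n_categories, par$p_inv)
    rates <- lapply(gamma_flag, function(g) if (g) mix_g$rate else mix_t$rate)
    wts <- lapply(gamma_flag, function(g) if (g) mix_g$weight else mix_t$weight)
    .prune_loglik(tree$edge[rows, , drop = FALSE], tree$age, tree$n_tip,
                  tips_list, weights_list, freqs_list,
                  rep.int(par$kappa, n_parts), rates, wts,
                  par$clock, par$rel[parts])
  }

  cur_prior <- eval_prior(tree, par, demog)
  attempts <- 0L
  while (!is.finite(cur_prior) && attempts < 1000L) {
    attempts <- attempts + 1L
    par$clock <- stats::runif(1, 1e-9, 1e-7)
    tree <- repair_node_ages(tree, margin = attempts)
    cur_prior <- eval_prior(tree, par, demog)
  }
  if (!is.finite(cur_prior))
    stop("could not find a finite initial posterior after 1000 attempts")
  cur_ll <- eval_loglik(tree, par, post_rows)

  # --- move schedule ----------------------------------------------------
  internals <- if (tree$n_tip >= 3L)
    seq(tree$n_tip + 2L, 2L * tree$n_tip - 1L) else integer(0)  # non-root
  moves <- c(clock = 4, updown = 4, ne = 3, root = 2)
  if (is.null(fixed_subst$kappa)) moves["kappa"] <- 1.5
  if (length(internals)) moves["node"] <- max(4, length(internals) / 3)
  if (is.null(fixed_subst$alpha) &&
      any(vapply(parts, function(pt)
        !(pt == "tRNA" && !config$gamma_tRNA), logical(1))))
    moves["alpha"] <- 1.5
  if (config$estimate_pinv && is.null(fixed_subst$p_inv)) moves["pinv"] <- 1.5
  if (config$estimate_rel_rates && is.null(fixed_subst$rel) &&
      length(parts) > 1L) moves["rel"] <- 2
  if (n_und > 0L) {
    moves["tip_window"] <- 3 + n_und
    moves["tip_scale"] <- 2 + n_und
    moves["tip_draw"] <- 1 + n_und    # independence draw from the prior
    moves["tip_jump"] <- 2 + n_und    # prior draw + parent slack shift
  }
  if (sample_topology && length(internals)) moves["topo"] <- max(4, length(internals) / 3)
  if (config$demog_mode == "grid") { moves["tau"] <- 1; moves["ne_all"] <- 2 }
  if (structured && length(og_tips) >= 2L) moves["ne_og"] <- 1
  move_names <- names(moves)
  tune <- list(clock = 0.8, updown = 0.15, kappa = 0.5, alpha = 0.5,
               pinv = 0.15, rel = 0.1, ne = 1.0, root = 0.3, node = 0.5,
               tip_window = 2e5, tip_scale = 0.7, topo = NA_real_, tau = 1.0,
               ne_all = 0.8, ne_og = 1.0)
  stats_acc <- new_move_stats(names(moves))
  window <- stats::setNames(rep(0L, length(moves)), names(moves))
  window_acc <- window

  n_iter <- config$n_iterations
  burn <- floor(config$burn_in_fraction * n_iter)
  keep <- seq_len(n_iter)
  keep <- keep[keep > burn & keep %% config$thin == 0L]
  n_keep <- length(keep)

  par_cols <- c("clock_rate", "kappa", "alpha", "p_inv",
                paste0("rel_", parts),
                if (config$demog_mode == "constant") "Ne"
                else c(paste0("theta_", seq_along(demog$sizes)), "tau"),
                if (structured && length(og_tips) >= 2L) "Ne_outgroup",
                "root_age",
                if (n_und) paste0("age_", undated$sample_id))
  trace <- matrix(NA_real_, n_keep, 4L + length(par_cols))
  colnames(trace) <- c("iteration", "log_posterior", "log_likelihood",
                       "log_prior", par_cols)
  trees_out <- if (config$store_trees) vector("list", n_keep) else NULL
  keep_i <- 0L

  scale_factor <- function(lambda) exp(lambda * (stats::runif(1) - 0.5))

  for (iter in seq_len(n_iter)) {
    mv <- sample(move_names, 1L, prob = moves)
    new_tree <- tree; new_par <- par; new_demog <- demog
    log_h <- 0
    affects_ll <- TRUE
    valid <- TRUE
    if (mv == "clock") {
      s <- scale_factor(tune$clock); new_par$clock <- par$clock * s
      log_h <- log(s)
    } else if (mv == "updown") {
      # joint move along the rate-time ridge: all free node ages and the
      # coalescent sizes up, clock rate down by the same factor
      s <- scale_factor(tune$updown)
      scaled <- c(und_idx, seq(tree$n_tip + 1L, 2L * tree$n_tip - 1L))
      new_tree$age[scaled] <- tree$age[scaled] * s
      new_par$clock <- par$clock / s
      n_up <- length(scaled)
      if (config$demog_mode == "constant") {
        new_demog$Ne <- demog$Ne * s
        n_up <- n_up + 1L
      } else {
        new_demog$sizes <- demog$sizes * s
        n_up <- n_up + length(demog$sizes)
      }
      if (structured && length(og_tips) >= 2L) {
        new_par$ne_og <- par$ne_og * s
        n_up <- n_up + 1L
      }
      dur <- new_tree$age[new_tree$edge[, 1L]] - new_tree$age[new_tree$edge[, 2L]]
      if (any(dur <= 0)) valid <- FALSE
      log_h <- (n_up - 1) * log(s)
    } else if (mv == "ne_all") {
      # joint scale of the whole size trajectory (grid mode)
      s <- scale_factor(tune$ne_all)
      new_demog$sizes <- demog$sizes * s
      log_h <- length(demog$sizes) * log(s)
      affects_ll <- FALSE
    } else if (mv == "kappa") {
      s <- scale_factor(tune$kappa); new_par$kappa <- par$kappa * s
      log_h <- log(s)
    } else if (mv == "alpha") {
      s <- scale_factor(tune$alpha); new_par$alpha <- par$alpha * s
      log_h <- log(s)
    } else if (mv == "pinv") {
      x <- par$p_inv + stats::runif(1, -tune$pinv, tune$pinv)
      while (x < 0 || x > 0.999) {
        if (x < 0) x <- -x
        if (x > 0.999) x <- 2 * 0.999 - x
      }
      new_par$p_inv <- x
    } else if (mv == "rel") {
      # exchange mass between two partitions, keeping the weighted mean
      pick <- sample(length(parts), 2L)
      w <- lik_data$n_col[parts]
      mass <- stats::runif(1, 0, tune$rel * min(w))
      u <- par$rel * w
      u[pick[1L]] <- u[pick[1L]] - mass
      u[pick[2L]] <- u[pick[2L]] + mass
      if (u[pick[1L]] <= 0) valid <- FALSE else new_par$rel <- u / w
    } else if (mv == "ne") {
      s <- scale_factor(tune$ne)
      affects_ll <- FALSE
      if (config$demog_mode == "constant") {
        new_demog$Ne <- demog$Ne * s
      } else {
        k <- sample(length(demog$sizes), 1L)
        new_demog$sizes[k] <- demog$sizes[k] * s
      }
      log_h <- log(s)
    } else if (mv == "tau") {
      s <- scale_factor(tune$tau); new_demog$tau <- demog$tau * s
      log_h <- log(s); affects_ll <- FALSE
    } else if (mv == "ne_og") {
      s <- scale_factor(tune$ne_og); new_par$ne_og <- par$ne_og * s
      log_h <- log(s); affects_ll <- FALSE
    } else if (mv == "tip_jump") {
      # redraw the tip age from its prior and carry the parent along,
      # preserving the parent's height slack above its children
      k <- sample.int(n_und, 1L)
      ti <- und_idx[k]
      p <- tree$edge[tree$edge[, 2L] == ti, 1L]
      kids <- tree$edge[tree$edge[, 1L] == p, 2L]
      sib_age <- max(tree$age[kids[kids != ti]])
      slack <- tree$age[p] - max(tree$age[ti], sib_age)
      a_new <- stats::runif(1, calib_lo[k], calib_hi[k])
      p_new <- max(a_new, sib_age) + slack
      gp <- tree$edge[tree$edge[, 2L] == p, 1L]
      if (length(gp) && p_new >= tree$age[gp]) {
        valid <- FALSE
      } else {
        new_tree$age[ti] <- a_new
        new_tree$age[p] <- p_new
      }
    } else if (mv == "tip_window" || mv == "tip_scale" || mv == "tip_draw") {
      k <- sample.int(n_und, 1L)
      ti <- und_idx[k]
      if (mv == "tip_draw") {
        new_tree$age[ti] <- stats::runif(1, calib_lo[k], calib_hi[k])
      } else if (mv == "tip_window") {
        new_tree$age[ti] <- tree$age[ti] + stats::runif(1, -tune$tip_window,
                                                        tune$tip_window)
        if (new_tree$age[ti] < 0) valid <- FALSE
      } else {
        s <- scale_factor(tune$tip_scale)
        new_tree$age[ti] <- tree$age[ti] * s
        log_h <- log(s)
      }
      parent <- tree$edge[tree$edge[, 2L] == ti, 1L]
      if (valid && new_tree$age[ti] >= tree$age[parent]) valid <- FALSE
    } else if (mv == "node") {
      v <- internals[sample.int(length(internals), 1L)]
      kids <- tree$edge[tree$edge[, 1L] == v, 2L]
      parent <- tree$edge[tree$edge[, 2L] == v, 1L]
      lo <- max(tree$age[kids]); hi <- tree$age[parent]
      new_tree$age[v] <- stats::runif(1, lo, hi)
    } else if (mv == "root") {
      rt <- tree$n_tip + 1L
      kids <- tree$edge[tree$edge[, 1L] == rt, 2L]
      c0 <- max(tree$age[kids])
      s <- scale_factor(tune$root)
      new_tree$age[rt] <- c0 + (tree$age[rt] - c0) * s
      log_h <- log(s)
    } else if (mv == "topo") {
      v <- internals[sample.int(length(internals), 1L)]
      p <- tree$edge[tree$edge[, 2L] == v, 1L]
      sibs <- tree$edge[tree$edge[, 1L] == p, 2L]
      b <- sibs[sibs != v]
      kids <- tree$edge[tree$edge[, 1L] == v, 2L]
      g <- kids[sample.int(2L, 1L)]
      if (tree$age[v] <= tree$age[b]) valid <- FALSE
      else {
        rb <- which(tree$edge[, 1L] == p & tree$edge[, 2L] == b)
        rg <- which(tree$edge[, 1L] == v & tree$edge[, 2L] == g)
        new_tree$edge[rb, ] <- c(v, b)
        new_tree$edge[rg, ] <- c(p, g)
      }
    }

    if (valid) {
      new_rows <- if (mv == "topo") postorder_edges(new_tree) else post_rows
      new_prior <- eval_prior(new_tree, new_par, new_demog)
      if (is.finite(new_prior)) {
        new_ll <- if (affects_ll) eval_loglik(new_tree, new_par, new_rows)
                  else cur_ll
        log_ratio <- (new_prior + sum(new_ll)) -
          (cur_prior + sum(cur_ll)) + log_h
        if (log(stats::runif(1)) < log_ratio) {
          tree <- new_tree; par <- new_par; demog <- new_demog
          cur_prior <- new_prior; cur_ll <- new_ll; post_rows <- new_rows
          stats_acc[[mv]]$accepted <- stats_acc[[mv]]$accepted + 1L
          window_acc[mv] <- window_acc[mv] + 1L
        }
      }
    }
    stats_acc[[mv]]$proposed <- stats_acc[[mv]]$proposed + 1L
    window[mv] <- window[mv] + 1L

    # burn-in-only tuning toward ~23% acceptance
    if (iter <= burn && window[mv] >= 50L) {
      rate <- window_acc[mv] / window[mv]
      adj <- exp(0.7 * (rate - 0.234))
      if (mv %in% c("clock", "updown", "kappa", "alpha", "ne", "root",
                    "tip_scale", "tau", "ne_all", "ne_og"))
        tune[[mv]] <- min(5, max(1e-3, tune[[mv]] * adj))
      else if (mv == "pinv") tune$pinv <- min(0.5, max(1e-3, tune$pinv * adj))
      else if (mv == "rel") tune$rel <- min(1, max(1e-4, tune$rel * adj))
      else if (mv == "tip_window")
        tune$tip_window <- min(2e6, max(10, tune$tip_window * adj))
      window[mv] <- 0L; window_acc[mv] <- 0L
    }

    if (length(keep) && keep_i < n_keep && iter == keep[keep_i + 1L]) {
      keep_i <- keep_i + 1L
      vals <- c(iter, cur_prior + sum(cur_ll), sum(cur_ll), cur_prior,
                par$clock, par$kappa, par$alpha, par$p_inv, par$rel,
                if (config$demog_mode == "constant") demog$Ne
                else c(demog$sizes, demog$tau),
                if (structured && length(og_tips) >= 2L) par$ne_og,
                root_age(tree),
                if (n_und) tree$age[und_idx])
      trace[keep_i, ] <- vals
      if (config$store_trees) trees_out[[keep_i]] <- tree
    }
  }

  for (nm in names(stats_acc)) stats_acc[[nm]]$tune <- tune[[nm]]
  structure(list(trace = as.data.frame(trace), trees = trees_out,
                 acceptance = stats_acc,
                 final_state = list(tree = tree, par = par, demog = demog),
                 seed = seed,
                 config_hash = config_hash(config[setdiff(names(config),
                                                          "fixed_tree")])),
            class = "tip_chain")
}

#' @export
print.tip_chain <- function(x, ...) {
  cat(sprintf("tip_chain: %d retained samples, %d parameters\n",
              nrow(x$trace), ncol(x$trace) - 4L))
  acc <- vapply(x$acceptance, function(a)
    if (a$proposed > 0) a$accepted / a$proposed else NA_real_, numeric(1))
  cat("acceptance: ", paste(sprintf("%s=%.2f", names(acc), acc),
                            collapse = " "), "\n")
  invisible(x)
}
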