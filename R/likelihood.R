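# -- sequence encoding and site-pattern compression ---------------------------

BASE_CODES <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L, `-` = 4L)

encode_columns <- function(cols) {
  # cols: character matrix (tips x sites); N and '-' are fully ambiguous
  m <- matrix(BASE_CODES[cols], nrow = nrow(cols))
  if (anyNA(m)) stop("alignment contains characters outside {A,C,G,T,N,-}")
  rownames(m) <- rownames(cols)
  m
}

compress_patterns <- function(codes) {
  if (ncol(codes) == 0L)
    return(list(patterns = codes, weights = numeric(0)))
  key <- apply(codes, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  weights <- as.numeric(table(key)[key[first]])
  list(patterns = codes[, first, drop = FALSE], weights = weights)
}

empirical_freqs <- function(cols, pseudocount = 1) {
  counts <- c(A = sum(cols == "A"), C = sum(cols == "C"),
              G = sum(cols == "G"), T = sum(cols == "T")) + pseudocount
  counts / sum(counts)
}

# reorder alignment rows to tree tip order; error on mismatch
match_tips <- function(cols, tree) {
  missing <- setdiff(tree$tip_label, rownames(cols))
  if (length(missing))
    stop("alignment lacks rows for tips: ", paste(missing, collapse = ", "))
  cols[tree$tip_label, , drop = FALSE]
}

#' Log-likelihood of one partition on a dated tree
#'
#' Felsenstein-pruning log-likelihood of a set of alignment columns under
#' HKY with an optional discrete-Gamma + invariant-sites rate mixture and
#' a strict molecular clock. The branch distance of an edge is
#' `clock_rate * relative_rate * category_rate * (parent age - child age)`.
#' `N` and `-` are treated as fully ambiguous states. Identical site
#' patterns are compressed before evaluation; this does not change the
#' value.
#'
#' @param tree a [time_tree()].
#' @param cols character matrix of alignment columns (rows named by tip
#'   label, columns = sites of this partition).
#' @param params a [substitution_params()].
#' @param clock_rate strict-clock rate in substitutions/site/year.
#' @return the log-likelihood (sum over sites of log mixture
#'   likelihoods).
#' @export
partition_log_likelihood <- function(tree, cols, params, clock_rate) {
  stopifnot(inherits(tree, "time_tree"), clock_rate >= 0)
  cols <- match_tips(cols, tree)
  codes <- encode_columns(cols)
  cp <- compress_patterns(codes)
  mix <- rate_mixture_of(params)
  rows <- postorder_edges(tree)
  .prune_loglik(tree$edge[rows, , drop = FALSE], tree$age, tree$n_tip,
                list(cp$patterns), list(cp$weights), list(params$freqs),
                params$kappa, list(mix$rate), list(mix$weight),
                clock_rate, params$relative_rate)[1]
}

# -- precompiled likelihood data for MCMC -------------------------------------

# Bundle everything that is constant across MCMC iterations for a given
# topology-independent dataset: per-partition compressed patterns in a fixed
# tip order, empirical frequencies, pattern counts.
likelihood_data <- function(aln, tip_order) {
  stopifnot(inherits(aln, "partitioned_alignment"))
  m <- aln$seqs[tip_order, , drop = FALSE]
  parts <- live_partitions(aln)
  tips <- list(); weights <- list(); freqs <- list(); ncols <- integer(0)
  for (pt in parts) {
    cols <- m[, aln$partition == pt, drop = FALSE]
    codes <- encode_columns(cols)
    cp <- compress_patterns(codes)
    tips[[pt]] <- cp$patterns
    weights[[pt]] <- cp$weights
    freqs[[pt]] <- empirical_freqs(cols)
    ncols[pt] <- ncol(cols)
  }
  list(partitions = parts, tips = tips, weights = weights, freqs = freqs,
       n_col = ncols, tip_order = tip_order)
}

# evaluate all partitions; subst is a named list of substitution_params
all_partition_loglik <- function(tree, lik_data, subst, clock_rate,
                                 postorder_rows = NULL) {
  stopifnot(identical(lik_data$tip_order, tree$tip_label))
  parts <- lik_data$partitions
  rows <- if (is.null(postorder_rows)) postorder_edges(tree) else postorder_rows
  mixes <- lapply(parts, function(pt) rate_mixture_of(subst[[pt]]))
  ll <- .prune_loglik(tree$edge[rows, , drop = FALSE], tree$age, tree$n_tip,
                      lik_data$tips[parts], lik_data$weights[parts],
                      lapply(parts, function(pt) subst[[pt]]$freqs),
                      vapply(parts, function(pt) subst[[pt]]$kappa, numeric(1)),
                      lapply(mixes, `[[`, "rate"),
                      lapply(mixes, `[[`, "weight"),
                      clock_rate,
                      vapply(parts, function(pt) subst[[pt]]$relative_rate,
                             numeric(1)))
  stats::setNames(ll, parts)
}
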