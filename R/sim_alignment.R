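#' Simulate a partitioned alignment down a dated tree
#'
#' Strict-clock sequence simulation: every site draws a rate category
#' from its partition's Gamma+Invariant mixture, the root state is drawn
#' from the stationary frequencies, and states evolve down each branch
#' under HKY with expected substitutions
#' `clock_rate * relative_rate * category_rate * branch duration`.
#' Alignments are simulated gap-free; gaps and masking enter only through
#' the alignment post-processing operations.
#'
#' @param tree a [time_tree()].
#' @param partition character vector of column labels (the layout);
#'   every label must name an entry of `models`, except `masked` columns,
#'   which are simulated under the `control_region` model (first model if
#'   absent) and keep their `masked` label.
#' @param models named list of [substitution_params()], one per partition
#'   label in use.
#' @param clock_rate strict-clock rate, substitutions/site/year (>= 0).
#' @param seed integer RNG seed (required).
#' @param reference_row_id row to mark as the annotation reference
#'   (default: first tip).
#' @return a [partitioned_alignment()] with rows in tree tip order.
#' @export
simulate_alignment <- function(tree, partition, models, clock_rate, seed,
                               reference_row_id = NULL) {
  if (missing(seed)) stop("an explicit integer seed is required")
  stopifnot(inherits(tree, "time_tree"), clock_rate >= 0)
  L <- length(partition)
  labels <- unique(partition)
  model_of <- function(lab) {
    if (lab %in% names(models)) return(models[[lab]])
    if (lab %in% c("masked", "unassigned")) {
      # simulated but excluded from likelihood; content only needs realism
      if ("control_region" %in% names(models)) return(models[["control_region"]])
      return(models[[1L]])
    }
    stop("partition layout not covered by models: ", lab)
  }
  set.seed(seed)
  n <- tree$n_tip
  rows <- rev(postorder_edges(tree))          # preorder over branches
  edge <- tree$edge[rows, , drop = FALSE]
  dur <- tree$age[edge[, 1L]] - tree$age[edge[, 2L]]
  states <- matrix(0L, 2L * n - 1L, L)        # 1..4 = A,C,G,T
  bases <- c("A", "C", "G", "T")
  for (lab in labels) {
    cols <- which(partition == lab)
    mod <- model_of(lab)
    mix <- rate_mixture_of(mod)
    cat_of <- sample.int(nrow(mix), length(cols), replace = TRUE,
                         prob = mix$weight)
    states[n + 1L, cols] <- sample.int(4L, length(cols), replace = TRUE,
                                       prob = mod$freqs)
    for (ci in seq_len(nrow(mix))) {
      sc <- cols[cat_of == ci]
      if (!length(sc)) next
      site_rate <- clock_rate * mod$relative_rate * mix$rate[ci]
      for (e in seq_len(nrow(edge))) {
        par_states <- states[edge[e, 1L], sc]
        P <- hky_transition_matrix(mod, site_rate * dur[e])
        child <- integer(length(sc))
        for (s in 1:4) {
          idx <- which(par_states == s)
          if (length(idx))
            child[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                     prob = P[s, ])
        }
        states[edge[e, 2L], sc] <- child
      }
    }
  }
  m <- matrix(bases[states[seq_len(n), , drop = FALSE]], nrow = n)
  rownames(m) <- tree$tip_label
  if (is.null(reference_row_id)) reference_row_id <- tree$tip_label[1L]
  partitioned_alignment(m, partition, reference_row_id)
}
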