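#' Consensus-calling policy
#'
#' Depth and agreement thresholds for calling a consensus base from a
#' pileup. The default policy masks positions with less than 3x coverage
#' or less than 67% agreement; the strict policy (used for heavily
#' deaminated material) masks below 10x coverage or 90% agreement.
#' Threshold semantics are inclusive: agreement exactly equal to
#' `min_agreement` passes. The comparison is done on exact rationals
#' (cross-multiplication), so 2/3 correctly fails a 0.67 threshold.
#'
#' @param min_depth minimum read depth (>= 1).
#' @param min_agreement minimum majority fraction, in (0.5, 1].
#' @return a `consensus_policy` list.
#' @export
consensus_policy <- function(min_depth = 3L, min_agreement = 0.67) {
  stopifnot(min_depth >= 1L, min_agreement > 0.5, min_agreement <= 1)
  structure(list(min_depth = as.integer(min_depth),
                 min_agreement = min_agreement),
            class = "consensus_policy")
}

#' Call a consensus sequence from a pileup
#'
#' Per position: if depth is below `min_depth` the call is `N`; otherwise
#' let `m` be the largest base count — if `m / depth < min_agreement` the
#' call is `N`, else the majority symbol is emitted (`-` may be emitted
#' as a consensus deletion). Ties for the majority symbol cannot pass any
#' agreement threshold above 0.5, so tie-breaking never arises.
#'
#' @param pileup pileup data frame (columns `pos`, `A`, `C`, `G`, `T`,
#'   `del`; see [read_pileup()]).
#' @param policy a [consensus_policy()].
#' @return consensus sequence string over `{A,C,G,T,-,N}` (empty for an
#'   empty pileup).
#' @examples
#' p <- data.frame(pos = 1:2, A = c(2L, 3L), C = 0L, G = 0L, T = 0L, del = 0L)
#' call_consensus(p, consensus_policy(3, 0.67))  # "NA" -> N then A
#' @export
call_consensus <- function(pileup, policy = consensus_policy()) {
  pileup <- validate_pileup(pileup)
  if (nrow(pileup) == 0L) return("")
  counts <- as.matrix(pileup[, c("A", "C", "G", "T", "del")])
  symbols <- c("A", "C", "G", "T", "-")
  depth <- rowSums(counts)
  top <- max.col(counts, ties.method = "first")
  m <- counts[cbind(seq_len(nrow(counts)), top)]
  # exact rational comparison: m/depth >= min_agreement <=> m >= a*depth;
  # with a given as a decimal, compare m * 10^k >= a*10^k * depth in integers
  k <- 12L
  a_int <- round(policy$min_agreement * 10^k)
  pass <- depth >= policy$min_depth & (m * 10^k >= a_int * depth)
  call <- ifelse(pass, symbols[top], "N")
  paste(call, collapse = "")
}

#' Depth and breadth of coverage of a consensus
#'
#' @param pileup pileup data frame.
#' @param consensus consensus sequence string of the same length.
#' @return list with `mean_depth` (mean over all positions, including
#'   zero-depth ones) and `breadth` (fraction of non-`N` positions).
#' @export
coverage_stats <- function(pileup, consensus) {
  pileup <- validate_pileup(pileup)
  L <- nrow(pileup)
  if (nchar(consensus) != L) stop("consensus length does not match pileup")
  depth <- rowSums(as.matrix(pileup[, c("A", "C", "G", "T", "del")]))
  calls <- strsplit(consensus, "")[[1]]
  list(mean_depth = if (L) mean(depth) else NaN,
       breadth = if (L) sum(calls != "N") / L else NaN)
}

#' Simulate a pileup over a true sequence
#'
#' Per-position depth is drawn from a negative binomial with the given
#' mean and dispersion (size parameter; larger = closer to Poisson), and
#' each read base equals the true base with probability `1 - error_rate`,
#' otherwise one of the three alternatives uniformly. A true `-` is
#' propagated to the `del` column the same way.
#'
#' @param true_seq string over `{A,C,G,T,-}`.
#' @param mean_depth expected read depth (> 0).
#' @param depth_dispersion negative-binomial size parameter (> 0).
#' @param error_rate per-read-base error probability in `[0, 0.25)`.
#' @param seed integer RNG seed (required).
#' @return pileup data frame (`pos`, `A`, `C`, `G`, `T`, `del`).
#' @export
simulate_pileup <- function(true_seq, mean_depth, depth_dispersion = 5,
                            error_rate = 0.001, seed) {
  if (missing(seed)) stop("an explicit integer seed is required")
  stopifnot(mean_depth > 0, depth_dispersion > 0,
            error_rate >= 0, error_rate < 0.25)
  set.seed(seed)
  truth <- strsplit(toupper(true_seq), "")[[1]]
  symbols <- c("A", "C", "G", "T", "-")
  if (!all(truth %in% symbols)) stop("true_seq must be over {A,C,G,T,-}")
  L <- length(truth)
  depth <- stats::rnbinom(L, size = depth_dispersion, mu = mean_depth)
  counts <- matrix(0L, L, 5L, dimnames = list(NULL, c("A", "C", "G", "T", "del")))
  true_idx <- match(truth, symbols)
  for (i in seq_len(L)) {
    d <- depth[i]
    if (d == 0L) next
    n_err <- stats::rbinom(1L, d, error_rate)
    counts[i, true_idx[i]] <- d - n_err
    if (n_err > 0L) {
      alt <- setdiff(1:4, true_idx[i])          # errors land on other bases
      if (true_idx[i] == 5L) alt <- 1:4         # reads over a deletion
      err <- table(sample(alt, n_err, replace = TRUE))
      counts[i, as.integer(names(err))] <- counts[i, as.integer(names(err))] +
        as.integer(err)
    }
  }
  data.frame(pos = seq_len(L), counts)
}
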