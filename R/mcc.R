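#' Maximum clade credibility tree from a tree sample
#'
#' Computes per-clade posterior frequencies over a sample of dated trees
#' on an identical tip set, selects the sampled tree maximising the sum
#' of log clade frequencies, and annotates each of its internal nodes
#' with the clade's posterior support and the mean and 95% HPD of the
#' matching clade's node age across the sample.
#'
#' @param trees list of [time_tree()]s (>= 1) on the same tips.
#' @param hpd_mass probability mass of the node-height HPD annotation.
#' @return list with `tree` (the MCC [time_tree()]), `annotations`
#'   (data frame per internal node: `clade`, `support`, `height_mean`,
#'   `height_hpd_lo`, `height_hpd_hi`) and `log_clade_credibility`.
#' @export
mcc_tree <- function(trees, hpd_mass = 0.95) {
  stopifnot(length(trees) >= 1L)
  tipset <- sort(trees[[1L]]$tip_label)
  n <- trees[[1L]]$n_tip
  keys_list <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!identical(sort(tr$tip_label), tipset))
      stop("inconsistent tip sets across the tree sample")
    keys_list[[i]] <- clade_keys(tr)
  }
  # clade frequencies over internal nodes (tips are trivially frequency 1)
  internal_keys <- lapply(keys_list, function(k) k[-seq_len(n)])
  freq <- table(unlist(internal_keys)) / length(trees)
  score <- vapply(internal_keys, function(k)
    sum(log(as.numeric(freq[k]))), numeric(1))
  best <- which.max(score)
  tree <- trees[[best]]
  keys <- keys_list[[best]]
  node_ids <- seq(n + 1L, 2L * n - 1L)
  # collect matching-clade ages across the sample
  ann <- data.frame(node = node_ids, clade = keys[node_ids],
                    support = as.numeric(freq[keys[node_ids]]),
                    height_mean = NA_real_, height_hpd_lo = NA_real_,
                    height_hpd_hi = NA_real_, stringsAsFactors = FALSE)
  ages_by_clade <- list()
  for (i in seq_along(trees)) {
    k <- keys_list[[i]]
    for (v in seq(n + 1L, 2L * n - 1L))
      ages_by_clade[[k[v]]] <- c(ages_by_clade[[k[v]]], trees[[i]]$age[v])
  }
  for (r in seq_len(nrow(ann))) {
    a <- ages_by_clade[[ann$clade[r]]]
    ann$height_mean[r] <- mean(a)
    if (length(a) >= 20L) {
      h <- hpd_interval(a, hpd_mass)
      ann$height_hpd_lo[r] <- h[1]; ann$height_hpd_hi[r] <- h[2]
    } else {
      ann$height_hpd_lo[r] <- min(a); ann$height_hpd_hi[r] <- max(a)
    }
  }
  list(tree = tree, annotations = ann, log_clade_credibility = score[best])
}
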