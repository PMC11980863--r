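#' Dated phylogenies with heterochronous tips
#'
#' A `time_tree` is a rooted binary tree in which every node carries an
#' absolute age in years before present (BP). Tips may be sampled at
#' different times (heterochronous sampling); every internal node is
#' strictly older than each of its children. Node numbering follows the
#' \pkg{ape} convention: tips are `1..n`, the root is `n + 1`, and the
#' remaining internal nodes are `n + 2 .. 2n - 1`.
#'
#' @param edge integer matrix with two columns (parent, child), one row per
#'   branch, `2n - 2` rows for `n` tips.
#' @param tip_label character vector of `n` unique tip labels.
#' @param age numeric vector of `2n - 1` node ages in years BP, indexed by
#'   node number.
#' @return An object of class `time_tree`: a list with elements `edge`,
#'   `tip_label`, `age` and `n_tip`.
#' @examples
#' tr <- time_tree(rbind(c(3L, 1L), c(3L, 2L)), c("a", "b"), c(0, 2000, 9000))
#' root_age(tr)
#' @export
time_tree <- function(edge, tip_label, age) {
  n <- length(tip_label)
  edge <- matrix(as.integer(edge), ncol = 2L)
  obj <- structure(
    list(edge = edge, tip_label = as.character(tip_label),
         age = as.numeric(age), n_tip = n),
    class = "time_tree")
  validate_time_tree(obj)
  obj
}

validate_time_tree <- function(tree) {
  n <- tree$n_tip
  if (n < 2L) stop("a time_tree needs at least 2 tips")
  if (anyDuplicated(tree$tip_label)) stop("duplicate tip labels")
  if (length(tree$age) != 2L * n - 1L) stop("age vector must have 2n-1 entries")
  if (nrow(tree$edge) != 2L * n - 2L) stop("edge matrix must have 2n-2 rows")
  if (any(tree$age < 0)) stop("node ages must be non-negative (years BP)")
  kids <- tabulate(tree$edge[, 1L], nbins = 2L * n - 1L)
  if (any(kids[-seq_len(n)] != 2L)) stop("tree must be binary")
  if (any(kids[seq_len(n)] != 0L)) stop("tips cannot have children")
  dur <- tree$age[tree$edge[, 1L]] - tree$age[tree$edge[, 2L]]
  if (any(dur <= 0)) stop("every parent must be strictly older than its children")
  invisible(tree)
}

#' @rdname time_tree
#' @param tree a `time_tree`.
#' @export
root_age <- function(tree) tree$age[tree$n_tip + 1L]

#' @rdname time_tree
#' @export
tip_ages <- function(tree) {
  stats::setNames(tree$age[seq_len(tree$n_tip)], tree$tip_label)
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf("time_tree: %d tips, root age %.6g years BP\n", x$n_tip, root_age(x)))
  cat(sprintf("tip ages: %s\n",
              paste(sprintf("%s=%.5g", x$tip_label, x$age[seq_len(x$n_tip)]),
                    collapse = " ")))
  invisible(x)
}

# edge rows ordered so every child row precedes its parent's row
# (children before parents: a postorder traversal over branches)
postorder_edges <- function(tree) {
  n_node <- 2L * tree$n_tip - 1L
  parent <- integer(n_node)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  # iterative postorder from root
  root <- tree$n_tip + 1L
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  order_nodes <- integer(0)
  stack <- root
  visited <- logical(n_node)
  out <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    ch <- children[[as.character(v)]]
    if (is.null(ch) || visited[v]) {
      out <- c(out, v)
      stack <- stack[-length(stack)]
    } else {
      visited[v] <- TRUE
      stack <- c(stack, ch)
    }
  }
  out <- out[out > tree$n_tip | out <= tree$n_tip]  # all nodes, postorder
  # convert node postorder to edge-row order (row index by child)
  row_of_child <- integer(n_node)
  row_of_child[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  rows <- row_of_child[out[out != root]]
  rows
}

#' Convert between `time_tree` and \pkg{ape}'s `phylo`
#'
#' Branch lengths of the resulting `phylo` are durations in years
#' (parent age minus child age).
#'
#' @param tree a `time_tree`.
#' @return `as_phylo()` returns an `ape::phylo`; `as_time_tree()` a
#'   `time_tree`.
#' @export
as_phylo <- function(tree) {
  stopifnot(inherits(tree, "time_tree"))
  phy <- list(edge = tree$edge,
              edge.length = tree$age[tree$edge[, 1L]] - tree$age[tree$edge[, 2L]],
              tip.label = tree$tip_label,
              Nnode = tree$n_tip - 1L)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy
}

#' @rdname as_phylo
#' @param phy an `ape::phylo` with branch lengths in years.
#' @param tip_ages named numeric vector of tip ages (years BP); names must
#'   cover all tip labels.
#' @param tol relative tolerance for path-consistency of node ages: the age
#'   of an internal node must be reconstructible identically (within `tol`)
#'   through each of its children.
#' @export
as_time_tree <- function(phy, tip_ages, tol = 1e-6) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) stop("phylo must carry branch lengths")
  n <- length(phy$tip.label)
  missing <- setdiff(phy$tip.label, names(tip_ages))
  if (length(missing)) stop("tip ages missing for: ", paste(missing, collapse = ", "))
  age <- rep(NA_real_, 2L * n - 1L)
  age[seq_len(n)] <- as.numeric(tip_ages[phy$tip.label])
  # children before parents
  ord <- order(node_depths(phy), decreasing = TRUE)
  for (v in ord) {
    if (v <= n) next
  }
  # propagate ages upward along edges, checking consistency
  repeat {
    done <- TRUE
    for (i in seq_len(nrow(phy$edge))) {
      p <- phy$edge[i, 1L]; c <- phy$edge[i, 2L]
      if (!is.na(age[c])) {
        cand <- age[c] + phy$edge.length[i]
        if (is.na(age[p])) {
          age[p] <- cand
          done <- FALSE
        } else {
          scale <- max(abs(age[p]), abs(cand), 1)
          if (abs(age[p] - cand) > tol * scale)
            stop("inconsistent node ages: tip ages and branch lengths disagree")
        }
      }
    }
    if (done) break
  }
  time_tree(phy$edge, phy$tip.label, age)
}

node_depths <- function(phy) {
  n <- length(phy$tip.label)
  depth <- integer(n + phy$Nnode)
  ord <- seq_len(nrow(phy$edge))
  repeat {
    changed <- FALSE
    for (i in ord) {
      p <- phy$edge[i, 1L]; c <- phy$edge[i, 2L]
      if (depth[c] < depth[p] + 1L) { depth[c] <- depth[p] + 1L; changed <- TRUE }
    }
    if (!changed) break
  }
  depth
}

#' Read and write dated trees as Newick plus a node-annotation sidecar
#'
#' Trees are written as plain Newick with branch lengths in years; node
#' ages are reconstructed on read from tip ages plus branch lengths.
#' Optional node annotations (posterior support, height HPDs) travel in a
#' TSV sidecar keyed by the sorted tip set of each clade, avoiding
#' non-standard Newick comment blocks.
#'
#' @param path file path of the Newick file.
#' @param tree a `time_tree`.
#' @param annotations optional data frame of node annotations with a
#'   `clade` column (tip labels joined by `|`, sorted); written to
#'   `paste0(path, ".nodes.tsv")`.
#' @return `read_time_tree()` returns a `time_tree` (with an
#'   `annotations` attribute when the sidecar exists).
#' @export
write_time_tree <- function(tree, path, annotations = NULL) {
  phy <- as_phylo(tree)
  ape::write.tree(phy, file = path, digits = 17)
  # sidecar always carries tip ages so the tree is reconstructible alone
  ages <- data.frame(tip = tree$tip_label,
                     age = tree$age[seq_len(tree$n_tip)],
                     stringsAsFactors = FALSE)
  utils::write.table(ages, paste0(path, ".tips.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(annotations)) {
    utils::write.table(annotations, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_time_tree
#' @param tip_ages optionally override the tip ages of the sidecar.
#' @export
read_time_tree <- function(path, tip_ages = NULL) {
  phy <- ape::read.tree(path)
  if (is.null(tip_ages)) {
    side <- paste0(path, ".tips.tsv")
    if (!file.exists(side))
      stop("no tip ages given and no sidecar found at ", side)
    tab <- utils::read.delim(side, stringsAsFactors = FALSE)
    tip_ages <- stats::setNames(tab$age, tab$tip)
  }
  if (any(phy$edge.length < 0)) stop("negative branch length in Newick input")
  tree <- as_time_tree(phy, tip_ages)
  nodes <- paste0(path, ".nodes.tsv")
  if (file.exists(nodes))
    attr(tree, "annotations") <- utils::read.delim(nodes, stringsAsFactors = FALSE)
  tree
}

# clade key: sorted tip labels joined by "|", for MCC bookkeeping
clade_keys <- function(tree) {
  n <- tree$n_tip
  n_node <- 2L * n - 1L
  sets <- vector("list", n_node)
  for (i in seq_len(n)) sets[[i]] <- tree$tip_label[i]
  rows <- postorder_edges(tree)
  for (i in rows) {
    p <- tree$edge[i, 1L]; c <- tree$edge[i, 2L]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  vapply(sets, function(s) paste(sort(s), collapse = "|"), character(1))
}
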