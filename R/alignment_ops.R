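#' Partitioned multiple sequence alignments
#'
#' A `partitioned_alignment` couples an alignment (character matrix, rows
#' named by sample id) with a per-column partition label, one of `tRNA`,
#' `rRNA`, `codon1`, `codon2`, `codon3`, `control_region`, `masked` or
#' `unassigned`, plus the id of the annotation-bearing reference row.
#' `masked` and `unassigned` columns are excluded from all likelihood
#' computations.
#'
#' @param seqs character matrix over `{A,C,G,T,N,-}` with row names, or a
#'   named character vector of aligned sequences.
#' @param partition character vector of per-column labels.
#' @param reference_row_id row name of the reference sequence whose
#'   ungapped coordinates the annotation refers to.
#' @return an object of class `partitioned_alignment`.
#' @export
partitioned_alignment <- function(seqs, partition, reference_row_id) {
  if (!is.matrix(seqs)) seqs <- alignment_matrix(seqs)
  levels <- c("tRNA", "rRNA", "codon1", "codon2", "codon3", "control_region",
              "masked", "unassigned")
  stopifnot(length(partition) == ncol(seqs), all(partition %in% levels),
            reference_row_id %in% rownames(seqs))
  structure(list(seqs = seqs, partition = as.character(partition),
                 reference_row_id = reference_row_id),
            class = "partitioned_alignment")
}

#' @export
print.partitioned_alignment <- function(x, ...) {
  cat(sprintf("partitioned_alignment: %d sequences x %d columns\n",
              nrow(x$seqs), ncol(x$seqs)))
  print(table(x$partition))
  invisible(x)
}

live_partitions <- function(aln) {
  setdiff(unique(aln$partition), c("masked", "unassigned"))
}

#' Remove singleton-support columns from an alignment
#'
#' Drops every column in which exactly one sequence carries a determinate
#' base (A/C/G/T) while all other sequences carry `-` — single-sequence
#' insertion artifacts — as well as all-gap columns. `N` counts as
#' neither a base nor a gap assignment, so a column containing any `N`
#' alongside the single base is kept.
#'
#' @param aln character matrix (or named character vector) alignment.
#' @return list with `alignment` (the filtered matrix) and
#'   `removed_columns` (1-based indices of dropped columns).
#' @export
remove_singleton_columns <- function(aln) {
  if (!is.matrix(aln)) aln <- alignment_matrix(aln)
  is_base <- aln %in% c("A", "C", "G", "T")
  dim(is_base) <- dim(aln)
  is_gap <- aln == "-"
  n_base <- colSums(is_base)
  n_gap <- colSums(is_gap)
  nseq <- nrow(aln)
  singleton <- n_base == 1L & n_gap == nseq - 1L
  all_gap <- n_gap == nseq
  drop <- which(singleton | all_gap)
  list(alignment = aln[, setdiff(seq_len(ncol(aln)), drop), drop = FALSE],
       removed_columns = drop)
}

#' Map a reference interval to alignment columns
#'
#' Translates an interval given in ungapped reference coordinates
#' (1-based inclusive) into alignment column indices by walking the
#' reference row: the k-th non-gap character of the reference row
#' corresponds to reference position k. This replaces annotation
#' lift-over: gap-pattern coordinate transfer along the alignment's own
#' reference sequence.
#'
#' @param aln alignment matrix (or named character vector).
#' @param reference_row_id row name of the reference sequence.
#' @param start,end interval bounds on the ungapped reference, inclusive.
#' @param include_gap_columns if `TRUE` (the masking default), alignment
#'   gap columns falling strictly inside the mapped span are included;
#'   if `FALSE`, only columns carrying the reference bases themselves.
#' @return integer vector of 1-based alignment column indices.
#' @export
ref_to_alignment_columns <- function(aln, reference_row_id, start, end,
                                     include_gap_columns = TRUE) {
  if (!is.matrix(aln)) aln <- alignment_matrix(aln)
  stopifnot(reference_row_id %in% rownames(aln), start >= 1, end >= start)
  ref <- aln[reference_row_id, ]
  nongap <- which(ref != "-")
  if (end > length(nongap))
    stop("interval exceeds ungapped reference length (", length(nongap), ")")
  anchor <- nongap[start:end]
  if (include_gap_columns) seq(min(anchor), max(anchor)) else anchor
}

#' Mask the VNTR region of an alignment
#'
#' Labels every column mapped from the annotation's VNTR interval as
#' `masked`, excluding it from downstream likelihood computations. The
#' VNTR (variable number tandem repeat) of the mitochondrial control
#' region is hypervariable and alignment-hostile, so it is masked rather
#' than modelled. Masking is idempotent.
#'
#' @param aln a [partitioned_alignment()].
#' @param annotation annotation data frame containing a `VNTR` row
#'   (see [read_annotation()]).
#' @return the alignment with VNTR columns relabelled `masked`.
#' @export
mask_vntr <- function(aln, annotation) {
  stopifnot(inherits(aln, "partitioned_alignment"))
  annotation <- validate_annotation(annotation)
  v <- annotation[annotation$feature_class == "VNTR", , drop = FALSE]
  if (nrow(v) == 0L) stop("annotation has no VNTR row")
  for (i in seq_len(nrow(v))) {
    cols <- ref_to_alignment_columns(aln$seqs, aln$reference_row_id,
                                     v$start[i], v$end[i],
                                     include_gap_columns = TRUE)
    aln$partition[cols] <- "masked"
  }
  aln
}

#' Assign the six-way partition map to an alignment
#'
#' Labels every column by the annotated feature of its reference
#' position: `tRNA`, `rRNA`, `control_region`, or — for CDS features —
#' `codon1`/`codon2`/`codon3` cycling from the feature's
#' `codon_phase_origin`. Columns already `masked` stay masked; columns
#' outside every feature (including alignment gap columns of the
#' reference row) become `unassigned`.
#'
#' @param aln alignment matrix (or named character vector), or an
#'   existing [partitioned_alignment()] to relabel.
#' @param annotation annotation data frame (see [read_annotation()]).
#' @param reference_row_id reference row name (taken from `aln` when it
#'   is already partitioned).
#' @return a [partitioned_alignment()].
#' @export
assign_partitions <- function(aln, annotation, reference_row_id = NULL) {
  if (inherits(aln, "partitioned_alignment")) {
    seqs <- aln$seqs
    reference_row_id <- aln$reference_row_id
    partition <- aln$partition
  } else {
    if (!is.matrix(aln)) aln <- alignment_matrix(aln)
    seqs <- aln
    if (is.null(reference_row_id)) stop("reference_row_id required")
    partition <- rep("unassigned", ncol(seqs))
  }
  annotation <- validate_annotation(annotation)
  ref <- seqs[reference_row_id, ]
  nongap <- which(ref != "-")
  refpos <- integer(ncol(seqs))          # 0 for gap columns of the reference
  refpos[nongap] <- seq_along(nongap)
  masked <- partition == "masked"
  partition[!masked] <- "unassigned"
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i, ]
    if (a$feature_class == "VNTR") next  # handled by mask_vntr
    if (a$end > length(nongap))
      stop("annotation interval exceeds ungapped reference length")
    cols <- which(refpos >= a$start & refpos <= a$end & !masked)
    if (a$feature_class == "CDS") {
      phase <- (refpos[cols] - a$codon_phase_origin) %% 3
      partition[cols] <- paste0("codon", phase + 1)
    } else {
      partition[cols] <- a$feature_class
    }
  }
  partitioned_alignment(seqs, partition, reference_row_id)
}
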