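#' Read and write FASTA files
#'
#' Sequences are returned as a named character vector over the alphabet
#' `{A,C,G,T,N,-}` (uppercased on read). Input order is preserved.
#'
#' @param path file path.
#' @param alignment if `TRUE`, require all sequences to have equal length.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, alignment = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("sequence(s) contain characters outside {A,C,G,T,N,-}: ",
         paste(ids[bad], collapse = ", "))
  if (any(nchar(seqs) == 0L)) stop("empty sequence in ", path)
  if (alignment && length(unique(nchar(seqs))) != 1L)
    stop("ragged alignment: sequences differ in length")
  seqs
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# alignment as character matrix (rows = samples, cols = columns)
alignment_matrix <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1L) stop("sequences are not aligned")
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  m
}

matrix_alignment <- function(m) {
  stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

#' Read and write per-sample calibration metadata
#'
#' The sample table drives tip dating: `calibrated_fixed` rows are the
#' reference tips whose (recalibrated radiocarbon) ages anchor the clock,
#' `outgroup_modern` rows are present-day outgroup sequences fixed at age
#' zero, and `undated` rows receive a uniform age prior with bounds
#' `prior_lo`/`prior_hi` in years BP (the study default is 1 ka to 2 Ma).
#'
#' @param path TSV file with header columns `sample_id`, `age_status`,
#'   `fixed_age`, `prior_lo`, `prior_hi`.
#' @return data frame with one row per sample.
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_table(tab)
}

#' @rdname read_sample_table
#' @param tab sample-table data frame.
#' @export
write_sample_table <- function(tab, path) {
  validate_sample_table(tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_sample_table <- function(tab) {
  need <- c("sample_id", "age_status", "fixed_age", "prior_lo", "prior_hi")
  for (cn in setdiff(need, names(tab))) tab[[cn]] <- NA_real_
  tab <- tab[need]
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in sample table")
  ok_status <- c("calibrated_fixed", "undated", "outgroup_modern")
  if (!all(tab$age_status %in% ok_status))
    stop("age_status must be one of ", paste(ok_status, collapse = ", "))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (r$age_status %in% c("calibrated_fixed", "outgroup_modern")) {
      if (is.na(r$fixed_age)) stop("fixed_age required for ", r$sample_id)
      if (r$fixed_age < 0) stop("negative age for ", r$sample_id)
      if (r$age_status == "outgroup_modern" && r$fixed_age != 0)
        stop("outgroup_modern samples must have fixed_age 0: ", r$sample_id)
    } else {
      if (is.na(r$prior_lo) || is.na(r$prior_hi))
        stop("undated sample ", r$sample_id, " needs prior_lo and prior_hi")
      if (!(r$prior_lo < r$prior_hi))
        stop("prior_lo must be < prior_hi for ", r$sample_id)
      if (r$prior_lo < 0) stop("negative age bound for ", r$sample_id)
    }
  }
  tab
}

#' Read and write MCMC traces
#'
#' A trace is a data frame of retained (post burn-in, thinned) MCMC
#' samples. The first four columns are `iteration`, `log_posterior`,
#' `log_likelihood` and `log_prior`, followed by one column per named
#' model parameter. Values round-trip at full double precision.
#'
#' @param trace trace data frame.
#' @param path TSV file path.
#' @return `read_trace()` returns the trace data frame.
#' @export
write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace), nrow(trace) >= 1L)
  need <- c("iteration", "log_posterior", "log_likelihood", "log_prior")
  if (!all(need %in% names(trace)))
    stop("trace must contain columns ", paste(need, collapse = ", "))
  out <- trace
  num <- vapply(out, is.numeric, logical(1))
  # full precision so write/read is lossless
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("iteration", "log_posterior", "log_likelihood", "log_prior")
  if (!all(need %in% names(tab)))
    stop("trace file lacks required columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  if (anyNA(tab$log_posterior) || any(!is.finite(tab$log_posterior)))
    stop("non-finite log_posterior in trace ", path)
  if (is.unsorted(tab$iteration, strictly = TRUE))
    stop("iteration indices must be strictly increasing")
  tab
}

#' Read and write pileup tables
#'
#' A pileup stores, for each reference position `1..L`, the read-base
#' counts over `{A,C,G,T,-}` used by consensus calling.
#'
#' @param path TSV with columns `pos`, `A`, `C`, `G`, `T`, `del`.
#' @return data frame with those columns.
#' @export
read_pileup <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_pileup(tab)
}

#' @rdname read_pileup
#' @param pileup pileup data frame.
#' @export
write_pileup <- function(pileup, path) {
  validate_pileup(pileup)
  utils::write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_pileup <- function(tab) {
  need <- c("pos", "A", "C", "G", "T", "del")
  if (!all(need %in% names(tab)))
    stop("pileup needs columns ", paste(need, collapse = ", "))
  tab <- tab[need]
  counts <- as.matrix(tab[, -1L])
  if (any(counts < 0) || any(counts != round(counts)))
    stop("pileup counts must be non-negative integers")
  if (!identical(tab$pos, seq_len(nrow(tab))) &&
      !identical(as.integer(tab$pos), seq_len(nrow(tab))))
    stop("pileup positions must be 1..L in order")
  tab
}

#' Read and write reference annotation tables
#'
#' Feature intervals on the ungapped reference, 1-based inclusive
#' (GenBank convention). `codon_phase_origin` gives, for CDS rows, the
#' reference coordinate carrying codon position 1.
#'
#' @param path TSV with columns `feature_class`, `start`, `end`,
#'   `codon_phase_origin`.
#' @return validated data frame.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_annotation(tab)
}

#' @rdname read_annotation
#' @param annotation annotation data frame.
#' @export
write_annotation <- function(annotation, path) {
  validate_annotation(annotation)
  utils::write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_annotation <- function(tab) {
  need <- c("feature_class", "start", "end")
  if (!all(need %in% names(tab)))
    stop("annotation needs columns ", paste(need, collapse = ", "))
  if (is.null(tab$codon_phase_origin)) tab$codon_phase_origin <- NA_real_
  classes <- c("tRNA", "rRNA", "CDS", "control_region", "VNTR")
  if (!all(tab$feature_class %in% classes))
    stop("feature_class must be one of ", paste(classes, collapse = ", "))
  if (any(tab$start < 1) || any(tab$end < tab$start))
    stop("annotation intervals must satisfy 1 <= start <= end")
  cds <- tab$feature_class == "CDS"
  if (any(cds & is.na(tab$codon_phase_origin)))
    stop("CDS rows require codon_phase_origin")
  # overlap between distinct classes only allowed for VNTR inside control_region
  n <- nrow(tab)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    a <- tab[i, ]; b <- tab[j, ]
    if (a$start <= b$end && b$start <= a$end &&
        a$feature_class != b$feature_class) {
      pair <- c(a$feature_class, b$feature_class)
      if (!setequal(pair, c("VNTR", "control_region")))
        stop("overlapping features of classes ", pair[1], " and ", pair[2])
    }
  }
  tab
}

# hash of an R object (config provenance); uses serialization + md5
config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2)
  unname(tools::md5sum(tmp))
}
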