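#' Haplotype alignment container
#'
#' A `hap_alignment` bundles an in-frame alignment of coding-strand haplotype
#' sequences with per-haplotype metadata (observed frequency, group label)
#' and the coordinate anchors every downstream stage needs: the alignment
#' column of the first complete codon (`frame_offset`, 0-based) and the
#' signed offset mapping alignment column 0 to a 1-based reference
#' coordinate (`ref_offset`).
#'
#' Columns containing a gap or `N` in any haplotype are recorded in
#' `excluded_columns` (0-based) and dropped from every downstream statistic.
#'
#' @param ids Character vector of haplotype labels (unique).
#' @param seqs Character vector of equal-length DNA strings over
#'   `{A,C,G,T,N,-}` (case-insensitive; stored uppercase).
#' @param group Group label per haplotype.
#' @param freq Non-negative integer count per haplotype (default 1 each).
#' @param frame_offset Integer in `{0,1,2}`.
#' @param ref_offset Signed integer; see [map_reference_position()].
#' @param code_table Genetic-code identifier, see [genetic_code()].
#' @return An object of class `hap_alignment`.
#' @export
hap_alignment <- function(ids, seqs, group, freq = rep(1L, length(ids)),
                          frame_offset = 0L, ref_offset = 0L,
                          code_table = "2") {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) {
    stop("`ids` and `seqs` must have the same length")
  }
  if (anyDuplicated(ids)) stop("duplicate haplotype ids")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences are not aligned: lengths ", paste(unique(lens), collapse = ", "))
  }
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    stop("sequence(s) contain characters outside {A,C,G,T,N,-}: ",
         paste(ids[bad], collapse = ", "))
  }
  freq <- as.integer(freq)
  if (any(is.na(freq)) || any(freq < 0)) stop("frequencies must be non-negative integers")
  group <- as.character(group)
  if (length(group) != length(ids)) stop("`group` must match `ids` in length")
  grp_tot <- tapply(freq, group, sum)
  if (any(grp_tot == 0)) {
    stop("group(s) with zero total frequency: ",
         paste(names(grp_tot)[grp_tot == 0], collapse = ", "))
  }
  frame_offset <- as.integer(frame_offset)
  if (!frame_offset %in% 0:2 || frame_offset >= lens[1]) {
    stop("`frame_offset` must be 0, 1 or 2 and smaller than the alignment length")
  }

  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  excl <- which(apply(mat, 2L, function(col) any(col %in% c("N", "-")))) - 1L

  structure(
    list(
      ids = ids,
      seqs = seqs,
      meta = tibble::tibble(id = ids, group = group, freq = freq),
      frame_offset = frame_offset,
      ref_offset = as.integer(ref_offset),
      code_table = as.character(code_table),
      excluded_columns = as.integer(excl),
      matrix = mat
    ),
    class = "hap_alignment"
  )
}

# character matrix (haplotypes x columns); cached on the alignment
seq_matrix <- function(x) {
  if (inherits(x, "hap_alignment")) return(x$matrix)
  do.call(rbind, strsplit(x, "", fixed = TRUE))
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat("<hap_alignment> ", length(x$ids), " haplotypes x ", nchar(x$seqs[1]),
      " columns\n", sep = "")
  tab <- dplyr::count(x$meta, .data$group, wt = .data$freq, name = "n")
  cat("  groups: ", paste0(tab$group, " (n=", tab$n, ")", collapse = ", "), "\n", sep = "")
  cat("  frame_offset ", x$frame_offset, ", ref_offset ", x$ref_offset,
      ", code table ", x$code_table, "\n", sep = "")
  if (length(x$excluded_columns)) {
    cat("  ", length(x$excluded_columns), " column(s) excluded (gap/N)\n", sep = "")
  }
  invisible(x)
}

#' @export
length.hap_alignment <- function(x) length(x$ids)

#' Alignment length in columns
#' @param aln A [hap_alignment()].
#' @return Integer number of alignment columns.
#' @export
n_columns <- function(aln) nchar(aln$seqs[1])

#' Segregating (polymorphic) alignment columns
#'
#' @param aln A [hap_alignment()].
#' @param include_excluded Keep columns flagged as containing gaps/N?
#' @return Integer vector of 0-based columns with more than one base among
#'   the haplotypes.
#' @export
segregating_columns <- function(aln, include_excluded = FALSE) {
  mat <- seq_matrix(aln)
  seg <- which(apply(mat, 2L, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")])) > 1L
  })) - 1L
  if (!include_excluded) seg <- setdiff(seg, aln$excluded_columns)
  as.integer(seg)
}

#' Read a haplotype alignment from FASTA plus a metadata table
#'
#' The metadata file is tab-separated with columns `id`, `group` and
#' (optionally) `freq`; ids must match the FASTA record names exactly. A
#' missing `freq` column, or missing individual values, defaults to 1 with a
#' warning.
#'
#' @param fasta_path Path to an aligned FASTA file.
#' @param meta_path Path to the TSV metadata file.
#' @inheritParams hap_alignment
#' @return A [hap_alignment()].
#' @export
read_alignment <- function(fasta_path, meta_path, frame_offset = 0L,
                           ref_offset = 0L, code_table = "2") {
  dna <- Biostrings::readBStringSet(fasta_path)
  ids <- names(dna)
  seqs <- toupper(as.character(dna))
  meta <- utils::read.delim(meta_path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("id", "group") %in% names(meta))) {
    stop("metadata must have columns `id` and `group`")
  }
  if (!setequal(meta$id, ids)) {
    stop("FASTA ids and metadata ids do not match")
  }
  meta <- meta[match(ids, meta$id), , drop = FALSE]
  if (is.null(meta$freq)) {
    warning("no `freq` column in metadata; defaulting all frequencies to 1")
    meta$freq <- 1L
  }
  if (anyNA(meta$freq)) {
    warning("missing frequencies defaulted to 1")
    meta$freq[is.na(meta$freq)] <- 1L
  }
  if (anyNA(meta$group) || any(!nzchar(meta$group))) {
    stop("unknown (empty) group label in metadata")
  }
  hap_alignment(ids, seqs, meta$group, meta$freq,
                frame_offset = frame_offset, ref_offset = ref_offset,
                code_table = code_table)
}

#' Write a haplotype alignment back to FASTA + TSV
#'
#' @param aln A [hap_alignment()].
#' @param fasta_path,meta_path Output paths.
#' @return `aln`, invisibly.
#' @export
write_alignment <- function(aln, fasta_path, meta_path) {
  set <- Biostrings::BStringSet(stats::setNames(aln$seqs, aln$ids))
  Biostrings::writeXStringSet(set, fasta_path)
  utils::write.table(aln$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(aln)
}

# 0-based columns of the codon containing `column` under the alignment frame
codon_columns <- function(column, frame_offset) {
  idx <- (column - frame_offset) %/% 3L
  frame_offset + idx * 3L + 0:2
}

# codon position 1|2|3 of an alignment column
codon_position <- function(column, frame_offset) {
  ((column - frame_offset) %% 3L) + 1L
}
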