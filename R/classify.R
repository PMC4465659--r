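#' Classify a single substitution
#'
#' Decides synonymy and the weak/strong direction class of one substitution
#' at an alignment column. The codon context is taken from the haplotypes
#' that carry the *from* allele at the focal column: at each of the two
#' non-focal codon positions the majority base among those haplotypes is
#' used, ties broken alphabetically. Synonymy is then
#' `translate(codon_from) == translate(codon_to)` under the alignment's
#' genetic code.
#'
#' @param aln A [hap_alignment()].
#' @param column 0-based alignment column of the substitution.
#' @param from_base,to_base The two alleles (must differ).
#' @param background_codon Optional length-3 string overriding the inferred
#'   codon context (the focal position within it is replaced by
#'   `from_base`/`to_base`).
#' @return A one-row tibble with `column`, `ref_position` (1-based reference
#'   coordinate), `from_base`, `to_base`, `codon_pos`, `codon_from`,
#'   `codon_to`, `aa_from`, `aa_to`, `synonymous`, `nonsense` (a stop codon
#'   is created or destroyed) and `ws_class`.
#' @export
#' @examples
#' aln <- hap_alignment(c("h1", "h2"), c("CTT", "CTC"), c("g", "g"))
#' classify_substitution(aln, 2, "T", "C") # CTT -> CTC, both Leu: synonymous W>S
classify_substitution <- function(aln, column, from_base, to_base,
                                  background_codon = NULL) {
  stopifnot(inherits(aln, "hap_alignment"))
  from_base <- toupper(from_base)
  to_base <- toupper(to_base)
  if (from_base == to_base) stop("`from_base` and `to_base` are identical: not a substitution")
  if (!from_base %in% c("A", "C", "G", "T") || !to_base %in% c("A", "C", "G", "T")) {
    stop("substitution bases must be in {A,C,G,T}")
  }
  L <- n_columns(aln)
  if (column < 0 || column >= L) stop("column out of range")

  cpos <- codon_position(column, aln$frame_offset)
  ccols <- codon_columns(column, aln$frame_offset)
  complete <- all(ccols >= 0 & ccols < L)

  if (is.null(background_codon)) {
    codon <- vapply(ccols, function(cc) {
      if (cc < 0 || cc >= L) return(NA_character_)
      consensus_base(aln, cc, focal_column = column, carrier_base = from_base)
    }, character(1))
  } else {
    background_codon <- toupper(background_codon)
    if (nchar(background_codon) != 3L) stop("`background_codon` must have length 3")
    codon <- strsplit(background_codon, "")[[1]]
  }

  codon_from <- codon
  codon_to <- codon
  codon_from[cpos] <- from_base
  codon_to[cpos] <- to_base

  usable <- complete && !anyNA(codon) && all(codon_from %in% c("A", "C", "G", "T"))
  if (!usable) {
    aa_from <- aa_to <- NA_character_
    synonymous <- NA
    nonsense <- NA
  } else {
    aa_from <- translate_codon(paste(codon_from, collapse = ""), aln$code_table)
    aa_to <- translate_codon(paste(codon_to, collapse = ""), aln$code_table)
    synonymous <- identical(aa_from, aa_to)
    nonsense <- xor(identical(aa_from, "*"), identical(aa_to, "*"))
    if (nonsense) synonymous <- FALSE
  }

  tibble::tibble(
    column = as.integer(column),
    ref_position = map_reference_position(as.integer(column), aln$ref_offset),
    from_base = from_base,
    to_base = to_base,
    codon_pos = as.integer(cpos),
    codon_from = if (usable) paste(codon_from, collapse = "") else NA_character_,
    codon_to = if (usable) paste(codon_to, collapse = "") else NA_character_,
    aa_from = aa_from,
    aa_to = aa_to,
    synonymous = synonymous,
    nonsense = nonsense,
    ws_class = ws_direction(from_base, to_base)
  )
}

# Majority base at `cc` among haplotypes carrying `carrier_base` at the focal
# column; ties broken alphabetically. NA when no carrier has an unambiguous
# base there.
consensus_base <- function(aln, cc, focal_column, carrier_base) {
  mat <- seq_matrix(aln)
  carriers <- mat[, focal_column + 1L] == carrier_base
  bases <- mat[carriers, cc + 1L]
  bases <- bases[bases %in% c("A", "C", "G", "T")]
  if (!length(bases)) return(NA_character_)
  tab <- table(bases)
  names(tab)[order(-tab, names(tab))][1]
}
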