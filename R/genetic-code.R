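#' Genetic-code tables and codon translation
#'
#' The package ships its own transcription of the NCBI translation tables it
#' needs. The default, table 2 (vertebrate mitochondrial), differs from the
#' standard code at four codons: AGA and AGG are stops, ATA is Met and TGA is
#' Trp. Stops are written `*`.
#'
#' @name genetic-code
#' @keywords internal
NULL

# NCBI transl_table 2 (vertebrate mitochondrial), transcribed base by base.
.MITO_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "M", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "W", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "*", AGG = "*",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# NCBI transl_table 1 (standard), kept for the configurable code_table slot.
.STANDARD_CODE <- {
  x <- .MITO_CODE
  x[c("AGA", "AGG")] <- "R"
  x["ATA"] <- "I"
  x["TGA"] <- "*"
  x
}

#' Look up a genetic-code table by identifier
#'
#' @param code_table `"2"`/`"vertebrate_mito"` (default used throughout the
#'   package) or `"1"`/`"standard"`.
#' @return Named character vector mapping all 64 codons to one-letter amino
#'   acids, with `*` for stop.
#' @export
#' @examples
#' genetic_code("2")[["TGA"]] # "W" in the vertebrate mitochondrial code
genetic_code <- function(code_table = "2") {
  switch(as.character(code_table),
    "2" = , "vertebrate_mito" = .MITO_CODE,
    "1" = , "standard" = .STANDARD_CODE,
    stop("unknown genetic code table: ", code_table)
  )
}

#' Translate one codon
#'
#' @param codon Length-3 DNA string over `{A,C,G,T}`.
#' @inheritParams genetic_code
#' @return One-letter amino acid, `*` for stop, or `NA_character_` when the
#'   codon contains an ambiguous base or gap.
#' @export
translate_codon <- function(codon, code_table = "2") {
  codon <- toupper(codon)
  tab <- genetic_code(code_table)
  unname(ifelse(codon %in% names(tab), tab[codon], NA_character_))
}

#' Classify a nucleotide as weak (W) or strong (S)
#'
#' Weak bases (A, T) pair with two hydrogen bonds; strong bases (G, C) with
#' three. Ambiguity codes and gaps have no class: the site must be excluded
#' by the caller.
#'
#' @param base Character vector of single bases (case-insensitive).
#' @return Character vector over `{"W","S"}`, `NA` for anything outside
#'   `{A,C,G,T}`.
#' @export
#' @examples
#' classify_ws(c("T", "C", "N"))
classify_ws <- function(base) {
  base <- toupper(base)
  out <- rep(NA_character_, length(base))
  out[base %in% c("A", "T")] <- "W"
  out[base %in% c("G", "C")] <- "S"
  out
}

# Direction label ("W>S", "S>W", "W>W", "S>S") for a from/to base pair.
ws_direction <- function(from_base, to_base) {
  f <- classify_ws(from_base)
  t <- classify_ws(to_base)
  ifelse(is.na(f) | is.na(t), NA_character_, paste0(f, ">", t))
}

#' Map an alignment column to a reference coordinate
#'
#' Alignment columns are 0-based internally; reported positions are 1-based
#' in the numbering of the reference mitochondrial sequence the alignment was
#' anchored to.
#'
#' @param column 0-based alignment column(s).
#' @param ref_offset Signed integer: reference coordinate of column 0 minus 1.
#' @return 1-based reference coordinate(s).
#' @seealso [reference_to_column()] for the exact inverse.
#' @export
#' @examples
#' map_reference_position(0, 15300) # 15301
map_reference_position <- function(column, ref_offset) {
  column + ref_offset + 1
}

#' @rdname map_reference_position
#' @param ref_position 1-based reference coordinate(s).
#' @export
reference_to_column <- function(ref_position, ref_offset) {
  ref_position - ref_offset - 1
}
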