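#' Synthetic three-haplotype diagnostic alignment
#'
#' Builds, entirely in code, a 1140-bp Cytb-like alignment of the three
#' main haplotypes of a two-species mitochondrial system: the ancestral
#' group BGa, its sister group BGp (two diagnostic T>C substitutions, 4
#' intervening nucleotides apart, both synonymous: a Leu TTA>CTA first
#' position and an Ala GCT>GCC third position), and a more distant group
#' SG (four further diagnostic columns). The six segregating columns map
#' to the reference coordinates 15627, 15966, 16004, 16206, 16211 and
#' 16502 under `ref_offset = 15380`. The invariant background is a
#' deterministic repeat of stop-free codons, so the fixture is synthetic:
#' only the diagnostic columns and their coordinates carry meaning.
#'
#' @param central_freq Frequencies of the three haplotypes (BGp, BGa, SG).
#' @return A [hap_alignment()] of three haplotypes.
#' @export
#' @examples
#' aln <- diagnostic_fixture()
#' map_reference_position(segregating_columns(aln), aln$ref_offset)
diagnostic_fixture <- function(central_freq = c(BGp = 30L, BGa = 40L, SG = 20L)) {
  L <- 1140L
  # deterministic stop-free background: repeating Leu/Ala/Thr/Phe codons
  background <- rep(c("CTA", "GCC", "ACA", "TTC"), length.out = L / 3L)

  # 0-based columns of the six diagnostic sites (reference pos - 15381)
  cols <- c(246L, 585L, 623L, 825L, 830L, 1121L)
  states <- rbind( # rows BGp, BGa, SG
    BGp = c("C", "A", "C", "C", "C", "A"),
    BGa = c("C", "A", "C", "T", "T", "A"),
    SG  = c("A", "C", "T", "T", "T", "G")
  )
  # codon backgrounds making the BGa/BGp pair and the third-position SG
  # sites synonymous: col 825 is pos 1 of a Leu codon (TTA/CTA), col 830
  # pos 3 of Ala (GCT/GCC), cols 623/1121 third positions (GCC/GCT,
  # GGA/GGG), cols 246/585 first positions (Leu/Ile, nonsynonymous by
  # frame geometry)
  codon_bg <- list(
    `246` = "CTT", `585` = "ATC", `623` = "GCC",
    `825` = "TTA", `830` = "GCT", `1121` = "GGA"
  )
  seqs <- vapply(rownames(states), function(h) {
    cod <- background
    for (i in seq_along(cols)) {
      col <- cols[i]
      cdn <- col %/% 3L + 1L
      pos <- col %% 3L + 1L
      base_codon <- codon_bg[[as.character(col)]]
      substr(base_codon, pos, pos) <- states[h, i]
      cod[cdn] <- base_codon
    }
    paste(cod, collapse = "")
  }, character(1))

  hap_alignment(
    ids = rownames(states), seqs = seqs, group = rownames(states),
    freq = unname(central_freq[rownames(states)]),
    frame_offset = 0L, ref_offset = 15380L, code_table = "2"
  )
}
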