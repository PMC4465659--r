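#' Transcribe coding-strand DNA to mRNA
#'
#' @param dna DNA string(s) over `{A,C,G,T}` (case-insensitive).
#' @return Uppercase RNA string(s) with T replaced by U.
#' @export
transcribe <- function(dna) {
  dna <- toupper(dna)
  if (any(grepl("[^ACGT]", dna))) stop("`dna` must contain only A, C, G, T")
  chartr("T", "U", dna)
}

.rna_code <- c(A = 0L, C = 1L, G = 2L, U = 3L)

encode_rna <- function(rna) {
  rna <- toupper(chartr("T", "U", rna))
  if (grepl("[^ACGU]", rna)) stop("sequence must contain only A, C, G, U (or T)")
  unname(.rna_code[strsplit(rna, "")[[1]]])
}

model_args <- function(model) {
  list(stack = model$dG_stack, hairpin = model$dG_hairpin,
       bulge = model$dG_bulge, internal_ = model$dG_internal,
       multi = unname(model$dG_multi), min_hairpin = model$min_hairpin,
       max_loop = model$max_loop)
}

new_rna_structure <- function(rna, pairing, energy, temperature) {
  structure(
    list(sequence = rna,
         dotbracket = pairing_to_dotbracket(pairing),
         pairs = pairing_to_pairs(pairing),
         energy = energy,
         temperature = temperature),
    class = "rna_structure"
  )
}

#' Predict the minimum-free-energy secondary structure
#'
#' Zuker-style dynamic programming over all nested structures under the
#' package's [energy_model()]. The returned structure is deterministic:
#' ties are broken by pairing the smallest position with its smallest
#' admissible partner.
#'
#' @param rna RNA (or DNA; T is read as U) string of length >= 1.
#' @param model An [energy_model()].
#' @return An `rna_structure`: `sequence`, `dotbracket`, `pairs` (two-column
#'   1-based matrix), `energy` (kcal/mol), `temperature`.
#' @export
#' @examples
#' fold_mfe("GGGAAACCC")$dotbracket
fold_mfe <- function(rna, model = energy_model()) {
  s <- encode_rna(rna)
  if (!length(s)) stop("empty sequence")
  if (length(s) > length(model$dG_hairpin)) {
    stop("sequence longer than the model's tabulated loop sizes (",
         length(model$dG_hairpin), " nt)")
  }
  res <- do.call(fold_mfe_cpp, c(list(seq = s), model_args(model)))
  new_rna_structure(toupper(chartr("T", "U", rna)), res$pairing, res$energy,
                    model$temperature)
}

#' Exhaustive-enumeration folding oracle
#'
#' Enumerates every nested pair set respecting the minimum-hairpin rule and
#' scores each with a loop-decomposition evaluator that is independent of
#' the dynamic program, returning the global minimum. Guarded to short
#' sequences; it exists to verify [fold_mfe()], not to replace it.
#'
#' @inheritParams fold_mfe
#' @param max_length Enumeration guard (default 25).
#' @return An `rna_structure` with attribute `n_structures`.
#' @export
brute_force_fold <- function(rna, model = energy_model(), max_length = 25L) {
  s <- encode_rna(rna)
  if (length(s) > max_length) {
    stop("brute_force_fold refuses sequences longer than ", max_length, " nt")
  }
  res <- do.call(brute_force_fold_cpp, c(list(seq = s), model_args(model)))
  out <- new_rna_structure(toupper(chartr("T", "U", rna)), res$pairing,
                           res$energy, model$temperature)
  attr(out, "n_structures") <- res$n_structures
  out
}

#' Energy of an arbitrary nested structure under a model
#'
#' @param rna RNA string.
#' @param dotbracket Structure in dot-bracket notation (same length).
#' @param model An [energy_model()].
#' @return Energy in kcal/mol; `Inf` for structures the model disallows.
#' @export
structure_energy <- function(rna, dotbracket, model = energy_model()) {
  s <- encode_rna(rna)
  pairing <- dotbracket_to_pairing(dotbracket)
  if (length(s) != length(pairing)) stop("sequence/structure length mismatch")
  do.call(structure_energy_cpp,
          c(list(seq = s, pairing = pairing), model_args(model)))
}

# pairing vector (0 = unpaired, else 1-based partner) -> helpers
pairing_to_pairs <- function(pairing) {
  i <- which(pairing > seq_along(pairing))
  m <- cbind(i = i, j = pairing[i])
  m[order(m[, 1]), , drop = FALSE]
}

pairing_to_dotbracket <- function(pairing) {
  out <- rep(".", length(pairing))
  out[pairing > seq_along(pairing)] <- "("
  out[pairing != 0 & pairing < seq_along(pairing)] <- ")"
  paste(out, collapse = "")
}

#' Convert dot-bracket notation to a pairing vector
#'
#' @param dotbracket String over `{(,),.}`.
#' @return Integer vector: 0 for unpaired, else the 1-based partner.
#' @export
dotbracket_to_pairing <- function(dotbracket) {
  ch <- strsplit(dotbracket, "")[[1]]
  if (any(!ch %in% c("(", ")", "."))) stop("dot-bracket must use only ( ) .")
  pairing <- integer(length(ch))
  stack <- integer(0)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      stack <- c(stack, k)
    } else if (ch[k] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket at position ", k)
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairing[i] <- k
      pairing[k] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched (")
  pairing
}

#' @export
print.rna_structure <- function(x, ...) {
  n <- nchar(x$sequence)
  cat("<rna_structure> ", n, " nt, ", nrow(x$pairs), " pairs, ",
      sprintf("%.3f", x$energy), " kcal/mol at ", x$temperature, " C\n",
      sep = "")
  if (n <= 80) {
    cat(" ", x$sequence, "\n ", x$dotbracket, "\n", sep = "")
  }
  invisible(x)
}

#' Write structures in Vienna two-line format
#'
#' @param structures A named list of `rna_structure` objects (names become
#'   record headers).
#' @param path Output path.
#' @export
write_vienna <- function(structures, path) {
  lines <- unlist(lapply(names(structures), function(nm) {
    st <- structures[[nm]]
    c(paste0(">", nm), st$sequence,
      sprintf("%s (%.2f)", st$dotbracket, st$energy))
  }))
  writeLines(lines, path)
  invisible(structures)
}

#' Read a FASTA of DNA or RNA sequences for folding
#'
#' @param path FASTA file; T and U are both accepted, sequences are
#'   returned as RNA.
#' @return Named character vector of RNA sequences.
#' @export
read_fold_input <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- toupper(chartr("T", "U", as.character(set)))
  stats::setNames(out, names(set))
}
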