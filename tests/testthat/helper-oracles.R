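# Independent oracles and small builders shared across the suite.

# Exhaustive two-tailed Fisher p for a 2x2 table: hypergeometric point
# probabilities from log-binomial coefficients, summed over every table
# with the observed margins whose probability is <= the observed one.
enum_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p <- exp(logp)
  obs <- p[support == tab[1, 1]]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# Frequency-expanded brute-force nucleotide diversity: replicate each
# haplotype `freq` times and average Hamming distances over all sequence
# pairs, per site.
brute_pi <- function(aln, columns, group = NULL, length_norm = length(columns)) {
  sel <- if (is.null(group)) rep(TRUE, length(aln$ids)) else aln$meta$group == group
  mat <- do.call(rbind, strsplit(aln$seqs[sel], ""))[, columns + 1L, drop = FALSE]
  expanded <- mat[rep(seq_len(nrow(mat)), aln$meta$freq[sel]), , drop = FALSE]
  n <- nrow(expanded)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- expanded[i, ]; b <- expanded[j, ]
      ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
      tot <- tot + sum(a[ok] != b[ok])
    }
  }
  tot / (n * (n - 1) / 2) / length_norm
}

# quick alignment builder with default single group
make_aln <- function(seqs, ids = paste0("h", seq_along(seqs)),
                     group = rep("g", length(seqs)),
                     freq = rep(1L, length(seqs)), ...) {
  hap_alignment(ids, seqs, group, freq, ...)
}

# random additive distance matrix from a random tree; returns both
random_additive <- function(n_taxa, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(n) stats::runif(n, 0.5, 5))
  d <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(d))
  list(tree = tr, d = d[ord, ord])
}

# random valid dot-bracket structure of length n (via MFE folds of random
# sequences, which always satisfy the structural invariants)
random_structure <- function(n, model = energy_model()) {
  s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
  fold_mfe(s, model)
}

# unordered multiset of (from, to) label pairs for tree comparison
topo_key <- function(tree) {
  ape::write.tree(ape::rotateConstr(tree, sort(tree$tip.label)))
}
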