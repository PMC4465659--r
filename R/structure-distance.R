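#' Base-pair distance between two secondary structures
#'
#' Size of the symmetric difference of the two base-pair sets. A true
#' metric on structures of a fixed length.
#'
#' @param s1,s2 `rna_structure` objects or dot-bracket strings of equal
#'   length.
#' @return Non-negative integer.
#' @export
#' @examples
#' bp_distance("(((...)))", "((.....))") # 1
bp_distance <- function(s1, s2) {
  p1 <- structure_pairs(s1)
  p2 <- structure_pairs(s2)
  if (attr(p1, "len") != attr(p2, "len")) {
    stop("structures have different lengths")
  }
  k1 <- paste(p1[, 1], p1[, 2])
  k2 <- paste(p2[, 1], p2[, 2])
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

structure_pairs <- function(s) {
  if (inherits(s, "rna_structure")) {
    out <- s$pairs
    attr(out, "len") <- nchar(s$dotbracket)
  } else {
    pairing <- dotbracket_to_pairing(s)
    out <- pairing_to_pairs(pairing)
    attr(out, "len") <- length(pairing)
  }
  out
}

#' Coarse-grained (homeomorphically reduced) structure distance
#'
#' Secondary metric: each structure is reduced to its shape string --
#' maximal helices collapsed to one bracket pair, unpaired runs to one dot
#' -- and compared by Levenshtein edit distance. Coarser than
#' [bp_distance()] and provided for qualitative comparison only.
#'
#' @inheritParams bp_distance
#' @return Non-negative integer edit distance between shape strings.
#' @export
shape_distance <- function(s1, s2) {
  as.integer(utils::adist(reduce_shape(s1), reduce_shape(s2)))
}

reduce_shape <- function(s) {
  db <- if (inherits(s, "rna_structure")) s$dotbracket else s
  p <- dotbracket_to_pairing(db)
  n <- length(p)
  if (!n) return("")
  # a pair (i,j) starts a helix unless (i-1, j+1) is also a pair
  helix_start <- function(i) !(i > 1 && p[i - 1] == p[i] + 1)
  out <- character(0)
  for (k in seq_len(n)) {
    if (p[k] == 0) {
      if (!length(out) || out[length(out)] != ".") out <- c(out, ".")
    } else if (p[k] > k) {
      if (helix_start(k)) out <- c(out, "(")
    } else {
      if (helix_start(p[k])) out <- c(out, ")")
    }
  }
  paste(out, collapse = "")
}

#' Structure distance matrices across a temperature sweep
#'
#' Folds every sequence at every temperature of the grid and returns one
#' pairwise distance matrix per temperature. With the default grid (1 to
#' 4 degrees C in steps of 0.1) this is 31 matrices.
#'
#' @param sequences Named character vector of RNA/DNA sequences (>= 3).
#' @param base_model Model to re-derive per temperature.
#' @param t_min,t_max,t_step Temperature grid, both ends inclusive.
#' @param metric `"bp"` (base-pair, default) or `"shape"`.
#' @return Named list of symmetric matrices, one per temperature; each
#'   carries its temperature in attribute `temperature`.
#' @export
sweep_distance_matrices <- function(sequences, base_model = energy_model(),
                                    t_min = 1.0, t_max = 4.0, t_step = 0.1,
                                    metric = c("bp", "shape")) {
  metric <- match.arg(metric)
  if (length(sequences) < 3) stop("need at least 3 sequences")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("`sequences` must have unique names")
  }
  grid <- temperature_grid(t_min, t_max, t_step, base_model)
  dist_fun <- if (metric == "bp") bp_distance else shape_distance
  lapply(grid, function(model) {
    folds <- lapply(sequences, fold_mfe, model = model)
    n <- length(folds)
    d <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d[i, j] <- d[j, i] <- dist_fun(folds[[i]], folds[[j]])
      }
    }
    attr(d, "temperature") <- model$temperature
    d
  })
}

#' Write / read a PHYLIP square distance matrix
#'
#' @param d Symmetric matrix with dimnames.
#' @param path File path.
#' @return `read_phylip_dist()` returns the matrix.
#' @export
write_phylip_dist <- function(d, path) {
  n <- nrow(d)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste0(formatC(rownames(d)[i], width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = "  "))
             }, character(1)))
  writeLines(lines, path)
  invisible(d)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  parts <- strsplit(trimws(lines[1 + seq_len(n)]), "[[:space:]]+")
  labels <- vapply(parts, `[[`, character(1), 1)
  d <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
  dimnames(d) <- list(labels, labels)
  d
}
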