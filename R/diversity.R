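#' Nucleotide diversity over a set of alignment columns
#'
#' Frequency-weighted average pairwise difference per site:
#' \deqn{\pi = \frac{\sum_{i<j} f_i f_j d_{ij}}{\binom{n}{2} L}}
#' with \eqn{f} the haplotype frequencies, \eqn{n = \sum f}, \eqn{d_{ij}}
#' the Hamming distance over the chosen columns and \eqn{L} the
#' normalising length (by default the number of columns supplied).
#'
#' @param aln A [hap_alignment()].
#' @param columns 0-based alignment columns (non-empty).
#' @param group Restrict to one group's haplotypes (default: all).
#' @param length_norm Length to divide by; defaults to `length(columns)`.
#'   Sliding windows pass the window width here so that class-restricted
#'   column subsets stay on the per-window-site scale.
#' @return Nucleotide diversity (non-negative double).
#' @export
nucleotide_diversity <- function(aln, columns, group = NULL,
                                 length_norm = length(columns)) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (!length(columns)) stop("`columns` must be non-empty")
  sel <- if (is.null(group)) rep(TRUE, length(aln$ids)) else aln$meta$group == group
  freq <- aln$meta$freq[sel]
  n <- sum(freq)
  if (n < 2) stop("need total frequency >= 2 to compute diversity")
  mat <- seq_matrix(aln)[sel, columns + 1L, drop = FALSE]
  sum(per_column_mismatch(mat, freq)) / (n * (n - 1) / 2) / length_norm
}

# per-column sum over pairs f_i f_j [base_i != base_j]; gap/N carriers are
# ignored at that column (pairs involving them contribute 0)
per_column_mismatch <- function(mat, freq) {
  apply(mat, 2L, function(col) {
    ok <- col %in% c("A", "C", "G", "T")
    cb <- tapply(freq[ok], col[ok], sum)
    t <- sum(cb)
    (t^2 - sum(cb^2)) / 2
  })
}

#' Sliding-window nucleotide diversity profile, partitioned by mutation class
#'
#' Slides a window of `width` bp by `step` bp along the alignment and
#' computes, per window, total nucleotide diversity and the diversity
#' contributed by columns whose oriented mutation class is W>S or S>W.
#' Columns with undefined orientation contribute to the total but to
#' neither class. All windows are normalised by their own length (`width`,
#' or less for a flagged truncated terminal window).
#'
#' @param aln A [hap_alignment()].
#' @param oriented Tibble from [orient_mutations()]; used to assign a class
#'   to segregating columns. When `group` is given, only that group's
#'   oriented mutations define the class columns.
#' @param width Window width in bp (default 100).
#' @param step Window slide in bp (default 10).
#' @param group Restrict to one group's haplotypes (default: all).
#' @return A tibble of class `window_profile`: `group`, `start`, `end`
#'   (0-based, half-open), `center`, `ref_center` (1-based reference
#'   coordinate of the center), `truncated`, `pi_total`, `pi_ws`, `pi_sw`.
#'   Attributes `width` and `step` record the parameters.
#' @export
sliding_profile <- function(aln, oriented, width = 100L, step = 10L,
                            group = NULL) {
  stopifnot(inherits(aln, "hap_alignment"))
  L <- n_columns(aln)
  if (width > L) stop("`width` exceeds the alignment length")
  if (step < 1) stop("`step` must be >= 1")

  om <- oriented
  if (!is.null(group)) om <- om[!is.na(om$group) & om$group == group, ]
  class_of <- function(cl) {
    cols <- unique(om$column[!is.na(om$ws_class) & om$ws_class == cl])
    setdiff(cols, aln$excluded_columns)
  }
  ws_cols <- class_of("W>S")
  sw_cols <- class_of("S>W")

  sel <- if (is.null(group)) rep(TRUE, length(aln$ids)) else aln$meta$group == group
  freq <- aln$meta$freq[sel]
  n <- sum(freq)
  if (n < 2) stop("need total frequency >= 2 in the selected group")
  mat <- seq_matrix(aln)[sel, , drop = FALSE]
  contrib <- per_column_mismatch(mat, freq)
  contrib[aln$excluded_columns + 1L] <- 0
  denom_pairs <- n * (n - 1) / 2

  starts <- seq(0L, L - width, by = step)
  # one flagged truncated terminal window when full windows fall short of L
  if (starts[length(starts)] + width < L) {
    starts <- c(starts, starts[length(starts)] + step)
  }
  rows <- lapply(starts, function(s) {
    e <- min(s + width, L)
    cols <- s:(e - 1L)
    win_len <- e - s
    pi_of <- function(cset) {
      cc <- intersect(cols, cset)
      if (!length(cc)) return(0)
      sum(contrib[cc + 1L]) / denom_pairs / win_len
    }
    tibble::tibble(
      group = if (is.null(group)) NA_character_ else group,
      start = s, end = e,
      center = (s + e - 1) / 2,
      ref_center = map_reference_position((s + e - 1) / 2, aln$ref_offset),
      truncated = win_len < width,
      pi_total = sum(contrib[cols + 1L]) / denom_pairs / win_len,
      pi_ws = pi_of(ws_cols),
      pi_sw = pi_of(sw_cols)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (all(out$pi_total == 0)) {
    warning("no diversity in any window (all-zero profile)")
  }
  attr(out, "width") <- as.integer(width)
  attr(out, "step") <- as.integer(step)
  class(out) <- c("window_profile", class(out))
  out
}

#' Write a window profile as TSV
#' @param profile A [sliding_profile()] result (or several row-bound).
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(profile)
}
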