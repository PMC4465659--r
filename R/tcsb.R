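#' Tally a weak/strong mutation spectrum per group
#'
#' Counts oriented *synonymous* mutations into the four direction classes
#' W>S, S>W, W>W and S>S. Nonsynonymous mutations are excluded from the
#' counts and reported in the `n_excluded_nonsyn` column; mutations whose
#' class or synonymy could not be determined (ambiguous context) are
#' likewise excluded and counted in `n_excluded_undetermined`.
#'
#' @param oriented Tibble from [orient_mutations()].
#' @param groups Groups to tally (default: all present).
#' @return A tibble of class `mutation_spectrum`, one row per group and
#'   class: `group`, `ws_class`, `n`, `pct` (percentage of the group's
#'   classified synonymous total), plus the per-group exclusion counts.
#' @export
tally_spectrum <- function(oriented, groups = NULL) {
  if (is.null(groups)) groups <- sort(unique(oriented$group))
  classes <- c("W>S", "S>W", "W>W", "S>S")
  out <- lapply(groups, function(g) {
    m <- oriented[!is.na(oriented$group) & oriented$group == g, ]
    undet <- is.na(m$synonymous) | is.na(m$ws_class)
    nonsyn <- !undet & !m$synonymous
    syn <- m[!undet & m$synonymous, ]
    n <- unname(vapply(classes, function(cl) sum(syn$ws_class == cl), integer(1)))
    tot <- sum(n)
    tibble::tibble(
      group = g, ws_class = classes, n = n,
      pct = if (tot > 0) 100 * n / tot else rep(0, 4L),
      n_excluded_nonsyn = sum(nonsyn),
      n_excluded_undetermined = sum(undet)
    )
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("mutation_spectrum", class(out))
  out
}

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Direct hypergeometric computation: with margins fixed, the two-tailed
#' p-value is the sum of the point probabilities of every table at most as
#' probable as the observed one (relative tolerance 1 + 1e-7, the
#' convention of mainstream statistical software). A table with a zero
#' margin carries no information and returns 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-tailed p-value in `[0, 1]`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)) # 1
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("`tab` must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) stop("`tab` must hold non-negative integers")
  m <- sum(tab[1, ])          # row-1 total
  n <- sum(tab[2, ])          # row-2 total
  k <- sum(tab[, 1])          # column-1 total
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  p <- sum(d[d <= d[support == x] * (1 + 1e-7)])
  min(max(p, 0), 1)
}

#' Compare the W/S direction bias of two groups (TCSB)
#'
#' The Test of Centrifugal Substitution Bias: the W>S and S>W counts of the
#' two groups form a 2x2 table compared by the two-tailed Fisher exact
#' test. W>W and S>S transversions do not alter the GC content and are not
#' part of the table.
#'
#' @param spectrum A [tally_spectrum()] result containing both groups.
#' @param group_a,group_b Group labels to compare.
#' @return An object of class `tcsb_test`: list with `groups`, `table`
#'   (2x2 matrix, rows = groups, cols = `W>S`/`S>W`) and `p_value`.
#' @export
compare_groups <- function(spectrum, group_a, group_b) {
  get_counts <- function(g) {
    s <- spectrum[spectrum$group == g, ]
    if (!nrow(s)) stop("group not present in spectrum: ", g)
    c(`W>S` = s$n[s$ws_class == "W>S"], `S>W` = s$n[s$ws_class == "S>W"])
  }
  tab <- rbind(get_counts(group_a), get_counts(group_b))
  rownames(tab) <- c(group_a, group_b)
  if (all(tab == 0)) {
    warning("both groups have zero W<->S mutations; p = 1")
    p <- 1
  } else {
    p <- fisher_exact_2x2(tab)
  }
  structure(list(groups = c(group_a, group_b), table = tab, p_value = p),
            class = "tcsb_test")
}

#' All pairwise TCSB comparisons
#'
#' @param spectrum A [tally_spectrum()] result.
#' @return Tibble with one row per unordered group pair: the four counts
#'   and the two-tailed p-value (unadjusted, as is conventional for this
#'   test's small number of planned comparisons).
#' @export
compare_all_groups <- function(spectrum) {
  gs <- unique(spectrum$group)
  if (length(gs) < 2) stop("need at least two groups")
  pairs <- utils::combn(gs, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    t <- compare_groups(spectrum, pairs[1, i], pairs[2, i])
    tibble::tibble(
      group_a = pairs[1, i], group_b = pairs[2, i],
      ws_a = t$table[1, 1], sw_a = t$table[1, 2],
      ws_b = t$table[2, 1], sw_b = t$table[2, 2],
      p_value = t$p_value
    )
  })
}

#' @export
print.tcsb_test <- function(x, ...) {
  cat("Test of Centrifugal Substitution Bias:",
      paste(x$groups, collapse = " vs "), "\n")
  print(x$table)
  cat("two-tailed Fisher exact p =", format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a TCSB test
#' @param x A `tcsb_test`.
#' @param ... Unused.
#' @return One row per group with its W>S / S>W counts and the shared
#'   p-value.
#' @export
tidy.tcsb_test <- function(x, ...) {
  tibble::tibble(
    group = x$groups,
    n_ws = x$table[, 1],
    n_sw = x$table[, 2],
    p_value = x$p_value
  )
}

#' @rdname tidy.tcsb_test
#' @return `glance()`: a one-row summary.
#' @export
glance.tcsb_test <- function(x, ...) {
  tibble::tibble(
    comparison = paste(x$groups, collapse = " vs "),
    n_total = sum(x$table),
    p_value = x$p_value
  )
}

#' Write spectra and test results
#'
#' @param spectrum A [tally_spectrum()] result.
#' @param tests A [compare_all_groups()] result.
#' @param spectrum_path TSV output path for the spectrum.
#' @param tests_path JSON output path for the tests.
#' @return Invisibly, `NULL`.
#' @export
write_tcsb_results <- function(spectrum, tests, spectrum_path, tests_path) {
  utils::write.table(as.data.frame(spectrum), spectrum_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(tests, tests_path, dataframe = "rows", digits = NA)
  invisible(NULL)
}
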