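#' Leaf bipartitions of an unrooted tree
#'
#' Every internal edge splits the leaf set in two; the split is recorded
#' canonically as the side *not* containing the alphabetically first leaf
#' label.
#'
#' @param tree An `ape::phylo`.
#' @return Character vector of canonical splits (labels sorted, joined by
#'   `|`); trivial splits (single leaf) are omitted.
#' @export
tree_bipartitions <- function(tree) {
  labs <- sort(tree$tip.label)
  ref <- labs[1]
  n <- length(tree$tip.label)
  splits <- character(0)
  # leaves below each internal node (tree rooted arbitrarily by ape)
  for (node in (n + 1):(n + tree$Nnode)) {
    tips <- tree$tip.label[phangorn_descendants(tree, node)]
    side <- if (ref %in% tips) setdiff(labs, tips) else tips
    if (length(side) >= 2 && length(side) <= n - 2) {
      splits <- c(splits, paste(sort(side), collapse = "|"))
    }
  }
  unique(splits)
}

# tip indices below `node` (iterative, no deps)
phangorn_descendants <- function(tree, node) {
  n <- length(tree$tip.label)
  stack <- node
  tips <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= n) {
      tips <- c(tips, v)
    } else {
      stack <- c(stack, tree$edge[tree$edge[, 1] == v, 2])
    }
  }
  tips
}

#' Majority-rule consensus tree with temperature-sweep supports
#'
#' Retains exactly the bipartitions present in more than half of the input
#' trees (strict majority; no extended-majority completion) and annotates
#' each with its occurrence percentage. For trees produced across a
#' temperature sweep these supports measure the stability of a grouping to
#' the folding temperature, not statistical support.
#'
#' @param trees List of `ape::phylo` objects (or an `ape::multiPhylo`)
#'   sharing one leaf set.
#' @return An `ape::phylo` whose internal node labels are the support
#'   percentages (formatted to one decimal); also carries attribute
#'   `splits`, a tibble of every observed split and its support.
#' @export
majority_consensus <- function(trees) {
  trees <- unclass(trees)
  if (!length(trees)) stop("no trees supplied")
  leaf_sets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(leaf_sets, identical, logical(1), leaf_sets[[1]]))) {
    stop("trees do not share one leaf set")
  }
  labs <- leaf_sets[[1]]
  ntree <- length(trees)

  split_counts <- table(unlist(lapply(trees, tree_bipartitions)))
  support <- 100 * as.vector(split_counts) / ntree
  splits_tbl <- tibble::tibble(
    split = names(split_counts),
    n = as.vector(split_counts),
    support = support
  )
  keep <- splits_tbl[splits_tbl$n > ntree / 2, ]
  keep <- keep[order(-lengths(strsplit(keep$split, "|", fixed = TRUE))), ]

  # assemble: nest strict-majority clusters (mutually compatible by
  # counting), rooted at the reference leaf side
  clusters <- strsplit(keep$split, "|", fixed = TRUE)
  tree <- build_consensus_tree(labs, clusters, keep$support)
  attr(tree, "splits") <- splits_tbl
  tree
}

build_consensus_tree <- function(labs, clusters, supports) {
  # node: list(members, support, children = list of nodes or leaf labels);
  # clusters arrive largest-first, so each nests under an existing node
  root <- list(members = labs, support = NA_real_, children = as.list(labs))
  for (k in seq_along(clusters)) {
    root <- insert_into(root, clusters[[k]], supports[k])
  }
  nwk <- paste0(node_to_newick(root), ";")
  ape::read.tree(text = nwk)
}

insert_into <- function(node, members, support) {
  for (i in seq_along(node$children)) {
    ch <- node$children[[i]]
    if (!is.character(ch) && all(members %in% ch$members) &&
        length(ch$members) > length(members)) {
      node$children[[i]] <- insert_into(ch, members, support)
      return(node)
    }
  }
  inside <- vapply(node$children, function(ch) {
    chm <- if (is.character(ch)) ch else ch$members
    all(chm %in% members)
  }, logical(1))
  new_node <- list(members = members, support = support,
                   children = node$children[inside])
  node$children <- c(node$children[!inside], list(new_node))
  node
}

node_to_newick <- function(node) {
  parts <- vapply(node$children, function(ch) {
    if (is.character(ch)) ch else node_to_newick(ch)
  }, character(1))
  lab <- if (is.na(node$support)) "" else sprintf("%.1f", node$support)
  paste0("(", paste(parts, collapse = ","), ")", lab)
}

#' Write / parse Newick trees
#'
#' Thin wrappers over `ape`'s Newick support, so that supports serialised
#' as internal node labels round-trip. A multi-tree file holds one Newick
#' string per line.
#'
#' @param tree An `ape::phylo` (or list of them for [write_newick_file()]).
#' @return `write_newick()` the Newick string; `parse_newick()` an
#'   `ape::phylo`.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' @rdname write_newick
#' @param text Newick string.
#' @export
parse_newick <- function(text) {
  out <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(out)) stop("malformed Newick: ", substr(text, 1, 60))
  out
}

#' @rdname write_newick
#' @param trees List of trees.
#' @param path File path.
#' @export
write_newick_file <- function(trees, path) {
  writeLines(vapply(trees, write_newick, character(1)), path)
  invisible(trees)
}

#' @rdname write_newick
#' @export
read_newick_file <- function(path) {
  lapply(readLines(path), parse_newick)
}
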