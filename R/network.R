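#' Build a haplotype network under a parsimony criterion
#'
#' Constructs a minimum-spanning network: every edge that occurs in at least
#' one minimum spanning tree of the Hamming-distance graph is retained, so
#' tied alternatives produce reticulations instead of being broken
#' arbitrarily. Distances are counted over included columns only (columns
#' flagged gap/N are ignored). Identical haplotypes within a group are
#' collapsed first, frequencies summed.
#'
#' @param aln A [hap_alignment()] with at least 2 distinct haplotypes.
#' @return A `hap_network`: list with `nodes` (tibble: `id`, `group`, `freq`,
#'   `members`), `edges` (tibble: `from`, `to`, `length`, `columns`
#'   (list-column of 0-based differing columns), `in_mst` (always TRUE) ) and
#'   the source alignment in `$alignment`.
#' @export
build_network <- function(aln) {
  stopifnot(inherits(aln, "hap_alignment"))
  keep_cols <- setdiff(seq_len(n_columns(aln)) - 1L, aln$excluded_columns)

  # collapse duplicates (same sequence, same group)
  key <- paste(aln$seqs, aln$meta$group, sep = "\r")
  first <- !duplicated(key)
  idx_of <- match(key, key[first])
  nodes <- tibble::tibble(
    id = aln$ids[first],
    group = aln$meta$group[first],
    freq = as.integer(tapply(aln$meta$freq, idx_of, sum)[as.character(seq_len(sum(first)))]),
    members = unname(split(aln$ids, idx_of))
  )
  seqs <- aln$seqs[first]
  n <- nrow(nodes)
  if (n < 2L) stop("need at least 2 distinct haplotypes to build a network")

  mat <- seq_matrix(seqs)[, keep_cols + 1L, drop = FALSE]
  pairs <- utils::combn(n, 2L)
  diffs <- apply(pairs, 2L, function(p) {
    a <- mat[p[1], ]; b <- mat[p[2], ]
    keep_cols[a != b & a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")]
  }, simplify = FALSE)
  w <- lengths(diffs)

  # Kruskal with tie classes: an edge belongs to some MST iff its endpoints
  # are not yet connected using strictly lighter edges.
  ord <- order(w)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  keep <- logical(ncol(pairs))
  k <- 1L
  while (k <= length(ord)) {
    wk <- w[ord[k]]
    block <- ord[seq(k, length(ord))][w[ord[seq(k, length(ord))]] == wk]
    keep[block] <- vapply(block, function(e) {
      find(pairs[1, e]) != find(pairs[2, e])
    }, logical(1))
    for (e in block[keep[block]]) {
      ra <- find(pairs[1, e]); rb <- find(pairs[2, e])
      if (ra != rb) parent[ra] <- rb
    }
    k <- k + length(block)
  }
  if (any(w[keep] == 0L)) {
    # identical sequences in different groups stay distinct nodes,
    # linked by a zero-length edge
    warning("zero-length edge(s): identical haplotypes in different groups")
  }

  edges <- tibble::tibble(
    from = nodes$id[pairs[1, keep]],
    to = nodes$id[pairs[2, keep]],
    length = as.integer(w[keep]),
    columns = diffs[keep]
  )
  structure(list(nodes = nodes, edges = edges, alignment = aln),
            class = "hap_network")
}

#' @export
print.hap_network <- function(x, ...) {
  cat("<hap_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  print(x$edges[, c("from", "to", "length")], n = 10)
  invisible(x)
}

# adjacency list: named list id -> tibble rows of incident edges
.adjacency <- function(net) {
  ids <- net$nodes$id
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    adj[[e$from]] <- c(adj[[e$from]], list(list(other = e$to, edge = i)))
    adj[[e$to]] <- c(adj[[e$to]], list(list(other = e$from, edge = i)))
  }
  adj
}

#' Identify the central haplotype of a group
#'
#' The central haplotype is the presumed ancestral hub of a group's
#' star-like radiation.
#'
#' @param net A [build_network()] result.
#' @param group Group label.
#' @param method `"frequency"` (highest observed frequency) or `"degree"`
#'   (highest within-group degree). Ties broken by frequency, then by label.
#' @return Node id (character scalar).
#' @export
identify_central <- function(net, group, method = c("frequency", "degree")) {
  method <- match.arg(method)
  nd <- net$nodes[net$nodes$group == group, ]
  if (!nrow(nd)) stop("no haplotypes in group: ", group)
  if (method == "degree") {
    within <- net$edges$from %in% nd$id & net$edges$to %in% nd$id
    deg <- vapply(nd$id, function(id) {
      sum(net$edges$from[within] == id) + sum(net$edges$to[within] == id)
    }, integer(1))
    nd$key <- deg
  } else {
    nd$key <- nd$freq
  }
  nd <- nd[order(-nd$key, -nd$freq, nd$id), ]
  nd$id[1]
}

#' Orient every mutation centrifugally from a central haplotype
#'
#' Breadth-first search from the central node assigns each node a depth;
#' every edge between depths d and d+1 is read from the shallower to the
#' deeper node, and each differing column on it becomes one oriented
#' mutation with `from_base` taken from the shallower node. Edges joining
#' two nodes of equal depth (reticulation ties) cannot be oriented and are
#' dropped with a warning.
#'
#' @param net A [build_network()] result.
#' @param central Node id to orient from (see [identify_central()]).
#' @return A tibble of oriented mutations: the columns of
#'   [classify_substitution()] plus `from_node`, `to_node`, `group` (group
#'   of the receiving node) and `depth` (BFS depth of the receiving node).
#'   The number of dropped (unorientable) edges is in attribute
#'   `n_unoriented_edges`.
#' @export
orient_mutations <- function(net, central) {
  stopifnot(inherits(net, "hap_network"))
  if (!central %in% net$nodes$id) stop("unknown central node: ", central)
  aln <- net$alignment

  # BFS depths
  depth <- stats::setNames(rep(NA_integer_, nrow(net$nodes)), net$nodes$id)
  depth[central] <- 0L
  adj <- .adjacency(net)
  queue <- central
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (nb in adj[[v]]) {
      if (is.na(depth[nb$other])) {
        depth[nb$other] <- depth[v] + 1L
        queue <- c(queue, nb$other)
      }
    }
  }
  if (anyNA(depth)) {
    stop("network is not connected; cannot orient from ", central)
  }

  seqs <- stats::setNames(aln$seqs[match(net$nodes$id, aln$ids)], net$nodes$id)
  group_of <- stats::setNames(net$nodes$group, net$nodes$id)

  rows <- list()
  n_dropped <- 0L
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    d1 <- depth[e$from]; d2 <- depth[e$to]
    if (d1 == d2) {
      n_dropped <- n_dropped + 1L
      next
    }
    shallow <- if (d1 < d2) e$from else e$to
    deep <- if (d1 < d2) e$to else e$from
    for (col in e$columns[[1]]) {
      fb <- substr(seqs[shallow], col + 1L, col + 1L)
      tb <- substr(seqs[deep], col + 1L, col + 1L)
      cls <- classify_substitution(aln, col, fb, tb)
      cls$from_node <- shallow
      cls$to_node <- deep
      cls$group <- unname(group_of[deep])
      cls$depth <- unname(depth[deep])
      rows[[length(rows) + 1L]] <- cls
    }
  }
  if (n_dropped > 0L) {
    warning(n_dropped, " edge(s) between equal-depth nodes dropped from orientation")
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty_oriented_tbl()
  attr(out, "n_unoriented_edges") <- n_dropped
  attr(out, "central") <- central
  out
}

empty_oriented_tbl <- function() {
  tibble::tibble(
    column = integer(), ref_position = integer(), from_base = character(),
    to_base = character(), codon_pos = integer(), codon_from = character(),
    codon_to = character(), aa_from = character(), aa_to = character(),
    synonymous = logical(), nonsense = logical(), ws_class = character(),
    from_node = character(), to_node = character(), group = character(),
    depth = integer()
  )
}

#' Export a network as an edge-list TSV
#'
#' @param net A [build_network()] result.
#' @param path Output path.
#' @return `net`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  df <- net$edges
  df$columns <- vapply(df$columns, paste, character(1), collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(net)
}

#' Export a network as GraphML
#'
#' Minimal GraphML with node attributes `group` and `freq` and edge
#' attribute `length`.
#'
#' @inheritParams write_network_tsv
#' @export
write_network_graphml <- function(net, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '<key id="group" for="node" attr.name="group" attr.type="string"/>',
    '<key id="freq" for="node" attr.name="freq" attr.type="int"/>',
    '<key id="length" for="edge" attr.name="length" attr.type="int"/>',
    '<graph edgedefault="undirected">',
    vapply(seq_len(nrow(net$nodes)), function(i) {
      nd <- net$nodes[i, ]
      sprintf('<node id="%s"><data key="group">%s</data><data key="freq">%d</data></node>',
              esc(nd$id), esc(nd$group), nd$freq)
    }, character(1)),
    vapply(seq_len(nrow(net$edges)), function(i) {
      e <- net$edges[i, ]
      sprintf('<edge source="%s" target="%s"><data key="length">%d</data></edge>',
              esc(e$from), esc(e$to), e$length)
    }, character(1)),
    "</graph>", "</graphml>"
  )
  writeLines(lines, path)
  invisible(net)
}
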