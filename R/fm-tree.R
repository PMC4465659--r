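#' Fitch-Margoliash least-squares tree from a distance matrix
#'
#' Minimises the weighted least-squares mismatch between the input
#' distances and the tree's path lengths,
#' \deqn{\sum_{i<j} w_{ij}\,(d_{ij} - p_{ij})^2,\qquad w_{ij} = 1/d_{ij}^2,}
#' the classic Fitch-Margoliash weighting. Zero input distances are treated
#' as (numerically) exact constraints by giving them a weight far above
#' every finite \eqn{1/d^2}. The topology is found by sequential taxon
#' addition in input order followed by one full round of
#' nearest-neighbour-interchange refinement; branch lengths are the WLS
#' estimates with negative values clamped to zero. On an additive matrix
#' the generating topology and branch lengths are recovered exactly
#' (residual 0).
#'
#' @param d Symmetric distance matrix with row/column names, >= 3 taxa.
#' @return An unrooted `ape::phylo` tree with attributes `objective` (the
#'   weighted residual sum of squares) and `fitted` (the fitted path-length
#'   matrix).
#' @export
fitch_margoliash <- function(d) {
  d <- as.matrix(d)
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  if (is.null(labels) || anyDuplicated(labels)) stop("`d` must have unique row names")
  if (any(abs(d - t(d)) > 1e-9) || any(diag(d) != 0) || any(d < 0)) {
    stop("`d` must be symmetric, non-negative, with zero diagonal")
  }

  if (all(d == 0)) {
    warning("all distances are zero; returning a star tree with zero branches")
    nwk <- paste0("(", paste0(labels, ":0", collapse = ","), ");")
    tree <- ape::read.tree(text = nwk)
    attr(tree, "objective") <- 0
    return(tree)
  }

  pr <- utils::combn(n, 2L)
  dv <- d[cbind(pr[1, ], pr[2, ])]
  w <- ifelse(dv > 0, 1 / dv^2, NA)
  w[is.na(w)] <- 1e6 * max(w, na.rm = TRUE)

  # tree state: edge matrix of node ids; leaves 1..n, internals > n
  edges <- rbind(c(1L, n + 1L), c(2L, n + 1L), c(3L, n + 1L))
  next_node <- n + 2L

  fit_tree <- function(edges, taxa) {
    A <- path_incidence(edges, taxa)
    sub <- pr[1, ] %in% taxa & pr[2, ] %in% taxa
    y <- dv[sub]
    ww <- w[sub]
    fit <- stats::lm.wfit(A, y, ww)
    b <- fit$coefficients
    b[is.na(b)] <- 0
    b <- pmax(b, 0)
    resid <- y - as.vector(A %*% b)
    list(lengths = b, objective = sum(ww * resid^2))
  }

  for (t in seq(4L, length.out = max(0L, n - 3L))) {
    taxa <- 1:t
    best <- NULL
    for (e in seq_len(nrow(edges))) {
      cand <- subdivide(edges, e, t, next_node)
      f <- fit_tree(cand, taxa)
      if (is.null(best) || f$objective < best$objective - 1e-12) {
        best <- list(edges = cand, objective = f$objective)
      }
    }
    edges <- best$edges
    next_node <- next_node + 1L
  }

  # one full NNI pass over internal edges
  taxa <- 1:n
  cur <- fit_tree(edges, taxa)$objective
  internal <- which(edges[, 1] > n & edges[, 2] > n)
  for (e in internal) {
    for (alt in nni_alternatives(edges, e)) {
      f <- fit_tree(alt, taxa)
      if (f$objective < cur - 1e-12) {
        edges <- alt
        cur <- f$objective
      }
    }
  }

  final <- fit_tree(edges, taxa)
  tree <- edges_to_phylo(edges, final$lengths, labels)
  attr(tree, "objective") <- final$objective
  attr(tree, "fitted") <- fitted_path_matrix(edges, final$lengths, labels)
  tree
}

# rows = leaf pairs (combn order over `taxa`), cols = edges; entry 1 when
# the edge lies on the path between the pair. Built from root-path
# indicator vectors: path(i,j) = xor of the two root paths.
path_incidence <- function(edges, taxa) {
  m <- nrow(edges)
  top <- max(edges)
  B <- matrix(0, top, m)
  # BFS from an arbitrary internal node, recording the incoming edge
  root <- top
  parent <- rep(NA_integer_, top)
  visited <- logical(top)
  visited[root] <- TRUE
  queue <- root
  order_out <- integer(0)
  in_edge <- rep(NA_integer_, top)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order_out <- c(order_out, v)
    inc <- which(edges[, 1] == v | edges[, 2] == v)
    for (e in inc) {
      u <- if (edges[e, 1] == v) edges[e, 2] else edges[e, 1]
      if (!visited[u]) {
        visited[u] <- TRUE
        parent[u] <- v
        in_edge[u] <- e
        queue <- c(queue, u)
      }
    }
  }
  for (v in order_out) {
    if (!is.na(parent[v])) {
      B[v, ] <- B[parent[v], ]
      B[v, in_edge[v]] <- 1
    }
  }
  pairs <- utils::combn(taxa, 2L)
  abs(B[pairs[1, ], , drop = FALSE] - B[pairs[2, ], , drop = FALSE])
}

subdivide <- function(edges, e, new_leaf, new_internal) {
  a <- edges[e, 1]; b <- edges[e, 2]
  rbind(edges[-e, , drop = FALSE],
        c(a, new_internal), c(new_internal, b),
        c(as.integer(new_leaf), new_internal))
}

# the two alternative subtree arrangements around an internal edge
nni_alternatives <- function(edges, e) {
  u <- edges[e, 1]; v <- edges[e, 2]
  u_nb <- setdiff(which(edges[, 1] == u | edges[, 2] == u), e)
  v_nb <- setdiff(which(edges[, 1] == v | edges[, 2] == v), e)
  if (length(u_nb) != 2 || length(v_nb) != 2) return(list())
  swap <- function(eu, ev) {
    out <- edges
    fu <- if (out[eu, 1] == u) 2L else 1L
    fv <- if (out[ev, 1] == v) 2L else 1L
    other_u <- out[eu, fu]
    other_v <- out[ev, fv]
    out[eu, ] <- c(v, other_u)
    out[ev, ] <- c(u, other_v)
    out
  }
  list(swap(u_nb[2], v_nb[1]), swap(u_nb[2], v_nb[2]))
}

edges_to_phylo <- function(edges, lengths, labels) {
  n <- length(labels)
  root <- max(edges)
  adj <- vector("list", root)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, e))
    adj[[b]] <- rbind(adj[[b]], c(a, e))
  }
  build <- function(v, parent) {
    nb <- adj[[v]]
    kids <- nb[is.na(parent) | nb[, 1] != parent, , drop = FALSE]
    if (v <= n && !nrow(kids)) return(labels[v])
    parts <- vapply(seq_len(nrow(kids)), function(r) {
      paste0(build(kids[r, 1], v), ":",
             format(lengths[kids[r, 2]], digits = 10))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  ape::read.tree(text = paste0(build(root, NA_integer_), ";"))
}

fitted_path_matrix <- function(edges, lengths, labels) {
  n <- length(labels)
  A <- path_incidence(edges, 1:n)
  pv <- as.vector(A %*% lengths)
  pairs <- utils::combn(n, 2L)
  out <- matrix(0, n, n, dimnames = list(labels, labels))
  out[cbind(pairs[1, ], pairs[2, ])] <- pv
  out[cbind(pairs[2, ], pairs[1, ])] <- pv
  out
}
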