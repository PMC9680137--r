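#' Directed acyclic graphs over named nodes
#'
#' `dag()` builds a directed acyclic graph (DAG) over a set of named nodes.
#' Nodes are identified by strings; the declaration order of `nodes` is the
#' stable ordering used for all deterministic iteration (matrix coordinates,
#' topological tie-breaks, serialisation).
#'
#' Internally the graph is an adjacency matrix `amat` with `amat[i, j] = TRUE`
#' meaning an edge `i -> j` (row = parent, column = child).
#'
#' @param nodes character vector of unique node identifiers.
#' @param edges edges as a two-column matrix or data frame
#'   (first column parent, second column child), or `NULL` for an empty graph.
#' @return an object of class `"dag"` with elements `nodes` and `amat`.
#' @examples
#' g <- dag(c("C", "E", "O"), rbind(c("E", "C"), c("E", "O"), c("C", "O")))
#' dag_parents(g, "O")
#' @export
dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node identifiers")
  if (length(nodes) == 0L) stop("a DAG needs at least one node")
  p <- length(nodes)
  amat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns (parent, child)")
    from <- match(edges[, 1L], nodes)
    to <- match(edges[, 2L], nodes)
    if (anyNA(from) || anyNA(to)) {
      bad <- unique(c(edges[, 1L][is.na(from)], edges[, 2L][is.na(to)]))
      stop("unknown node identifier(s): ", paste(bad, collapse = ", "))
    }
    if (any(from == to)) stop("self-loops are not allowed")
    amat[cbind(from, to)] <- TRUE
  }
  g <- new_dag(nodes, amat)
  if (is.null(topological_order(g))) stop("edges contain a directed cycle")
  g
}

# fast internal constructor; skips validation
new_dag <- function(nodes, amat) {
  structure(list(nodes = nodes, amat = amat), class = "dag")
}

#' @export
print.dag <- function(x, ...) {
  cat(sprintf("dag: %d nodes, %d edges\n", length(x$nodes), sum(x$amat)))
  invisible(x)
}

#' Edge list of a DAG
#' @param g a `dag`.
#' @return two-column character matrix (parent, child); zero rows if no edges.
#' @export
dag_edges <- function(g) {
  idx <- which(g$amat, arr.ind = TRUE)
  cbind(parent = g$nodes[idx[, 1L]], child = g$nodes[idx[, 2L]])
}

#' @rdname dag_edges
#' @param node a node identifier.
#' @export
dag_parents <- function(g, node) g$nodes[g$amat[, node_index(g, node)]]

#' @rdname dag_edges
#' @export
dag_children <- function(g, node) g$nodes[g$amat[node_index(g, node), ]]

node_index <- function(g, node) {
  i <- match(node, g$nodes)
  if (anyNA(i)) stop("unknown node identifier(s): ",
                     paste(node[is.na(i)], collapse = ", "))
  i
}

#' Topological order of a DAG
#'
#' Kahn's algorithm with the declaration order as tie-break.
#'
#' @param g a `dag`.
#' @return integer vector of node indices in topological order, or `NULL`
#'   if the adjacency matrix contains a directed cycle.
#' @export
topological_order <- function(g) {
  amat <- g$amat
  p <- ncol(amat)
  indeg <- colSums(amat)
  order <- integer(p)
  placed <- rep(FALSE, p)
  for (k in seq_len(p)) {
    i <- which(!placed & indeg == 0L)[1L]
    if (is.na(i)) return(NULL)
    order[k] <- i
    placed[i] <- TRUE
    indeg <- indeg - amat[i, ]
  }
  order
}

# Reachability through directed edges; returns logical vector over nodes,
# TRUE for every node reachable from `start` (indices), excluding start
# unless reachable via a cycle-free path back (cannot happen in a DAG).
reach_directed <- function(amat, start) {
  p <- ncol(amat)
  seen <- rep(FALSE, p)
  frontier <- start
  while (length(frontier)) {
    nxt <- which(colSums(amat[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

#' Ancestors and descendants
#'
#' Proper ancestors/descendants of a set of nodes (the nodes themselves are
#' not included unless reachable through another member of the set).
#'
#' @param g a `dag`.
#' @param nodes node identifiers.
#' @return character vector of node names.
#' @export
dag_descendants <- function(g, nodes) {
  g$nodes[reach_directed(g$amat, node_index(g, nodes))]
}

#' @rdname dag_descendants
#' @export
dag_ancestors <- function(g, nodes) {
  g$nodes[reach_directed(t(g$amat), node_index(g, nodes))]
}

#' Completed partially directed acyclic graphs
#'
#' A `cpdag` represents a Markov equivalence class of DAGs: a partially
#' directed graph with the class's skeleton, in which compelled edges (those
#' oriented identically in every member) are directed and the rest are
#' undirected.
#'
#' @param nodes character vector of node identifiers.
#' @param directed two-column matrix of directed edges (parent, child), or NULL.
#' @param undirected two-column matrix of undirected edges (unordered), or NULL.
#' @return an object of class `"cpdag"` with elements `nodes`, `dmat`
#'   (directed adjacency, row = parent) and `umat` (symmetric undirected
#'   adjacency).
#' @export
cpdag <- function(nodes, directed = NULL, undirected = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node identifiers")
  p <- length(nodes)
  dmat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  umat <- dmat
  fill <- function(m, e, sym) {
    if (!is.null(e) && NROW(e) > 0L) {
      e <- as.matrix(e)
      i <- match(e[, 1L], nodes); j <- match(e[, 2L], nodes)
      if (anyNA(i) || anyNA(j)) stop("unknown node in edge list")
      if (any(i == j)) stop("self-loops are not allowed")
      m[cbind(i, j)] <- TRUE
      if (sym) m[cbind(j, i)] <- TRUE
    }
    m
  }
  dmat <- fill(dmat, directed, sym = FALSE)
  umat <- fill(umat, undirected, sym = TRUE)
  if (any(dmat & t(dmat))) stop("two-cycle in directed edges")
  if (any((dmat | t(dmat)) & umat))
    stop("an adjacency cannot be both directed and undirected")
  new_cpdag(nodes, dmat, umat)
}

new_cpdag <- function(nodes, dmat, umat) {
  dimnames(dmat) <- dimnames(umat) <- list(nodes, nodes)
  structure(list(nodes = nodes, dmat = dmat, umat = umat), class = "cpdag")
}

#' @export
print.cpdag <- function(x, ...) {
  cat(sprintf("cpdag: %d nodes, %d directed + %d undirected edges\n",
              length(x$nodes), sum(x$dmat), sum(x$umat) / 2L))
  invisible(x)
}

#' Edge lists of a CPDAG
#' @param g a `cpdag`.
#' @return `cpdag_directed_edges`: two-column matrix (parent, child).
#'   `cpdag_undirected_edges`: two-column matrix, one row per unordered pair
#'   with the lower declaration index first.
#' @export
cpdag_directed_edges <- function(g) {
  idx <- which(g$dmat, arr.ind = TRUE)
  cbind(parent = g$nodes[idx[, 1L]], child = g$nodes[idx[, 2L]])
}

#' @rdname cpdag_directed_edges
#' @export
cpdag_undirected_edges <- function(g) {
  idx <- which(g$umat & upper.tri(g$umat), arr.ind = TRUE)
  cbind(a = g$nodes[idx[, 1L]], b = g$nodes[idx[, 2L]])
}

#' Graph serialisation as JSON edge lists
#'
#' Graphs are stored as `{"nodes": [...], "directed": [[a,b], ...],
#' "undirected": [[a,b], ...]}`. A `dag` round-trips with an empty
#' `undirected` array.
#'
#' @param g a `dag` or `cpdag`.
#' @param path file path.
#' @export
write_graph_json <- function(g, path) {
  if (inherits(g, "dag")) {
    d <- dag_edges(g); u <- matrix(character(), 0L, 2L)
  } else if (inherits(g, "cpdag")) {
    d <- cpdag_directed_edges(g); u <- cpdag_undirected_edges(g)
  } else stop("g must be a dag or cpdag")
  as_pairs <- function(m) unname(apply(m, 1L, function(r) as.list(unname(r)),
                                       simplify = FALSE))
  obj <- list(nodes = g$nodes, directed = as_pairs(d), undirected = as_pairs(u))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_graph_json
#' @return `read_graph_json` returns a `dag` when the file has no undirected
#'   edges, otherwise a `cpdag`.
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_mat <- function(x) {
    if (is.null(x) || length(x) == 0L) return(matrix(character(), 0L, 2L))
    if (is.list(x)) x <- do.call(rbind, lapply(x, unlist))
    matrix(as.character(x), ncol = 2L)
  }
  d <- to_mat(obj$directed); u <- to_mat(obj$undirected)
  if (nrow(u) == 0L) dag(obj$nodes, d) else cpdag(obj$nodes, d, u)
}
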