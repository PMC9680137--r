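#' CPDAG of a DAG
#'
#' Computes the completed partially directed acyclic graph representing the
#' Markov equivalence class of `g`: the skeleton of `g` with its v-structures
#' oriented and all further compelled orientations added by Meek-rule closure;
#' every remaining edge is undirected (reversible).
#'
#' @param g a `dag`.
#' @return a `cpdag`.
#' @examples
#' # a single edge carries no orientation information
#' cpdag_of(dag(c("Cstar", "O"), rbind(c("Cstar", "O"))))
#' # a v-structure is fully compelled
#' cpdag_of(dag(c("Cstar", "O", "C"), rbind(c("Cstar", "O"), c("C", "O"))))
#' @export
cpdag_of <- function(g) {
  stopifnot(inherits(g, "dag"))
  skel <- g$amat | t(g$amat)
  dmat <- vstructure_arrows(g$amat, skel)
  umat <- skel & !(dmat | t(dmat))
  closed <- meek_closure(dmat, umat)
  new_cpdag(g$nodes, closed$dmat, closed$umat)
}

# arrows participating in at least one v-structure of a DAG:
# i -> j <- k with i, k non-adjacent
vstructure_arrows <- function(amat, skel) {
  out <- amat & FALSE
  for (j in which(colSums(amat) > 1L)) {
    pa <- which(amat[, j])
    for (a in seq_len(length(pa) - 1L)) for (b in seq.int(a + 1L, length(pa))) {
      if (!skel[pa[a], pa[b]]) out[c(pa[a], pa[b]), j] <- TRUE
    }
  }
  out
}

# canonical string keys "i|k>j" (i < k) for the v-structures of a partially
# directed graph given its directed part and full adjacency
vstructure_keys <- function(dmat, adj) {
  keys <- character()
  for (j in which(colSums(dmat) > 1L)) {
    pa <- which(dmat[, j])
    for (a in seq_len(length(pa) - 1L)) for (b in seq.int(a + 1L, length(pa))) {
      if (!adj[pa[a], pa[b]])
        keys <- c(keys, paste0(pa[a], "|", pa[b], ">", j))
    }
  }
  keys
}

# Meek orientation closure over a pattern (dmat directed, umat undirected).
# Rules 1-3 are applied to a fixpoint; orientations proposed in both
# directions within one pass cancel and the edge stays undirected (this can
# only arise for inconsistent sample patterns, never for a DAG's pattern).
# Rule 4 requires an orientation that did not originate in a v-structure and
# can therefore never fire here.
meek_closure <- function(dmat, umat) {
  p <- ncol(dmat)
  repeat {
    adj <- dmat | t(dmat) | umat
    diag(adj) <- TRUE
    want <- matrix(FALSE, p, p)
    # R1: a -> b - c, a and c non-adjacent  =>  b -> c
    want <- want | (crossprod(dmat, !adj) > 0)
    # R2: a -> b -> c with a - c  =>  a -> c
    want <- want | ((dmat %*% dmat) > 0)
    # R3: a - b with two non-adjacent c, d, both a - c, a - d, c -> b, d -> b
    ue <- which(umat, arr.ind = TRUE)
    for (r in seq_len(nrow(ue))) {
      a <- ue[r, 1L]; b <- ue[r, 2L]
      s <- which(umat[a, ] & dmat[, b])
      if (length(s) > 1L && any(!adj[s, s][upper.tri(diag(length(s)))]))
        want[a, b] <- TRUE
    }
    want <- want & umat
    conflict <- want & t(want)
    orient <- want & !conflict
    if (!any(orient)) break
    dmat <- dmat | orient
    umat <- umat & !(orient | t(orient))
  }
  list(dmat = dmat, umat = umat)
}

#' Enumerate a Markov equivalence class
#'
#' Lists every DAG in the class represented by a `cpdag`: each consistent
#' extension keeps all directed edges, orients every undirected edge, is
#' acyclic, and has exactly the v-structures of the `cpdag`. Exhaustive over
#' the `2^k` orientations of the `k` undirected edges, so `k` is capped.
#'
#' @param g a `cpdag`.
#' @param max_undirected capacity guard on the number of undirected edges.
#' @return list of `dag` objects (possibly empty if `g` admits no consistent
#'   extension).
#' @export
enumerate_class <- function(g, max_undirected = 15L) {
  stopifnot(inherits(g, "cpdag"))
  und <- which(g$umat & upper.tri(g$umat), arr.ind = TRUE)
  k <- nrow(und)
  if (k > max_undirected)
    stop(sprintf("class enumeration capped at %d undirected edges (got %d)",
                 max_undirected, k))
  adj <- g$dmat | t(g$dmat) | g$umat
  target <- sort(vstructure_keys(g$dmat, adj))
  out <- list()
  for (mask in seq_len(2L^k) - 1L) {
    amat <- g$dmat
    if (k > 0L) {
      bits <- bitwAnd(bitwShiftR(mask, seq_len(k) - 1L), 1L) == 1L
      amat[und[!bits, , drop = FALSE]] <- TRUE
      amat[und[bits, c(2L, 1L), drop = FALSE]] <- TRUE
    }
    cand <- new_dag(g$nodes, amat)
    if (is.null(topological_order(cand))) next
    if (!identical(sort(vstructure_keys(amat, adj)), target)) next
    out[[length(out) + 1L]] <- cand
  }
  out
}
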