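# Independent test oracles: everything here is deliberately brute force and
# shares no code path with the implementation it checks.

# random DAG fixture: ER adjacency, random topological order
random_dag_fixture <- function(n, p_edge = 0.4) {
  adj <- matrix(stats::runif(n * n) < p_edge, n, n)
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  adj <- adj | t(adj)
  pos <- sample.int(n)
  amat <- adj & outer(pos, pos, `<`)
  nodes <- paste0("v", seq_len(n))
  dimnames(amat) <- list(nodes, nodes)
  dag(nodes, which_edges(amat, nodes))
}

which_edges <- function(amat, nodes) {
  idx <- which(amat, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  cbind(nodes[idx[, 1L]], nodes[idx[, 2L]])
}

# all acyclic orientations of g's skeleton with the same v-structures,
# from scratch (no Meek rules); compelled edges are those oriented the same
# way in every member
brute_force_cpdag <- function(g) {
  amat <- g$amat
  skel <- amat | t(amat)
  und <- which(skel & upper.tri(skel), arr.ind = TRUE)
  k <- nrow(und)
  vkey <- function(m) {
    keys <- character()
    for (j in which(colSums(m) > 1L)) {
      pa <- which(m[, j])
      for (a in seq_len(length(pa) - 1L))
        for (b in seq.int(a + 1L, length(pa)))
          if (!skel[pa[a], pa[b]])
            keys <- c(keys, paste(pa[a], pa[b], j))
    }
    sort(keys)
  }
  acyclic <- function(m) {
    indeg <- colSums(m)
    left <- rep(TRUE, ncol(m))
    repeat {
      i <- which(left & indeg == 0L)
      if (!length(i)) break
      left[i] <- FALSE
      indeg <- indeg - colSums(m[i, , drop = FALSE])
    }
    !any(left)
  }
  target <- vkey(amat)
  members <- list()
  for (mask in seq_len(2L^k) - 1L) {
    m <- amat & FALSE
    if (k > 0L) {
      bits <- bitwAnd(bitwShiftR(mask, seq_len(k) - 1L), 1L) == 1L
      m[und[!bits, , drop = FALSE]] <- TRUE
      m[und[bits, c(2L, 1L), drop = FALSE]] <- TRUE
    }
    if (!acyclic(m)) next
    if (!identical(vkey(m), target)) next
    members[[length(members) + 1L]] <- m
  }
  dmat <- Reduce(`&`, members)
  list(dmat = dmat, umat = skel & !(dmat | t(dmat)), members = members)
}

# random linear-Gaussian SCM on a dag (independent of make_scm): weights may
# be signed, noise variances heterogeneous
random_scm_fixture <- function(g, w_range = c(0.3, 1), signed = FALSE) {
  idx <- which(g$amat, arr.ind = TRUE)
  W <- matrix(0, ncol(g$amat), ncol(g$amat), dimnames = dimnames(g$amat))
  if (nrow(idx)) {
    w <- stats::runif(nrow(idx), w_range[1], w_range[2])
    if (signed) w <- w * sample(c(-1, 1), nrow(idx), replace = TRUE)
    W[idx] <- w
  }
  structure(list(dag = g, W = W,
                 noise = stats::setNames(stats::runif(length(g$nodes),
                                                      0.5, 1.5), g$nodes)),
            class = "lg_scm")
}

# partial correlation computed directly from a covariance matrix by the
# regression residual definition (not matrix-inverse shortcut)
pcor_oracle <- function(S, i, j, cond) {
  if (!length(cond)) return(S[i, j] / sqrt(S[i, i] * S[j, j]))
  Szz <- S[cond, cond, drop = FALSE]
  bi <- solve(Szz, S[cond, i])
  bj <- solve(Szz, S[cond, j])
  vi <- S[i, i] - crossprod(S[cond, i], bi)
  vj <- S[j, j] - crossprod(S[cond, j], bj)
  cij <- S[i, j] - crossprod(S[cond, i], bj)
  as.numeric(cij / sqrt(vi * vj))
}

# global IDA oracle: enumerate the whole equivalence class and, for every
# member DAG, regress the outcome on the exposure plus that member's parents
# of the exposure (0 when the outcome itself is a parent)
global_ida_effects <- function(cp, S, exposure, outcome) {
  members <- enumerate_class(cp)
  vapply(members, function(d) {
    pa <- dag_parents(d, exposure)
    if (outcome %in% pa) return(0)
    v <- c(exposure, pa)
    b <- solve(S[v, v, drop = FALSE], S[v, outcome])
    b[[1L]]
  }, numeric(1))
}

# random discrete Bayesian network with strictly positive random CPTs
random_bn_fixture <- function(n_nodes, card_max = 3L, p_edge = 0.5) {
  g <- random_dag_fixture(n_nodes, p_edge)
  card <- stats::setNames(sample(2:card_max, n_nodes, replace = TRUE),
                          g$nodes)
  cpts <- lapply(g$nodes, function(v) {
    q <- prod(card[dag_parents(g, v)])
    m <- matrix(stats::rgamma(q * card[[v]], shape = 1) + 0.05,
                nrow = q, ncol = card[[v]])
    m / rowSums(m)
  })
  names(cpts) <- g$nodes
  ldag(g, card, cpts = cpts)
}

# enumerate every separation query (x, y | z) over a small graph
all_queries <- function(nodes) {
  out <- list()
  for (i in seq_len(length(nodes) - 1L)) for (j in seq.int(i + 1L,
                                                           length(nodes))) {
    rest <- setdiff(nodes, nodes[c(i, j)])
    for (k in 0:length(rest)) {
      zsets <- if (k == 0L) list(character()) else
        utils::combn(rest, k, simplify = FALSE)
      for (z in zsets)
        out[[length(out) + 1L]] <- separation_query(nodes[i], nodes[j], z)
    }
  }
  out
}
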