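# partial correlation of variables i, j given set S from a covariance or
# correlation matrix; inversion of the (|S|+2)-dimensional submatrix
pcor_from_cov <- function(C, i, j, S = integer()) {
  if (length(S) == 0L) {
    r <- C[i, j] / sqrt(C[i, i] * C[j, j])
  } else if (length(S) == 1L) {
    k <- S
    rij <- C[i, j] / sqrt(C[i, i] * C[j, j])
    rik <- C[i, k] / sqrt(C[i, i] * C[k, k])
    rjk <- C[j, k] / sqrt(C[j, j] * C[k, k])
    den <- (1 - rik^2) * (1 - rjk^2)
    if (den <= .Machine$double.eps)
      stop("singular conditioning set in partial correlation")
    r <- (rij - rik * rjk) / sqrt(den)
  } else {
    idx <- c(i, j, S)
    P <- tryCatch(solve(C[idx, idx]), error = function(e)
      stop(sprintf("singular conditioning set {%s} for pair (%d, %d)",
                   paste(S, collapse = ","), i, j)))
    r <- -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
  }
  max(-1, min(1, r))
}

#' Fisher-z test of conditional independence
#'
#' Gaussian conditional-independence test: the sample partial correlation
#' `r` of x and y given z is mapped to the statistic
#' `sqrt(n - |z| - 3) * atanh(r)`, which is approximately standard normal
#' under independence; the p-value is two-sided.
#'
#' @param x a data matrix (rows = observations) or a covariance/correlation
#'   matrix. A covariance matrix requires `n`.
#' @param q a [separation_query()] with node names matching `colnames(x)`.
#' @param n sample size; taken from `nrow(x)` when `x` is data.
#' @param alpha significance level used for the `independent` verdict.
#' @return an object of class `"ci_test_result"`: `query`, `estimate`
#'   (partial correlation), `statistic`, `p_value`, `independent`.
#' @export
fisher_z_test <- function(x, q, n = NULL, alpha = 0.01) {
  if (!inherits(q, "separation_query")) q <- separation_query(q$x, q$y, q$z)
  is_cov <- is.matrix(x) && nrow(x) == ncol(x) &&
    isTRUE(all.equal(unname(x), unname(t(x)), tolerance = 1e-8))
  if (is_cov) {
    if (is.null(n)) stop("n is required when x is a covariance matrix")
    C <- x
  } else {
    x <- as.matrix(x)
    if (is.null(n)) n <- nrow(x)
    C <- stats::cov(x)
  }
  vars <- colnames(C)
  ii <- match(c(q$x, q$y, q$z), vars)
  if (anyNA(ii)) stop("query names not found among variables")
  if (length(q$z) > n - 4L) stop("conditioning set too large for sample size")
  r <- pcor_from_cov(C, ii[1L], ii[2L], ii[-(1:2)])
  df <- n - length(q$z) - 3
  stat <- sqrt(df) * atanh(max(-1 + 1e-15, min(1 - 1e-15, r)))
  p <- 2 * stats::pnorm(-abs(stat))
  structure(list(query = q, estimate = r, statistic = stat, p_value = p,
                 independent = p > alpha, alpha = alpha),
            class = "ci_test_result")
}

#' @export
print.ci_test_result <- function(x, ...) {
  cat(sprintf("CI test %s _||_ %s | {%s}: r = %.4f, z = %.3f, p = %.3g (%s)\n",
              x$query$x, x$query$y, paste(x$query$z, collapse = ", "),
              x$estimate, x$statistic, x$p_value,
              if (x$independent) "independent" else "dependent"))
  invisible(x)
}

# Generic stable-PC engine. indep(i, j, S) must return TRUE iff x_i and x_j
# are judged independent given the index set S. level-0 decisions may be
# supplied precomputed via `indep0` (a logical matrix) to allow vectorised
# marginal screening. v_structure chooses the collider decision rule:
# "sepset" orients i -> k <- j when k is missing from the recorded
# separating set; "majority" re-examines all separating subsets of the
# endpoints' adjacency sets (up to max_subset per side) and orients only
# when k appears in fewer than half of them, leaving ambiguous triples
# undirected.
pc_engine <- function(nodes, indep, indep0 = NULL, max_cond = Inf,
                      v_structure = c("majority", "sepset"),
                      max_subset = 5L) {
  v_structure <- match.arg(v_structure)
  p <- length(nodes)
  adj <- matrix(TRUE, p, p); diag(adj) <- FALSE
  sepset <- vector("list", p * p)
  sep_at <- function(i, j) (i - 1L) * p + j
  # level 0
  for (i in seq_len(p - 1L)) for (j in seq.int(i + 1L, p)) {
    drop <- if (!is.null(indep0)) indep0[i, j] else indep(i, j, integer())
    if (drop) {
      adj[i, j] <- adj[j, i] <- FALSE
      sepset[[sep_at(i, j)]] <- integer()
    }
  }
  l <- 1L
  while (l <= max_cond) {
    snapshot <- adj                     # stable variant: fixed per level
    nbr_count <- rowSums(snapshot)
    if (!any(nbr_count >= l + 1L)) break
    pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      if (!adj[i, j]) next
      for (side in 1:2) {
        a <- if (side == 1L) i else j
        b <- if (side == 1L) j else i
        nbrs <- which(snapshot[a, ]); nbrs <- nbrs[nbrs != b]
        if (length(nbrs) < l) next
        combs <- utils::combn(length(nbrs), l)
        removed <- FALSE
        for (cc in seq_len(ncol(combs))) {
          S <- nbrs[combs[, cc]]
          if (indep(i, j, S)) {
            adj[i, j] <- adj[j, i] <- FALSE
            sepset[[sep_at(i, j)]] <- S
            removed <- TRUE
            break
          }
        }
        if (removed) break
      }
    }
    l <- l + 1L
  }
  # v-structures from separating sets; conflicting arrowheads cancel
  arrows <- matrix(FALSE, p, p)
  for (k in seq_len(p)) {
    nb <- which(adj[k, ])
    if (length(nb) < 2L) next
    for (u in seq_len(length(nb) - 1L)) for (v in seq.int(u + 1L, length(nb))) {
      i <- nb[u]; j <- nb[v]
      if (adj[i, j]) next
      S <- sepset[[sep_at(min(i, j), max(i, j))]]
      if (is.null(S)) next                       # never separated: no triple
      orient <- if (v_structure == "sepset") {
        !(k %in% S)
      } else {
        frac <- sepset_majority(i, j, k, adj, indep, max_subset)
        !is.na(frac) && frac < 0.5
      }
      if (orient) arrows[i, k] <- arrows[j, k] <- TRUE
    }
  }
  conflict <- arrows & t(arrows)
  dmat <- arrows & !conflict
  umat <- adj & !(dmat | t(dmat))
  closed <- meek_closure(dmat, umat)
  new_cpdag(nodes, closed$dmat, closed$umat)
}

# fraction of separating subsets (over both endpoints' adjacency sets, up
# to size max_subset) that contain k; NA when no separating subset exists
sepset_majority <- function(i, j, k, adj, indep, max_subset) {
  cand <- unique(c(which(adj[i, ]), which(adj[j, ])))
  cand <- cand[!cand %in% c(i, j)]
  n_sep <- 0L
  n_with_k <- 0L
  for (l in 0:min(length(cand), max_subset)) {
    combs <- if (l == 0L) list(integer()) else
      utils::combn(cand, l, simplify = FALSE)
    for (S in combs) {
      if (indep(i, j, S)) {
        n_sep <- n_sep + 1L
        if (k %in% S) n_with_k <- n_with_k + 1L
      }
    }
  }
  if (n_sep == 0L) return(NA_real_)
  n_with_k / n_sep
}

#' The PC algorithm (stable variant)
#'
#' Constraint-based structure learning with the Fisher-z partial-correlation
#' test: the order-independent ("stable") skeleton phase with conditioning
#' sets drawn from adjacency sets frozen at the start of each level,
#' v-structure orientation from separating sets (conflicting arrowheads are
#' logged by cancellation and left undirected), and Meek-rule closure.
#'
#' @param x data matrix (rows = observations, named columns), or a
#'   covariance matrix together with `n`.
#' @param alpha significance level of the individual CI tests.
#' @param n sample size when `x` is a covariance matrix.
#' @param max_cond cap on the conditioning-set size.
#' @param v_structure collider decision rule: `"majority"` (the default:
#'   re-examine all separating subsets of the endpoints' adjacency sets and
#'   orient an unshielded triple into a collider only when the middle node
#'   appears in fewer than half of them, leaving ambiguous triples
#'   undirected — markedly more robust to spurious separating sets) or
#'   `"sepset"` (orient when the middle node is missing from the single
#'   recorded separating set — faster, classic, more error-prone).
#' @param max_subset subset-size cap of the majority re-examination.
#' @return a `cpdag` over the column names of `x`.
#' @export
pc <- function(x, alpha = 0.01, n = NULL, max_cond = Inf,
               v_structure = c("majority", "sepset"), max_subset = 5L) {
  is_cov <- is.matrix(x) && nrow(x) == ncol(x) && !is.null(n) &&
    isTRUE(all.equal(unname(x), unname(t(x)), tolerance = 1e-8))
  if (is_cov) {
    C <- x
  } else {
    x <- as.matrix(x)
    if (!is.numeric(x)) stop("data must be numeric")
    if (is.null(n)) n <- nrow(x)
    if (n < 10L) stop("refusing to run PC on fewer than 10 observations")
    C <- stats::cov(x)
  }
  nodes <- colnames(C)
  if (is.null(nodes)) stop("variables must be named")
  R <- stats::cov2cor(C)
  p <- ncol(R)
  # vectorised marginal screening (level 0)
  z0 <- sqrt(n - 3) * atanh(pmin(pmax(R, -1 + 1e-15), 1 - 1e-15))
  indep0 <- 2 * stats::pnorm(-abs(z0)) > alpha
  indep <- function(i, j, S) {
    # a numerically singular conditioning set cannot certify independence
    r <- tryCatch(pcor_from_cov(R, i, j, S), error = function(e) NA_real_)
    if (is.na(r)) return(FALSE)
    stat <- sqrt(n - length(S) - 3) * atanh(max(-1 + 1e-15,
                                                min(1 - 1e-15, r)))
    2 * stats::pnorm(-abs(stat)) > alpha
  }
  pc_engine(nodes, indep, indep0 = indep0, max_cond = max_cond,
            v_structure = v_structure, max_subset = max_subset)
}

#' Oracle PC with a d-separation test
#'
#' Runs the identical PC machinery but answers every conditional-independence
#' query exactly by d-separation in a known DAG — the infinite-sample limit.
#' Sound and complete, so the output equals [cpdag_of()] of the DAG.
#'
#' @param g a `dag`.
#' @param max_cond cap on the conditioning-set size.
#' @return a `cpdag`.
#' @export
pc_oracle <- function(g, max_cond = Inf) {
  stopifnot(inherits(g, "dag"))
  amat <- g$amat
  indep <- function(i, j, S) !moral_connected(amat, i, j, S)
  # with an exact CI oracle the sepset and majority rules coincide; use the
  # cheap one
  pc_engine(g$nodes, indep, max_cond = max_cond, v_structure = "sepset")
}
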