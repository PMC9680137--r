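#' IDA: possible causal effects from a CPDAG
#'
#' The local IDA estimator. For each subset `S` of the exposure's undirected
#' neighbours in the CPDAG such that orienting `S -> exposure` creates no new
#' v-structure at the exposure (the members of `S` must be pairwise adjacent,
#' and adjacent to every directed parent of the exposure), the effect is the
#' regression coefficient of the exposure in the regression of the outcome
#' on the exposure, its directed parents, and `S`. When the outcome itself
#' enters the parent configuration, the effect for that configuration is 0
#' by the structural convention (an effect on one's own cause is zero);
#' exact zeros arise only this way, never by rounding.
#'
#' The multiset of effects over all locally valid `S` is summarised by its
#' minimum absolute value, a lower bound on the magnitude of the true causal
#' effect when the CPDAG is correct.
#'
#' @param g a `cpdag`.
#' @param x data matrix (used for its covariance), or `NULL` if `cov` given.
#' @param cov covariance matrix (e.g. [exact_covariance()] for oracle runs).
#' @param exposure,outcome node names present in `g`.
#' @return an object of class `"ida_result"`: `exposure`, `outcome`,
#'   `effects` (numeric multiset, one entry per valid parent configuration),
#'   `min_abs`, `nonzero`.
#' @export
ida_local <- function(g, x = NULL, cov = NULL, exposure, outcome) {
  stopifnot(inherits(g, "cpdag"))
  if (is.null(cov)) {
    if (is.null(x)) stop("provide data x or a covariance matrix")
    cov <- stats::cov(as.matrix(x))
  }
  if (is.null(colnames(cov))) stop("covariance must carry variable names")
  ie <- match(exposure, g$nodes); io <- match(outcome, g$nodes)
  if (is.na(ie) || is.na(io)) stop("exposure and outcome must be graph nodes")
  if (ie == io) stop("exposure and outcome must be distinct")
  ci <- match(g$nodes, colnames(cov))
  if (anyNA(ci)) stop("covariance is missing graph variables")
  adj <- g$dmat | t(g$dmat) | g$umat
  pa <- which(g$dmat[, ie])
  sib <- which(g$umat[ie, ])
  # a sibling non-adjacent to some directed parent can never be oriented
  # into the exposure without creating a new collider
  sib <- sib[vapply(sib, function(s) all(adj[s, pa]), TRUE)]
  subsets <- clique_subsets(sib, adj)
  effects <- vapply(subsets, function(S) {
    V <- c(pa, S)
    if (io %in% V) return(0)
    vars <- ci[c(ie, V)]
    b <- tryCatch(solve(cov[vars, vars, drop = FALSE], cov[vars, ci[io]]),
                  error = function(e)
                    stop(sprintf(
                      "singular regression for exposure %s with parent set {%s}",
                      exposure, paste(g$nodes[V], collapse = ", "))))
    b[[1L]]
  }, numeric(1))
  new_ida_result(exposure, outcome, effects)
}

# all subsets of `cand` (node indices) that are cliques under `adj`,
# including the empty set; enumerated without touching non-clique branches
clique_subsets <- function(cand, adj) {
  out <- list(integer())
  grow <- function(S, rest) {
    for (k in seq_along(rest)) {
      v <- rest[k]
      if (all(adj[v, S])) {
        S2 <- c(S, v)
        out[[length(out) + 1L]] <<- S2
        grow(S2, rest[-seq_len(k)])
      }
    }
  }
  grow(integer(), cand)
  out
}

new_ida_result <- function(exposure, outcome, effects) {
  if (!length(effects)) stop("IDA produced no effects")
  m <- min(abs(effects))
  structure(list(exposure = exposure, outcome = outcome, effects = effects,
                 min_abs = m, nonzero = m > 0),
            class = "ida_result")
}

#' @export
print.ida_result <- function(x, ...) {
  cat(sprintf("ida: %s -> %s, %d candidate effect(s), min |effect| = %.4g%s\n",
              x$exposure, x$outcome, length(x$effects), x$min_abs,
              if (x$nonzero) "" else " (zero: reverse orientation possible)"))
  invisible(x)
}

#' Oracle IDA: the infinite-sample limit
#'
#' Evaluates local IDA on the true CPDAG ([cpdag_of()] of the SCM's DAG)
#' with the exact model covariance. This is what IDA would return given
#' unlimited data, and averaging its discovery indicator over random systems
#' yields the theoretical upper limit on the discovery rate.
#'
#' @param scm an `lg_scm`.
#' @param exposure,outcome node names.
#' @return an `"ida_result"`.
#' @export
oracle_ida <- function(scm, exposure, outcome) {
  ida_local(cpdag_of(scm$dag), cov = exact_covariance(scm),
            exposure = exposure, outcome = outcome)
}

#' Discovery rates from a batch of IDA results
#'
#' A replicate counts as a discovery when its minimum-absolute-value summary
#' is non-zero. Replicates with non-zero true effect contribute to the true
#' discovery rate, replicates with zero true effect (reversed mechanisms) to
#' the false positive rate. Quartiles of the non-zero estimates are reported
#' as a distribution summary.
#'
#' @param results list of `"ida_result"` objects.
#' @param truth numeric vector of true causal effects, one per result.
#' @return list with `n_true`, `n_null`, `true_discovery_rate`,
#'   `false_positive_rate` (either is `NA` if its stratum is empty), and
#'   `nonzero_quartiles` (25/50/75% quantiles of non-zero `min_abs` among
#'   true-effect replicates).
#' @export
discovery_rates <- function(results, truth) {
  if (!length(results)) stop("empty result list")
  if (length(results) != length(truth))
    stop("results and truth must have equal length")
  nz <- vapply(results, function(r) r$nonzero, TRUE)
  est <- vapply(results, function(r) r$min_abs, numeric(1))
  fwd <- truth != 0
  tdr <- if (any(fwd)) mean(nz[fwd]) else NA_real_
  fpr <- if (any(!fwd)) mean(nz[!fwd]) else NA_real_
  q <- if (any(fwd & nz)) {
    stats::quantile(est[fwd & nz], c(0.25, 0.5, 0.75), names = FALSE)
  } else rep(NA_real_, 3L)
  list(n_true = sum(fwd), n_null = sum(!fwd),
       true_discovery_rate = tdr, false_positive_rate = fpr,
       nonzero_quartiles = stats::setNames(q, c("q25", "q50", "q75")))
}
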