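#' Scenario specification for the simulated OTU systems
#'
#' Describes one cell of the simulation study: a random sparse DAG over
#' `n_otus` continuous OTU-abundance variables (values mimic log-transformed,
#' normalised titres), an outcome variable `O` wired to the community in one
#' of three ways, and the direction of the outcome mechanism.
#'
#' * Scenario `"A"`: the outcome is linked to a single randomly chosen
#'   exposure OTU.
#' * Scenario `"B"`: two OTUs cause the outcome and are themselves directly
#'   linked, the community partner being a parent of the exposure (so an open
#'   backdoor path through the partner exists unless its edge is oriented).
#' * Scenario `"C"`: two non-adjacent OTUs cause the outcome, forming a
#'   v-structure at the outcome.
#'
#' `direction = "forward"` points the outcome edges from the microbiome into
#' `O` (true effect of the exposure on `O` equal to `effect`);
#' `direction = "reversed"` points them from `O` into the microbiome (true
#' effect exactly 0), with the same edge-weight magnitude.
#'
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param direction `"forward"` or `"reversed"`.
#' @param n_otus number of OTU variables (>= 3).
#' @param expected_neighbors number of neighbours per OTU in the random
#'   graph. Under `graph_model = "regular"` (the default) every OTU has
#'   exactly this many neighbours; under `"er"` each unordered pair is
#'   adjacent independently with probability
#'   `expected_neighbors / (n_otus - 1)`, so it is the expected degree.
#' @param effect structural coefficient on every edge incident to the
#'   outcome.
#' @param weight_range positive interval from which OTU-OTU structural
#'   coefficients are drawn uniformly (positive weights encode symbiotic,
#'   positively correlated abundances).
#' @param graph_model `"regular"` for a uniformly random simple
#'   `expected_neighbors`-regular graph, `"er"` for the Erdos-Renyi model
#'   with that expected degree.
#' @return an object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(scenario = c("A", "B", "C"),
                          direction = c("forward", "reversed"),
                          n_otus = 100L,
                          expected_neighbors = 3,
                          effect = 0.75,
                          weight_range = c(0.1, 1),
                          graph_model = c("regular", "er")) {
  scenario <- match.arg(scenario)
  direction <- match.arg(direction)
  graph_model <- match.arg(graph_model)
  n_otus <- as.integer(n_otus)
  if (n_otus < 3L) stop("n_otus must be at least 3")
  if (!is.finite(effect)) stop("effect must be finite")
  if (expected_neighbors < 0 || expected_neighbors >= n_otus)
    stop("expected_neighbors must lie in [0, n_otus)")
  if (graph_model == "regular") {
    if (expected_neighbors != round(expected_neighbors))
      stop("the regular graph model needs a whole-number degree")
    if ((n_otus * expected_neighbors) %% 2L == 1L)
      stop("a k-regular graph needs n_otus * expected_neighbors even")
  }
  if (length(weight_range) != 2L || any(weight_range <= 0) ||
      weight_range[1] > weight_range[2])
    stop("weight_range must be a positive interval")
  structure(list(scenario = scenario, direction = direction, n_otus = n_otus,
                 expected_neighbors = expected_neighbors, effect = effect,
                 weight_range = weight_range, graph_model = graph_model),
            class = "scenario_spec")
}

#' Read or write a scenario specification as YAML
#' @param spec a `scenario_spec`.
#' @param path file path.
#' @export
write_scenario_yaml <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  scenario_spec(scenario = x$scenario, direction = x$direction,
                n_otus = x$n_otus, expected_neighbors = x$expected_neighbors,
                effect = x$effect, weight_range = unlist(x$weight_range),
                graph_model = x$graph_model)
}

otu_names <- function(n) sprintf("OTU_%d", seq_len(n))

#' Random sparse DAG over the OTU variables
#'
#' Draws the undirected coexistence graph — a uniformly random simple
#' `expected_neighbors`-regular graph by default, so every OTU has exactly
#' that many neighbours, or an Erdos-Renyi graph with the same expected
#' degree under `graph_model = "er"` — and orients its edges along a
#' uniformly random topological order. Uses the current RNG state; seed
#' control belongs to the caller (see [run_effect_study()] for the
#' stream-splitting contract).
#'
#' @param spec a `scenario_spec`.
#' @return a `dag` over nodes `OTU_1 ... OTU_n` only.
#' @export
random_otu_dag <- function(spec) {
  n <- spec$n_otus
  nodes <- otu_names(n)
  if (spec$graph_model == "regular") {
    k <- as.integer(round(spec$expected_neighbors))
    if (k == 0L) {
      adj <- matrix(FALSE, n, n)
    } else {
      if ((n * k) %% 2L == 1L)
        stop("a k-regular graph needs n * k even")
      ug <- igraph::sample_k_regular(n, k)
      adj <- matrix(FALSE, n, n)
      e <- igraph::as_edgelist(ug, names = FALSE)
      adj[e] <- TRUE
      adj <- adj | t(adj)
    }
  } else {
    prob <- spec$expected_neighbors / (n - 1)
    adj <- matrix(FALSE, n, n)
    adj[upper.tri(adj)] <- stats::runif(n * (n - 1L) / 2L) < prob
    adj <- adj | t(adj)
  }
  pos <- sample.int(n)             # pos[i] = topological position of node i
  amat <- adj & (outer(pos, pos, `<`))
  dimnames(amat) <- list(nodes, nodes)
  new_dag(nodes, amat)
}

#' Wire the outcome node into an OTU DAG
#'
#' Adds the outcome node `O` and the scenario's causal mechanism to a DAG of
#' OTUs, choosing the exposure OTU (and, for scenarios B and C, its community
#' partner) at random. The returned DAG carries the choices in its
#' `$exposure` and `$partner` elements.
#'
#' Scenario B draws the community as a uniformly random directed edge of the
#' OTU DAG, so the partner is a parent of the exposure (partner ->
#' exposure), creating the open backdoor path exposure <- partner -> O.
#' Scenario C draws a uniformly random non-adjacent pair.
#'
#' @param g a `dag` over OTU nodes (>= 2 of them).
#' @param spec a `scenario_spec`.
#' @return a `dag` including node `"O"`, with elements `exposure` and
#'   `partner` (`NA` for scenario A) naming the causal OTUs.
#' @export
attach_outcome <- function(g, spec) {
  stopifnot(inherits(g, "dag"))
  n <- length(g$nodes)
  if (n < 2L) stop("need at least two OTU nodes")
  nodes <- c(g$nodes, "O")
  amat <- matrix(FALSE, n + 1L, n + 1L, dimnames = list(nodes, nodes))
  amat[seq_len(n), seq_len(n)] <- g$amat
  io <- n + 1L
  partner <- NA_character_
  if (spec$scenario == "A") {
    exp_i <- sample.int(n, 1L)
    causes <- exp_i
  } else if (spec$scenario == "B") {
    ed <- which(g$amat, arr.ind = TRUE)
    if (nrow(ed) == 0L)
      stop("scenario B needs at least one OTU-OTU edge (directly linked pair)")
    k <- if (nrow(ed) == 1L) 1L else sample.int(nrow(ed), 1L)
    par_i <- ed[k, 1L]                   # partner -> exposure
    exp_i <- ed[k, 2L]
    partner <- g$nodes[par_i]
    causes <- c(exp_i, par_i)
  } else {                               # scenario C
    skel <- g$amat | t(g$amat)
    free <- which(!skel & upper.tri(skel), arr.ind = TRUE)
    if (nrow(free) == 0L)
      stop("scenario C impossible: the OTU graph is complete")
    k <- if (nrow(free) == 1L) 1L else sample.int(nrow(free), 1L)
    pair <- c(free[k, 1L], free[k, 2L])
    if (stats::runif(1) < 0.5) pair <- rev(pair)
    # the exposure must not be an ancestor of its partner, or part of its
    # effect on O would flow through the partner (true effect must stay at
    # exactly spec$effect)
    if (reach_directed(g$amat, pair[[1L]])[pair[[2L]]]) pair <- rev(pair)
    exp_i <- pair[[1L]]
    par_i <- pair[[2L]]
    partner <- g$nodes[par_i]
    causes <- c(exp_i, par_i)
  }
  if (spec$direction == "forward") {
    amat[causes, io] <- TRUE
  } else {
    amat[io, causes] <- TRUE
  }
  out <- new_dag(nodes, amat)
  out$exposure <- g$nodes[exp_i]
  out$partner <- partner
  out
}

#' Linear-Gaussian structural causal model on a DAG
#'
#' Attaches structural coefficients and noise variances to a DAG: each
#' variable equals the weighted sum of its parents plus independent Gaussian
#' noise. OTU-OTU weights are drawn uniformly from `spec$weight_range`
#' (positive, so adjacent OTUs are positively correlated, the symbiosis
#' convention); every edge incident to the outcome carries `spec$effect`;
#' noise variances are 1.
#'
#' @param g a `dag` from [attach_outcome()].
#' @param spec a `scenario_spec`.
#' @return an object of class `"lg_scm"`: `dag`, weight matrix `W`
#'   (`W[i, j]` = coefficient of parent i in the equation of child j) and
#'   `noise` (per-node variance), plus the inherited `exposure`/`partner`.
#' @export
make_scm <- function(g, spec) {
  stopifnot(inherits(g, "dag"))
  idx <- which(g$amat, arr.ind = TRUE)
  W <- matrix(0, nrow(g$amat), ncol(g$amat), dimnames = dimnames(g$amat))
  w <- stats::runif(nrow(idx), spec$weight_range[1], spec$weight_range[2])
  io <- match("O", g$nodes)
  if (!is.na(io)) w[idx[, 1L] == io | idx[, 2L] == io] <- spec$effect
  W[idx] <- w
  structure(list(dag = g, W = W,
                 noise = stats::setNames(rep(1, length(g$nodes)), g$nodes),
                 exposure = g$exposure, partner = g$partner),
            class = "lg_scm")
}

#' @export
print.lg_scm <- function(x, ...) {
  cat(sprintf("lg_scm: %d variables, %d edges\n",
              length(x$dag$nodes), sum(x$dag$amat)))
  invisible(x)
}

#' Exact covariance of a linear-Gaussian SCM
#'
#' Closed form `t(A) D A` with `A = (I - W)^{-1}` and `D` the diagonal noise
#' variances; always well defined because `I - W` is triangular up to a
#' permutation for a DAG.
#'
#' @param scm an `lg_scm`.
#' @return symmetric positive-definite covariance matrix in declaration
#'   order.
#' @export
exact_covariance <- function(scm) {
  p <- ncol(scm$W)
  A <- solve(diag(p) - scm$W)
  S <- crossprod(A, scm$noise * A)   # t(A) %*% diag(noise) %*% A
  dimnames(S) <- dimnames(scm$W)
  (S + t(S)) / 2
}

#' Sample an abundance table from an SCM
#'
#' Ancestral sampling: independent Gaussian noise propagated through the
#' structural equations (computed jointly as `E %*% (I - W)^{-1}`).
#'
#' @param scm an `lg_scm`.
#' @param n number of subjects (rows).
#' @param seed optional integer; if given, `set.seed(seed)` is applied so the
#'   table is reproducible.
#' @return numeric matrix `n x p` with the SCM's node names as columns.
#' @export
scm_sample <- function(scm, n, seed = NULL) {
  if (n < 1L) stop("n must be positive")
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(scm$W)
  E <- matrix(stats::rnorm(n * p), n, p)
  E <- sweep(E, 2L, sqrt(scm$noise), `*`)
  X <- E %*% solve(diag(p) - scm$W)
  colnames(X) <- scm$dag$nodes
  X
}

#' Total causal effect in a linear SCM
#'
#' Sum over all directed paths from exposure to outcome of the products of
#' edge weights along the path; equals the interventional regression slope
#' `d E[outcome | do(exposure = x)] / dx`. Computed in closed form as the
#' (exposure, outcome) entry of `(I - W)^{-1}`.
#'
#' @param scm an `lg_scm`.
#' @param exposure,outcome node identifiers.
#' @return a single number; 0 when no directed path exists.
#' @export
true_effect <- function(scm, exposure, outcome) {
  i <- node_index(scm$dag, exposure); j <- node_index(scm$dag, outcome)
  if (i == j) stop("exposure and outcome must be distinct")
  p <- ncol(scm$W)
  Tm <- solve(diag(p) - scm$W)
  unname(Tm[i, j])
}

#' Abundance-table I/O
#'
#' Plain TSV with a header row of node names; values are the continuous
#' simulated abundances.
#'
#' @param x abundance matrix from [scm_sample()].
#' @param path file path.
#' @export
write_abundance_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path) {
  as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                              check.names = FALSE))
}
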