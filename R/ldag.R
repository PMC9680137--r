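#' Labelled DAGs: context-specific independence in Bayesian networks
#'
#' An LDAG is a DAG over discrete variables whose edges may carry labels: a
#' label on the edge `X -> Y` lists assignments ("contexts") of the other
#' parents of `Y` under which the dependence of `Y` on `X` vanishes. In a
#' labelled context all conditional rows that differ only in `X` are
#' constrained equal, so an LDAG is strictly more expressive than its
#' underlying DAG and can break Markov-equivalence ties that plain DAGs
#' cannot.
#'
#' @param g a `dag` over discrete nodes.
#' @param card named integer vector of cardinalities (all >= 2); states are
#'   coded `0:(card - 1)`.
#' @param labels list of label entries, each
#'   `list(edge = c(parent, child), contexts = list(...))` where every
#'   context is a named vector assigning a state to each co-parent of the
#'   edge's child. An empty list gives an ordinary Bayesian network.
#' @param cpts optional conditional probability tables: for each node a
#'   matrix with one row per parent configuration (parents in declaration
#'   order, the first varying fastest) and one column per state; rows merged
#'   by a label must be identical.
#' @return an object of class `"ldag"`.
#' @export
ldag <- function(g, card, labels = list(), cpts = NULL) {
  stopifnot(inherits(g, "dag"))
  card <- card[g$nodes]
  if (anyNA(card) || any(card < 2L))
    stop("card must give a cardinality >= 2 for every node")
  card <- stats::setNames(as.integer(card), g$nodes)
  for (lb in labels) {
    pa <- lb$edge[[1L]]; ch <- lb$edge[[2L]]
    if (!g$amat[node_index(g, pa), node_index(g, ch)])
      stop(sprintf("label on absent edge %s -> %s", pa, ch))
    co <- setdiff(dag_parents(g, ch), pa)
    if (!length(lb$contexts)) stop("label with no contexts")
    for (ctx in lb$contexts) {
      if (!setequal(names(ctx), co))
        stop(sprintf("label context on %s -> %s must assign exactly {%s}",
                     pa, ch, paste(co, collapse = ", ")))
      if (any(ctx < 0 | ctx >= card[names(ctx)]))
        stop("label context value outside the co-parent's state space")
    }
  }
  obj <- structure(list(dag = g, card = card, labels = labels, cpts = cpts),
                   class = "ldag")
  if (!is.null(cpts)) validate_cpts(obj)
  obj
}

#' @export
print.ldag <- function(x, ...) {
  cat(sprintf("ldag: %d nodes, %d edges, %d labelled edge(s)%s\n",
              length(x$dag$nodes), sum(x$dag$amat), length(x$labels),
              if (is.null(x$cpts)) "" else ", with CPTs"))
  invisible(x)
}

labels_child <- function(labels)
  vapply(labels, function(lb) lb$edge[[2L]], character(1))

# parent configuration grid of a node: rows in expand.grid order over the
# parents in declaration order (first parent varying fastest)
parent_grid <- function(model, node) {
  pa <- dag_parents(model$dag, node)
  if (!length(pa)) return(matrix(integer(), 1L, 0L))
  g <- expand.grid(lapply(model$card[pa], function(k) seq_len(k) - 1L),
                   KEEP.OUT.ATTRS = FALSE)
  names(g) <- pa
  as.matrix(g)
}

# partition of a node's parent configurations induced by the labels:
# each context of a label on X -> node merges all configurations that agree
# with the context (i.e. vary only in X). Returns one class id per row.
label_partition <- function(model, node) {
  grid <- parent_grid(model, node)
  q <- nrow(grid)
  cls <- seq_len(q)
  find <- function(i) { while (cls[i] != i) i <- cls[i] <<- cls[cls[i]]; i }
  for (lb in model$labels) {
    if (lb$edge[[2L]] != node) next
    for (ctx in lb$contexts) {
      co <- names(ctx)
      hit <- if (length(co)) {
        which(rowSums(grid[, co, drop = FALSE] !=
                        matrix(ctx, q, length(co), byrow = TRUE)) == 0L)
      } else seq_len(q)
      if (length(hit) > 1L) {
        root <- find(hit[1L])
        for (h in hit[-1L]) cls[find(h)] <- root
      }
    }
  }
  vapply(seq_len(q), find, 1L)
}

validate_cpts <- function(model) {
  for (node in model$dag$nodes) {
    pt <- model$cpts[[node]]
    grid <- parent_grid(model, node)
    if (is.null(pt) || nrow(pt) != nrow(grid) ||
        ncol(pt) != model$card[[node]])
      stop(sprintf("cpt of %s must be %d x %d", node, nrow(grid),
                   model$card[[node]]))
    if (any(pt < -1e-12) || any(abs(rowSums(pt) - 1) > 1e-9))
      stop(sprintf("cpt rows of %s must be distributions", node))
    part <- label_partition(model, node)
    for (k in unique(part)) {
      rows <- pt[part == k, , drop = FALSE]
      if (max(rows) - min(rows) > 0 &&
          max(abs(sweep(rows, 2L, rows[1L, ]))) > 1e-9)
        stop(sprintf("cpt of %s violates a label-induced equality", node))
    }
  }
  invisible(model)
}

#' Full joint of a discrete Bayesian network or LDAG
#'
#' Multiplies the conditional tables into the joint probability array.
#'
#' @param model an `ldag` with CPTs.
#' @return a `discrete_joint` over the model's nodes.
#' @export
bn_joint <- function(model) {
  stopifnot(inherits(model, "ldag"))
  if (is.null(model$cpts)) stop("model must carry conditional tables")
  nodes <- model$dag$nodes
  card <- model$card
  cfg <- as.matrix(expand.grid(lapply(card, function(k) seq_len(k) - 1L),
                               KEEP.OUT.ATTRS = FALSE))
  prob <- rep(1, nrow(cfg))
  for (node in nodes) {
    pa <- dag_parents(model$dag, node)
    row <- rep(1L, nrow(cfg))
    if (length(pa)) {
      mult <- 1L
      for (p in pa) {
        row <- row + cfg[, p] * mult
        mult <- mult * card[[p]]
      }
    }
    prob <- prob * model$cpts[[node]][cbind(row, cfg[, node] + 1L)]
  }
  arr <- array(prob, dim = unname(card),
               dimnames = lapply(card, function(k) as.character(0:(k - 1))))
  discrete_joint(arr)
}

# contingency counts over all nodes as an array in state order 0..k-1
counts_array <- function(x, nodes, card) {
  if (is.array(x) && !is.null(dimnames(x)) &&
      setequal(names(dimnames(x)), nodes)) {
    perm <- match(nodes, names(dimnames(x)))
    return(aperm(x, perm))
  }
  x <- as.data.frame(x)
  if (!all(nodes %in% names(x))) stop("data columns must match node names")
  f <- lapply(nodes, function(v) {
    vals <- x[[v]]
    if (any(!vals %in% (seq_len(card[[v]]) - 1L)))
      stop(sprintf("values of %s outside 0..%d", v, card[[v]] - 1L))
    factor(vals, levels = seq_len(card[[v]]) - 1L)
  })
  unname_table <- table(f)
  names(dimnames(unname_table)) <- nodes
  unname_table
}

#' Dirichlet-multinomial marginal likelihood of an LDAG
#'
#' The Bayesian structure score: a product over nodes of
#' Dirichlet-multinomial marginal likelihoods in which the counts of parent
#' configurations merged by a label are pooled into a single parameter row.
#' Hyperparameters follow the BDeu convention, `ess / (q * r)` per cell of
#' the *unmerged* table (`q` parent configurations, `r` states), so a merged
#' row inherits the sum of the hyperparameters it absorbs; with no labels
#' this is exactly the standard BDeu score of the plain DAG.
#'
#' @param x data (rows = observations, columns named after the nodes, states
#'   coded from 0) or a contingency array with named dimnames.
#' @param model an `ldag` (CPTs not required).
#' @param ess equivalent sample size (> 0) of the Dirichlet prior.
#' @return the log marginal likelihood.
#' @export
ldag_marginal_likelihood <- function(x, model, ess = 1) {
  stopifnot(inherits(model, "ldag"))
  if (ess <= 0) stop("ess must be positive")
  nodes <- model$dag$nodes
  cnt <- counts_array(x, nodes, model$card)
  score <- 0
  for (node in nodes) {
    pa <- dag_parents(model$dag, node)
    r <- model$card[[node]]
    ipa <- match(pa, nodes); ino <- match(node, nodes)
    fam <- apply(cnt, c(ipa, ino), sum)
    q <- as.integer(prod(model$card[pa]))
    N <- matrix(as.numeric(fam), nrow = q, ncol = r)
    part <- label_partition(model, node)
    Np <- rowsum(N, part)
    m <- as.numeric(rowsum(rep(1, q), part))
    a_cell <- ess / (q * r)
    A <- matrix(m * a_cell, nrow(Np), r)
    score <- score +
      sum(lgamma(rowSums(A)) - lgamma(rowSums(A) + rowSums(Np))) +
      sum(lgamma(A + Np) - lgamma(A))
  }
  score
}

#' Posterior-mean conditional tables under an LDAG structure
#'
#' Fits the CPTs of `model` from data by Dirichlet-multinomial posterior
#' means, pooling counts over label-merged parent configurations so the
#' label constraints hold exactly in the fit.
#'
#' @inheritParams ldag_marginal_likelihood
#' @return the `ldag` with its `cpts` filled in.
#' @export
ldag_fit_cpts <- function(x, model, ess = 1) {
  stopifnot(inherits(model, "ldag"))
  nodes <- model$dag$nodes
  cnt <- counts_array(x, nodes, model$card)
  cpts <- list()
  for (node in nodes) {
    pa <- dag_parents(model$dag, node)
    r <- model$card[[node]]
    ipa <- match(pa, nodes); ino <- match(node, nodes)
    fam <- apply(cnt, c(ipa, ino), sum)
    q <- as.integer(prod(model$card[pa]))
    N <- matrix(as.numeric(fam), nrow = q, ncol = r)
    part <- label_partition(model, node)
    Np <- rowsum(N, part)
    m <- as.numeric(rowsum(rep(1, q), part))
    A <- Np + m * ess / (q * r)
    P <- A / rowSums(A)
    cpts[[node]] <- P[match(part, sort(unique(part))), , drop = FALSE]
  }
  model$cpts <- cpts
  validate_cpts(model)
  model
}

# --- equivalence by induced (conditional + context-specific) independences -

# context-specific reduced graph: remove every edge whose label fires in the
# given context (an assignment of a subset of nodes); a label fires when its
# context variables are all assigned and match
reduced_dag <- function(model, assignment) {
  amat <- model$dag$amat
  for (lb in model$labels) {
    pa <- lb$edge[[1L]]; ch <- lb$edge[[2L]]
    for (ctx in lb$contexts) {
      co <- names(ctx)
      if (all(co %in% names(assignment)) &&
          all(assignment[co] == ctx)) {
        amat[node_index(model$dag, pa), node_index(model$dag, ch)] <- FALSE
        break
      }
    }
  }
  new_dag(model$dag$nodes, amat)
}

# signature of all CI and CSI statements an LDAG over <= 3 variables
# induces; two structures are statistically equivalent iff signatures match
csi_signature <- function(model) {
  nodes <- model$dag$nodes
  g <- model$dag
  bits <- logical(0)
  for (i in seq_len(length(nodes) - 1L)) for (j in seq.int(i + 1L,
                                                           length(nodes))) {
    x <- nodes[i]; y <- nodes[j]
    rest <- setdiff(nodes, c(x, y))
    bits <- c(bits, is_d_separated(g, separation_query(x, y)))
    if (length(rest) == 1L) {
      z <- rest
      bits <- c(bits, is_d_separated(g, separation_query(x, y, z)))
      for (v in seq_len(model$card[[z]]) - 1L) {
        rg <- reduced_dag(model, stats::setNames(v, z))
        bits <- c(bits, is_d_separated(rg, separation_query(x, y, z)))
      }
    }
  }
  paste(as.integer(bits), collapse = "")
}

# all DAGs over exactly 3 nodes (25 of them)
all_three_node_dags <- function(nodes) {
  stopifnot(length(nodes) == 3L)
  pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  out <- list()
  for (s1 in 0:2) for (s2 in 0:2) for (s3 in 0:2) {
    amat <- matrix(FALSE, 3L, 3L, dimnames = list(nodes, nodes))
    st <- c(s1, s2, s3)
    for (k in 1:3) {
      if (st[k] == 1L) amat[pairs[k, 1L], pairs[k, 2L]] <- TRUE
      if (st[k] == 2L) amat[pairs[k, 2L], pairs[k, 1L]] <- TRUE
    }
    g <- new_dag(nodes, amat)
    if (!is.null(topological_order(g))) out[[length(out) + 1L]] <- g
  }
  out
}

# all admissible label assignments of a 3-node binary DAG: for every child
# with two parents, each incoming edge may carry no label or a proper,
# non-empty subset of the co-parent's states ({0} or {1} for binary)
ldag_candidates_for_dag <- function(g, card) {
  base <- ldag(g, card)
  out <- list(base)
  two_parent <- g$nodes[colSums(g$amat) == 2L]
  for (ch in two_parent) {
    pa <- dag_parents(g, ch)
    opts <- lapply(pa, function(p) {
      co <- setdiff(pa, p)
      c(list(NULL),
        lapply(seq_len(card[[co]]) - 1L, function(v)
          list(edge = c(p, ch), contexts = list(stats::setNames(v, co)))))
    })
    combos <- expand.grid(lapply(opts, seq_along))
    new <- list()
    for (r in seq_len(nrow(combos))) {
      picked <- Filter(Negate(is.null),
                       lapply(seq_along(opts),
                              function(k) opts[[k]][[combos[r, k]]]))
      if (!length(picked)) next                 # the unlabelled base itself
      for (m in out)
        new[[length(new) + 1L]] <- ldag(g, card, c(m$labels, picked))
    }
    out <- c(out, new)
  }
  out
}

# session cache of the candidate enumeration: the candidate structures,
# their equivalence signatures, and per-node (parent set, label partition)
# descriptors are dataset-independent, so they are computed once per
# (node names, model class) and reused across replicates
.candidate_cache <- new.env(parent = emptyenv())

candidate_set <- function(nodes, model_class, card) {
  key <- paste(c(nodes, model_class), collapse = "\r")
  hit <- .candidate_cache[[key]]
  if (!is.null(hit)) return(hit)
  cands <- list()
  for (g in all_three_node_dags(nodes)) {
    if (model_class == "dag") {
      cands[[length(cands) + 1L]] <- ldag(g, card)
    } else {
      cands <- c(cands, ldag_candidates_for_dag(g, card))
    }
  }
  sigs <- vapply(cands, csi_signature, character(1))
  families <- lapply(cands, function(m)
    lapply(nodes, function(v) {
      pa <- dag_parents(m$dag, v)
      list(node = v, key = paste(c(v, pa), collapse = "\r"),
           q = as.integer(prod(m$card[pa])),
           partition = label_partition(m, v))
    }))
  val <- list(cands = cands, sigs = sigs, families = families)
  assign(key, val, envir = .candidate_cache)
  val
}

# log Dirichlet-multinomial family score from a q x r count matrix, a label
# partition of the q rows, and the BDeu cell hyperparameter ess / (q * r)
family_score <- function(N, partition, ess) {
  Np <- rowsum(N, partition)
  m <- as.numeric(rowsum(rep(1, nrow(N)), partition))
  A <- m * (ess / (nrow(N) * ncol(N)))
  rs <- rowSums(Np)
  sum(lgamma(A * ncol(N)) - lgamma(A * ncol(N) + rs)) +
    sum(lgamma(A + Np) - lgamma(matrix(A, nrow(Np), ncol(N))))
}

#' Exhaustive Bayesian structure learning over three binary variables
#'
#' Enumerates every candidate structure of the chosen model class — all 25
#' DAGs over the three variables and, for the LDAG class, additionally every
#' admissible labelling of edges whose child has two parents — scores each
#' with the Dirichlet-multinomial marginal likelihood, groups candidates
#' into statistical-equivalence classes by their induced set of conditional
#' and context-specific independences, and returns the class of the
#' top-scoring structure.
#'
#' @param x data frame or matrix of binary (0/1) observations over exactly
#'   three named variables, or a contingency array.
#' @param model_class `"dag"` for plain DAGs, `"ldag"` to include labels.
#' @param ess equivalent sample size of the BDeu-style prior.
#' @param tie_tol two classes whose best scores differ by less than this (in
#'   log units) are treated as tied; a tied top class is flagged ambiguous.
#' @return an object of class `"structure_class"`: `members` (list of
#'   `ldag` structures), `score` (log marginal likelihood of its best
#'   member), `ambiguous`, `model_class`, and `n_candidates`.
#' @export
learn_structure <- function(x, model_class = c("dag", "ldag"), ess = 1,
                            tie_tol = 1e-9) {
  model_class <- match.arg(model_class)
  if (is.array(x) && !is.null(dimnames(x))) {
    nodes <- names(dimnames(x))
  } else {
    nodes <- colnames(x)
  }
  if (length(nodes) != 3L)
    stop("exhaustive search is restricted to exactly 3 variables")
  card <- stats::setNames(rep(2L, 3L), nodes)
  cnt <- counts_array(x, nodes, card)
  cs <- candidate_set(nodes, model_class, card)
  # family count matrices, one per (node, parent set), shared by candidates
  fam_counts <- new.env(parent = emptyenv())
  for (v in nodes) {
    iv <- match(v, nodes)
    others <- setdiff(nodes, v)
    for (k in 0:2) for (pa in if (k) utils::combn(others, k,
                                                  simplify = FALSE)
                        else list(character())) {
      ipa <- match(pa, nodes)
      fam <- apply(cnt, c(ipa, iv), sum)
      q <- as.integer(prod(card[pa]))
      assign(paste(c(v, pa), collapse = "\r"),
             matrix(as.numeric(fam), nrow = q, ncol = card[[v]]),
             envir = fam_counts)
    }
  }
  scores <- vapply(cs$families, function(fams)
    sum(vapply(fams, function(f)
      family_score(fam_counts[[f$key]], f$partition, ess), numeric(1))),
    numeric(1))
  class_best <- tapply(scores, cs$sigs, max)
  ord <- order(class_best, decreasing = TRUE)
  top_sig <- names(class_best)[ord[1L]]
  ambiguous <- length(ord) > 1L &&
    class_best[ord[1L]] - class_best[ord[2L]] < tie_tol
  structure(list(members = cs$cands[cs$sigs == top_sig],
                 score = unname(class_best[ord[1L]]),
                 ambiguous = ambiguous,
                 model_class = model_class,
                 n_candidates = length(cs$cands)),
            class = "structure_class")
}

#' @export
print.structure_class <- function(x, ...) {
  cat(sprintf(
    "structure_class (%s): %d member(s), log score %.4f%s\n",
    x$model_class, length(x$members), x$score,
    if (x$ambiguous) " [tied with another class]" else ""))
  invisible(x)
}

#' Did structure learning recover the community mechanism?
#'
#' A learned equivalence class counts as a correct discovery only when every
#' member contains all the edges `causes -> outcome` — i.e. the joint causal
#' mechanism is present in each structure the data cannot distinguish — and
#' the class was not tied with a competing class (ties are conservatively
#' incorrect).
#'
#' @param cls a `"structure_class"` from [learn_structure()].
#' @param causes character vector of cause nodes.
#' @param outcome outcome node.
#' @return `TRUE` or `FALSE`.
#' @export
is_correct_discovery <- function(cls, causes = c("C1", "C2"),
                                 outcome = "O") {
  stopifnot(inherits(cls, "structure_class"))
  if (!length(cls$members)) return(FALSE)
  if (isTRUE(cls$ambiguous)) return(FALSE)
  all(vapply(cls$members, function(m) {
    io <- match(outcome, m$dag$nodes)
    ic <- match(causes, m$dag$nodes)
    if (anyNA(io) || anyNA(ic)) return(FALSE)
    all(m$dag$amat[ic, io])
  }, TRUE))
}

#' Orient an edge from a context-specific independence
#'
#' The deduction used when previous knowledge supplies a confounded triple
#' `effect_var <- driver -> outcome_var` (the driver a known direct cause of
#' both) plus an undirected adjacency between `effect_var` and
#' `outcome_var`, and the data exhibit the context-specific independence
#' "`outcome_var` is independent of `driver` when `effect_var = v`". A
#' variable can only modulate the dependence between two others if it is a
#' cause of one of them; since `effect_var` is already known to be an effect
#' of the driver, it must be a cause of `outcome_var`, orienting the
#' remaining edge — information no plain Markov-equivalence argument can
#' provide.
#'
#' @param known a `dag` carrying the established edges (must contain
#'   `driver -> effect_var`).
#' @param driver,effect_var,outcome_var node names: the common cause, the
#'   label's context variable, and the variable at the other end of the
#'   undirected edge.
#' @param csi `NULL` when no context-specific independence is available, or
#'   a list `list(context_value = v)` stating in which state of
#'   `effect_var` the `driver -> outcome_var` dependence vanishes.
#' @return `list(status, edge)`: `status = "oriented"` with
#'   `edge = c(effect_var, outcome_var)`, or `status = "unknown"` when no
#'   CSI statement is supplied (the two orientations are Markov equivalent).
#' @export
csi_orient <- function(known, driver, effect_var, outcome_var, csi = NULL) {
  stopifnot(inherits(known, "dag"))
  idr <- node_index(known, driver)
  ief <- node_index(known, effect_var)
  iou <- node_index(known, outcome_var)
  adj <- known$amat | t(known$amat)
  if (!adj[idr, ief] || !adj[idr, iou])
    stop("the context variable's modulated pair must both be adjacent to ",
         "the driver in the known structure")
  if (reach_directed(known$amat, ief)[idr])
    stop("inconsistent knowledge: the context variable is an ancestor of ",
         "the driver it is supposed to be an effect of")
  if (!known$amat[idr, ief])
    stop("the driver must be a known direct cause of the context variable")
  if (is.null(csi)) return(list(status = "unknown", edge = NULL))
  list(status = "oriented", edge = c(effect_var, outcome_var))
}

#' LDAG serialisation as JSON
#'
#' `{nodes, cardinalities, edges, labels: [{edge, contexts}], cpts}` with
#' edges as `[parent, child]` pairs and CPT rows in parent-configuration
#' order.
#'
#' @param model an `ldag`.
#' @param path file path.
#' @export
write_ldag_json <- function(model, path) {
  stopifnot(inherits(model, "ldag"))
  e <- dag_edges(model$dag)
  obj <- list(
    nodes = model$dag$nodes,
    cardinalities = as.list(model$card),
    edges = unname(apply(e, 1L, function(r) as.list(unname(r)),
                         simplify = FALSE)),
    labels = lapply(model$labels, function(lb)
      list(edge = as.list(unname(lb$edge)),
           contexts = lapply(lb$contexts, as.list))),
    cpts = lapply(model$cpts, function(m) apply(m, 1L, c, simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ldag_json
#' @export
read_ldag_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- unlist(obj$nodes)
  edges <- if (length(obj$edges))
    do.call(rbind, lapply(obj$edges, unlist)) else NULL
  g <- dag(nodes, edges)
  card <- unlist(obj$cardinalities)[nodes]
  labels <- lapply(obj$labels, function(lb)
    list(edge = unlist(lb$edge),
         contexts = lapply(lb$contexts, function(ctx)
           stats::setNames(as.integer(unlist(ctx)), names(ctx)))))
  cpts <- if (length(obj$cpts)) {
    lapply(obj$cpts, function(rows)
      do.call(rbind, lapply(rows, unlist)))
  } else NULL
  ldag(g, card, labels, cpts)
}
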