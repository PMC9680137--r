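#' Joint distributions over discrete variables
#'
#' A thin container for a full joint probability table: a numeric array with
#' one dimension per variable, `dimnames` giving the state labels, entries
#' non-negative and summing to 1.
#'
#' @param prob named numeric array with complete `dimnames`.
#' @return an object of class `"discrete_joint"`.
#' @export
discrete_joint <- function(prob) {
  dn <- dimnames(prob)
  if (is.null(dn) || is.null(names(dn)) || any(names(dn) == ""))
    stop("prob must be an array with named dimnames (one per variable)")
  if (any(prob < -1e-12)) stop("negative probabilities")
  if (abs(sum(prob) - 1) > 1e-9) stop("probabilities must sum to 1")
  structure(list(vars = names(dn),
                 card = vapply(dn, length, 1L),
                 prob = prob),
            class = "discrete_joint")
}

#' @export
print.discrete_joint <- function(x, ...) {
  cat(sprintf("discrete_joint over %s (%d cells)\n",
              paste(x$vars, collapse = ", "), length(x$prob)))
  invisible(x)
}

#' Marginal of a discrete joint
#' @param joint a `discrete_joint`.
#' @param vars variables to keep.
#' @return a `discrete_joint` over `vars`.
#' @export
joint_marginal <- function(joint, vars) {
  stopifnot(inherits(joint, "discrete_joint"))
  keep <- match(vars, joint$vars)
  if (anyNA(keep)) stop("unknown variable(s): ",
                        paste(vars[is.na(keep)], collapse = ", "))
  m <- apply(joint$prob, keep, sum)
  if (length(keep) == 1L) {
    m <- array(m, dim = length(m),
               dimnames = stats::setNames(dimnames(joint$prob)[keep],
                                          joint$vars[keep]))
  }
  discrete_joint(m)
}

#' Backdoor adjustment on a discrete joint
#'
#' The adjustment identity
#' `p(outcome | do(exposure = c)) = sum_z p(outcome | c, z) p(z)`:
#' valid whenever `z` satisfies the backdoor criterion in the generating
#' graph, in which case it equals the interventional distribution obtained
#' by graph surgery. Works purely on the observational joint; the graph is
#' not consulted.
#'
#' @param joint a `discrete_joint`.
#' @param exposure,outcome variable names.
#' @param z character vector of adjustment variables (may be empty, giving
#'   the plain conditional).
#' @return matrix with one row per exposure level and one column per outcome
#'   level; each row sums to 1.
#' @export
backdoor_estimate <- function(joint, exposure, outcome, z = character()) {
  stopifnot(inherits(joint, "discrete_joint"))
  all_named <- c(exposure, outcome, z)
  if (anyDuplicated(all_named)) stop("exposure, outcome, z must be disjoint")
  if (!all(all_named %in% joint$vars))
    stop("unknown variable(s): ",
         paste(setdiff(all_named, joint$vars), collapse = ", "))
  ie <- match(exposure, joint$vars)
  io <- match(outcome, joint$vars)
  iz <- match(z, joint$vars)
  # p(exposure, outcome, z) with z flattened into one index
  pxyz <- apply(joint$prob, c(ie, io, iz), sum)
  dx <- joint$card[ie]; dy <- joint$card[io]
  nz <- prod(joint$card[iz])      # 1 when z is empty
  pxyz <- array(pxyz, dim = c(dx, dy, nz))
  pz <- apply(pxyz, 3L, sum)
  pxz <- apply(pxyz, c(1L, 3L), sum)
  out <- matrix(0, dx, dy,
                dimnames = list(dimnames(joint$prob)[[ie]],
                                dimnames(joint$prob)[[io]]))
  zlabels <- if (length(iz)) {
    do.call(paste, c(expand.grid(dimnames(joint$prob)[iz]), sep = ","))
  } else ""
  for (k in seq_len(nz)) {
    if (pz[k] <= 0) next
    empty <- which(pxz[, k] <= 0)
    if (length(empty))
      stop(sprintf(
        "positivity violation: p(%s = %s, {%s} = {%s}) = 0",
        exposure, dimnames(joint$prob)[[ie]][empty[1L]],
        paste(z, collapse = ","), zlabels[k]))
    out <- out + pz[k] * pxyz[, , k] / pxz[, k]
  }
  out
}

#' Interventional truth by graph surgery
#'
#' Deletes the incoming edges of the exposure in a discrete Bayesian network
#' (an [ldag()], possibly label-free), clamps the exposure to `level`, and
#' recomputes the joint by multiplying the remaining conditional tables.
#' This is the definition of the do-operator and serves as the exact
#' reference that [backdoor_estimate()] must reproduce under a valid
#' adjustment set.
#'
#' @param model an `ldag` with conditional probability tables.
#' @param exposure node name.
#' @param level state of the exposure to clamp (integer in
#'   `0:(cardinality - 1)`).
#' @return a `discrete_joint` over all variables of the model (the exposure
#'   dimension is a point mass at `level`).
#' @export
surgery_truth <- function(model, exposure, level) {
  stopifnot(inherits(model, "ldag"))
  if (is.null(model$cpts)) stop("model must carry conditional tables")
  ie <- node_index(model$dag, exposure)
  if (level < 0 || level >= model$card[[exposure]])
    stop("level outside the exposure's state space")
  m <- model
  m$dag$amat[, ie] <- FALSE              # sever incoming edges
  pt <- matrix(0, 1L, m$card[[exposure]])
  pt[1L, level + 1L] <- 1                # clamp
  m$cpts[[exposure]] <- pt
  m$labels <- m$labels[labels_child(m$labels) != exposure]
  bn_joint(m)
}

#' Sample configurations from a discrete joint
#'
#' @param joint a `discrete_joint`.
#' @param n number of i.i.d. rows.
#' @param seed optional integer for reproducibility.
#' @return data frame of integer state codes (0-based), one column per
#'   variable.
#' @export
sample_joint <- function(joint, n, seed = NULL) {
  stopifnot(inherits(joint, "discrete_joint"))
  if (!is.null(seed)) set.seed(seed)
  cells <- which(array(TRUE, dim = dim(joint$prob)), arr.ind = TRUE) - 1L
  if (is.null(dim(cells))) cells <- matrix(cells, ncol = 1L)
  idx <- sample.int(nrow(cells), n, replace = TRUE,
                    prob = as.numeric(joint$prob))
  out <- as.data.frame(cells[idx, , drop = FALSE])
  names(out) <- joint$vars
  rownames(out) <- NULL
  out
}

#' Plug-in empirical joint from finite samples
#'
#' Empirical cell frequencies, optionally with add-half smoothing (half a
#' pseudo-count per cell) to guard against empty cells before adjustment.
#'
#' @param x data frame/matrix of integer state codes (0-based), columns
#'   named after the variables.
#' @param card named integer vector of cardinalities.
#' @param smooth add 1/2 to every cell before normalising (off by default:
#'   the plug-in estimator).
#' @return a `discrete_joint`.
#' @export
empirical_joint <- function(x, card, smooth = FALSE) {
  cnt <- counts_array(x, names(card), card)
  p <- as.numeric(cnt) + if (smooth) 0.5 else 0
  arr <- array(p / sum(p), dim = dim(cnt), dimnames = dimnames(cnt))
  discrete_joint(arr)
}

#' Joint-table I/O as TSV
#'
#' One row per configuration (a column of state labels per variable) plus a
#' `probability` column.
#'
#' @param joint a `discrete_joint`.
#' @param path file path.
#' @export
write_joint_tsv <- function(joint, path) {
  stopifnot(inherits(joint, "discrete_joint"))
  grid <- expand.grid(dimnames(joint$prob), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$probability <- as.numeric(joint$prob)
  utils::write.table(grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_joint_tsv
#' @export
read_joint_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  vars <- setdiff(names(tab), "probability")
  dn <- lapply(tab[vars], function(v) sort(unique(v)))
  arr <- array(0, dim = unname(vapply(dn, length, 1L)), dimnames = dn)
  idx <- as.matrix(as.data.frame(Map(match, tab[vars], dn)))
  arr[idx] <- as.numeric(tab$probability)
  discrete_joint(arr)
}
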