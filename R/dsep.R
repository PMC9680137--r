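#' Conditional-independence queries on a DAG
#'
#' A separation query carries the statement "x independent of y given z";
#' `is_d_separated()` decides it graphically.
#'
#' @param x,y node identifiers (distinct).
#' @param z character vector of conditioning nodes (may be empty); must not
#'   contain `x` or `y`.
#' @return an object of class `"separation_query"`.
#' @export
separation_query <- function(x, y, z = character()) {
  x <- as.character(x); y <- as.character(y); z <- as.character(z)
  if (length(x) != 1L || length(y) != 1L) stop("x and y must be single nodes")
  if (x == y) stop("x and y must be distinct")
  if (x %in% z || y %in% z) stop("x and y must not be in the conditioning set")
  structure(list(x = x, y = y, z = unique(z)), class = "separation_query")
}

#' Test d-separation
#'
#' Decides whether every path between `q$x` and `q$y` is blocked given `q$z`,
#' using the moralised-ancestral-graph criterion: restrict to the ancestral
#' closure of \{x, y\} union z, marry co-parents, drop orientations, delete z,
#' and test graphical connectivity.
#'
#' @param g a `dag`.
#' @param q a `separation_query` (or anything coercible via
#'   `separation_query(x, y, z)` fields).
#' @return `TRUE` iff x and y are d-separated by z in `g`.
#' @examples
#' g <- dag(c("Cstar", "O", "C"), rbind(c("Cstar", "O"), c("C", "O")))
#' is_d_separated(g, separation_query("Cstar", "C"))          # TRUE
#' is_d_separated(g, separation_query("Cstar", "C", "O"))     # FALSE: collider
#' @export
is_d_separated <- function(g, q) {
  stopifnot(inherits(g, "dag"))
  if (!inherits(q, "separation_query")) q <- separation_query(q$x, q$y, q$z)
  ix <- node_index(g, q$x); iy <- node_index(g, q$y)
  iz <- if (length(q$z)) node_index(g, q$z) else integer()
  !moral_connected(g$amat, ix, iy, iz)
}

# connectivity of x and y in the moralised ancestral graph after deleting z
moral_connected <- function(amat, ix, iy, iz) {
  keep <- rep(FALSE, ncol(amat))
  keep[c(ix, iy, iz)] <- TRUE
  keep <- keep | reach_directed(t(amat), c(ix, iy, iz))  # ancestral closure
  sub <- amat[keep, keep, drop = FALSE]
  moral <- sub | t(sub)
  # marry parents that share a child
  for (j in seq_len(ncol(sub))) {
    pa <- which(sub[, j])
    if (length(pa) > 1L) moral[pa, pa] <- TRUE
  }
  diag(moral) <- FALSE
  ids <- which(keep)
  drop <- ids %in% iz
  moral[drop, ] <- FALSE
  moral[, drop] <- FALSE
  # BFS from x to y
  src <- match(ix, ids); dst <- match(iy, ids)
  seen <- rep(FALSE, length(ids)); seen[src] <- TRUE
  frontier <- src
  while (length(frontier)) {
    nxt <- which(colSums(moral[frontier, , drop = FALSE]) > 0 & !seen)
    if (dst %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen[dst]
}

#' Backdoor criterion
#'
#' Tests whether `z` is a valid backdoor adjustment set for the effect of
#' `exposure` on `outcome` in `g`: no member of `z` is a descendant of the
#' exposure, and `z` blocks every path that enters the exposure through an
#' incoming edge (checked as d-separation after removing the exposure's
#' outgoing edges).
#'
#' @param g a `dag`.
#' @param exposure,outcome node identifiers (distinct).
#' @param z character vector of adjustment nodes.
#' @return `TRUE` iff `z` satisfies the backdoor criterion.
#' @examples
#' g <- dag(c("C", "E", "O"), rbind(c("E", "C"), c("E", "O"), c("C", "O")))
#' satisfies_backdoor(g, "C", "O", "E")            # TRUE: blocks C <- E -> O
#' satisfies_backdoor(g, "C", "O", character())    # FALSE: open backdoor
#' @export
satisfies_backdoor <- function(g, exposure, outcome, z = character()) {
  stopifnot(inherits(g, "dag"))
  z <- as.character(z)
  ix <- node_index(g, exposure); iy <- node_index(g, outcome)
  if (ix == iy) stop("exposure and outcome must be distinct")
  iz <- if (length(z)) node_index(g, z) else integer()
  if (any(c(ix, iy) %in% iz)) stop("z must not contain exposure or outcome")
  desc <- reach_directed(g$amat, ix)
  if (any(desc[iz])) return(FALSE)
  amat2 <- g$amat
  amat2[ix, ] <- FALSE  # cut causal paths; what remains are backdoor paths
  !moral_connected(amat2, ix, iy, iz)
}
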