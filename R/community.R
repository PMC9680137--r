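#' Two-OTU community-effect model
#'
#' Specification of the binary community system (C1, C2, O): two OTUs that
#' tend to co-occur, and a disease outcome whose risk is raised only when
#' both OTUs are present — a joint causal effect no single taxon carries.
#'
#' The OTU pair follows the symmetric log-linear coexistence law
#' `P(C1 = c1, C2 = c2) proportional to exp(alpha * 1[c1 == c2])`: at
#' `alpha = 0` the OTUs are independent and uniform; as `alpha` grows,
#' configurations where both or neither OTU is present dominate, and in the
#' limit the two presences become deterministically equal (destroying
#' identifiability, since the pair then acts as a single cause). Disease
#' risk is `baseline` except in the both-present cell, where it is
#' `rr * baseline`.
#'
#' @param alpha coexistence strength, >= 0 and finite.
#' @param rr risk ratio of the both-present cell, >= 1; `rr * baseline`
#'   must not exceed 1.
#' @param baseline baseline disease probability (default 0.05).
#' @param n sample size for [sample_community()].
#' @return an object of class `"community_spec"`.
#' @export
community_spec <- function(alpha = 1, rr = 5, baseline = 0.05, n = 1000L) {
  if (alpha < 0 || !is.finite(alpha)) stop("alpha must be finite and >= 0")
  if (rr < 1) stop("rr must be >= 1")
  if (baseline <= 0 || baseline >= 1) stop("baseline must be in (0, 1)")
  if (rr * baseline > 1) stop("rr * baseline exceeds 1")
  if (n < 1L) stop("n must be positive")
  structure(list(alpha = alpha, rr = rr, baseline = baseline,
                 n = as.integer(n)),
            class = "community_spec")
}

#' Joint distribution of the community model
#'
#' @param spec a [community_spec()].
#' @return a `discrete_joint` over `(C1, C2, O)`, each binary.
#' @export
community_joint <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  ea <- exp(spec$alpha)
  pcc <- matrix(c(ea, 1, 1, ea), 2L, 2L) / (2 * ea + 2)   # [c1+1, c2+1]
  po1 <- matrix(spec$baseline, 2L, 2L)
  po1[2L, 2L] <- spec$rr * spec$baseline
  arr <- array(0, dim = c(2L, 2L, 2L),
               dimnames = list(C1 = c("0", "1"), C2 = c("0", "1"),
                               O = c("0", "1")))
  arr[, , 1L] <- pcc * (1 - po1)
  arr[, , 2L] <- pcc * po1
  discrete_joint(arr)
}

#' Sample binary community data
#'
#' Draws `spec$n` i.i.d. rows of `(C1, C2, O)` from [community_joint()].
#'
#' @param spec a [community_spec()].
#' @param seed optional integer for reproducibility.
#' @return data frame with integer 0/1 columns `C1`, `C2`, `O`.
#' @export
sample_community <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  joint <- community_joint(spec)
  cells <- which(array(TRUE, dim = dim(joint$prob)), arr.ind = TRUE) - 1L
  idx <- sample.int(nrow(cells), spec$n, replace = TRUE,
                    prob = as.numeric(joint$prob))
  out <- as.data.frame(cells[idx, , drop = FALSE])
  names(out) <- joint$vars
  rownames(out) <- NULL
  out
}

#' The generating community structure as an LDAG
#'
#' The ground truth behind [community_joint()]: `C1 -> C2` (the coexistence
#' dependence realised as a directed edge), both OTUs parents of `O`, and a
#' label on each OTU-to-outcome edge stating that its effect vanishes when
#' the other OTU is absent. Useful as a reference structure in tests and
#' for surgery-based interventional truths.
#'
#' @param spec a [community_spec()].
#' @return an `ldag` with CPTs matching [community_joint()] exactly.
#' @export
community_ldag <- function(spec) {
  g <- dag(c("C1", "C2", "O"),
           rbind(c("C1", "C2"), c("C1", "O"), c("C2", "O")))
  card <- c(C1 = 2L, C2 = 2L, O = 2L)
  labels <- list(
    list(edge = c("C1", "O"), contexts = list(c(C2 = 0L))),
    list(edge = c("C2", "O"), contexts = list(c(C1 = 0L))))
  ea <- exp(spec$alpha)
  p11 <- ea / (2 * ea + 2)            # P(C1 = c, C2 = c) per diagonal cell
  p10 <- 1 / (2 * ea + 2)
  b <- spec$baseline
  cpts <- list(
    C1 = matrix(c(0.5, 0.5), 1L, 2L),
    # P(C2 | C1): diagonal-favouring rows
    C2 = rbind(c(p11, p10) / (p11 + p10), c(p10, p11) / (p10 + p11)),
    # rows ordered (C1, C2) = (0,0), (1,0), (0,1), (1,1)
    O = rbind(c(1 - b, b), c(1 - b, b), c(1 - b, b),
              c(1 - spec$rr * b, spec$rr * b)))
  ldag(g, card, labels, cpts)
}
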