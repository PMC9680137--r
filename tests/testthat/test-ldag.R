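three_binary <- c(C1 = 2L, C2 = 2L, O = 2L)

collider_dag <- function() dag(c("C1", "C2", "O"),
                               rbind(c("C1", "O"), c("C2", "O")))

test_that("ldag construction validates labels and CPT constraints", {
  g <- collider_dag()
  expect_error(ldag(g, c(C1 = 1L, C2 = 2L, O = 2L)), "cardinality")
  expect_error(ldag(g, three_binary,
                    list(list(edge = c("C1", "C2"),
                              contexts = list(c(O = 0L))))), "absent edge")
  expect_error(ldag(g, three_binary,
                    list(list(edge = c("C1", "O"),
                              contexts = list(c(C1 = 0L))))), "exactly")
  expect_error(ldag(g, three_binary,
                    list(list(edge = c("C1", "O"),
                              contexts = list(c(C2 = 5L))))), "state space")
  # a CPT violating the label's equality constraint is rejected
  lab <- list(list(edge = c("C1", "O"), contexts = list(c(C2 = 0L))))
  cpts_bad <- list(C1 = matrix(c(0.5, 0.5), 1),
                   C2 = matrix(c(0.5, 0.5), 1),
                   O = rbind(c(0.9, 0.1), c(0.2, 0.8),
                             c(0.9, 0.1), c(0.5, 0.5)))
  expect_error(ldag(g, three_binary, lab, cpts_bad), "equality")
  cpts_ok <- cpts_bad
  cpts_ok$O[2L, ] <- cpts_ok$O[1L, ]   # rows (0,0) and (1,0) merged by label
  expect_silent(ldag(g, three_binary, lab, cpts_ok))
})

test_that("community_joint reproduces its limiting cases", {
  j0 <- community_joint(community_spec(alpha = 0, rr = 5))
  pc1c2 <- apply(j0$prob, c(1, 2), sum)
  expect_equal(unname(pc1c2), matrix(0.25, 2, 2))
  jinf <- community_joint(community_spec(alpha = 50, rr = 5))
  pinf <- apply(jinf$prob, c(1, 2), sum)
  expect_equal(unname(diag(pinf)), c(0.5, 0.5), tolerance = 1e-12)
  expect_lt(pinf[1, 2] + pinf[2, 1], 1e-12)
  j1 <- community_joint(community_spec(alpha = 1, rr = 1))
  po_given <- apply(j1$prob, c(1, 2), function(p) p[2] / sum(p))
  expect_equal(unname(po_given), matrix(0.05, 2, 2))
  expect_error(community_spec(alpha = 1, rr = 30, baseline = 0.05),
               "exceeds 1")
})

test_that("community_ldag reproduces community_joint through its CPTs", {
  spec <- community_spec(alpha = 1.3, rr = 8)
  expect_equal(bn_joint(community_ldag(spec))$prob,
               community_joint(spec)$prob, tolerance = 1e-12)
})

test_that("community sampling is reproducible and matches the analytic
          cells at scale", {
  spec <- community_spec(alpha = 2, rr = 10, n = 1e5)
  x1 <- sample_community(spec, seed = 7)
  x2 <- sample_community(spec, seed = 7)
  expect_identical(x1, x2)
  # P(C1 = C2) = 2 e^alpha / (2 e^alpha + 2)
  p_agree <- exp(2) / (exp(2) + 1)
  obs <- mean(x1$C1 == x1$C2)
  expect_lt(abs(obs - p_agree), 3 * sqrt(p_agree * (1 - p_agree) / 1e5))
  # empirical risk ratio between both-present and both-absent cells
  p11 <- mean(x1$O[x1$C1 == 1 & x1$C2 == 1])
  p00 <- mean(x1$O[x1$C1 == 0 & x1$C2 == 0])
  n11 <- sum(x1$C1 == 1 & x1$C2 == 1)
  n00 <- sum(x1$C1 == 0 & x1$C2 == 0)
  # 3 delta-method standard errors of the ratio of the two proportions
  se <- 3 * (p11 / p00) *
    sqrt((1 - p11) / (p11 * n11) + (1 - p00) / (p00 * n00))
  expect_lt(abs(p11 / p00 - 10), se)
})

test_that("the no-label score is exactly the plain BDeu score", {
  set.seed(701)
  x <- sample_community(community_spec(alpha = 1, rr = 5, n = 500), seed = 1)
  g <- dag(c("C1", "C2", "O"), rbind(c("C1", "C2"), c("C2", "O")))
  m <- ldag(g, three_binary)
  # independent BDeu computation from first principles
  bdeu <- 0
  for (v in c("C1", "C2", "O")) {
    pa <- dag_parents(g, v)
    q <- prod(three_binary[pa])
    a <- 1 / (q * 2)
    cfg <- if (length(pa)) x[[pa]] else rep(0L, nrow(x))
    for (cv in 0:(q - 1)) {
      nk <- tabulate(x[[v]][cfg == cv] + 1L, 2L)
      bdeu <- bdeu + lgamma(2 * a) - lgamma(2 * a + sum(nk)) +
        sum(lgamma(a + nk) - lgamma(a))
    }
  }
  expect_equal(ldag_marginal_likelihood(x, m, ess = 1), bdeu,
               tolerance = 1e-10)
})

test_that("a single binary node's score has the beta-binomial closed form", {
  x <- data.frame(v = c(rep(1L, 13L), rep(0L, 7L)))
  m <- ldag(dag("v"), c(v = 2L))
  closed <- lbeta(13 + 0.5, 7 + 0.5) - lbeta(0.5, 0.5)
  expect_equal(ldag_marginal_likelihood(x, m, ess = 1), closed,
               tolerance = 1e-12)
})

test_that("a fully labelled edge scores exactly like the graph without it", {
  set.seed(702)
  x <- sample_community(community_spec(alpha = 1, rr = 5, n = 400), seed = 2)
  g_with <- collider_dag()
  m_full <- ldag(g_with, three_binary,
                 list(list(edge = c("C1", "O"),
                           contexts = list(c(C2 = 0L), c(C2 = 1L)))))
  m_without <- ldag(dag(c("C1", "C2", "O"), rbind(c("C2", "O"))),
                    three_binary)
  expect_equal(ldag_marginal_likelihood(x, m_full),
               ldag_marginal_likelihood(x, m_without), tolerance = 1e-12)
})

test_that("Markov-equivalent chains score identically and label pooling
          conserves counts", {
  set.seed(703)
  x <- sample_community(community_spec(alpha = 1.5, rr = 5, n = 600),
                        seed = 3)
  chains <- list(
    dag(c("C1", "C2", "O"), rbind(c("C1", "C2"), c("C2", "O"))),
    dag(c("C1", "C2", "O"), rbind(c("O", "C2"), c("C2", "C1"))),
    dag(c("C1", "C2", "O"), rbind(c("C2", "C1"), c("C2", "O"))))
  sc <- vapply(chains, function(g)
    ldag_marginal_likelihood(x, ldag(g, three_binary)), numeric(1))
  expect_lt(max(sc) - min(sc), 1e-9)
  # pooled counts sum to n for every node of a labelled structure
  m <- community_ldag(community_spec(alpha = 1.5, rr = 5))
  cnt <- microcausal:::counts_array(x, m$dag$nodes, m$card)
  for (v in m$dag$nodes) {
    pa <- dag_parents(m$dag, v)
    fam <- apply(cnt, c(match(pa, m$dag$nodes), match(v, m$dag$nodes)), sum)
    N <- matrix(as.numeric(fam), nrow = prod(m$card[pa]))
    part <- microcausal:::label_partition(m, v)
    expect_equal(sum(rowsum(N, part)), nrow(x))
  }
})

test_that("structure learning recovers a chain's equivalence class at
          scale", {
  set.seed(704)
  g <- dag(c("C1", "C2", "O"), rbind(c("C1", "C2"), c("C2", "O")))
  m <- ldag(g, three_binary, cpts = list(
    C1 = matrix(c(0.4, 0.6), 1),
    C2 = rbind(c(0.8, 0.2), c(0.25, 0.75)),
    O = rbind(c(0.7, 0.3), c(0.2, 0.8))))
  joint <- bn_joint(m)
  hits <- replicate(10, {
    x <- sample_joint(joint, 2e4)
    cls <- learn_structure(x, "dag")
    keys <- vapply(cls$members, function(mm)
      paste(sort(apply(dag_edges(mm$dag), 1, paste, collapse = ">")),
            collapse = ";"), character(1))
    length(cls$members) == 3L &&
      "C1>C2;C2>O" %in% keys && !cls$ambiguous
  })
  expect_gte(mean(hits), 0.9)
})

test_that("on community data the DAG class never discovers the mechanism
          while the LDAG class does at scale", {
  set.seed(705)
  spec <- community_spec(alpha = 1, rr = 10, n = 4000)
  dag_hits <- ldag_hits <- logical(20)
  for (r in 1:20) {
    x <- sample_community(spec)
    dag_hits[r] <- is_correct_discovery(learn_structure(x, "dag"))
    ldag_hits[r] <- is_correct_discovery(learn_structure(x, "ldag"))
  }
  expect_equal(sum(dag_hits), 0L)
  expect_gte(mean(ldag_hits), 0.7)
})

test_that("the fitted top LDAG recovers the community parameters", {
  set.seed(706)
  spec <- community_spec(alpha = 1, rr = 10, n = 1e5)
  x <- sample_community(spec)
  cls <- learn_structure(x, "ldag")
  expect_true(is_correct_discovery(cls))
  fit <- ldag_fit_cpts(x, cls$members[[1L]])
  po <- fit$cpts$O
  grid <- microcausal:::parent_grid(fit, "O")
  both <- which(rowSums(grid) == 2L)
  se5 <- 3 * sqrt(0.5 * 0.5 / (1e5 * 0.25))
  expect_lt(abs(po[both, 2L] - 0.5), se5)
  others <- setdiff(seq_len(4L), both)
  expect_true(all(abs(po[others, 2L] - 0.05) <
                    3 * sqrt(0.05 * 0.95 / (1e5 * 0.25))))
})

test_that("is_correct_discovery demands the mechanism in every member and
          rejects ties", {
  spec <- community_spec(alpha = 1, rr = 10)
  truth <- community_ldag(spec)
  singleton <- structure(list(members = list(truth), score = 0,
                              ambiguous = FALSE, model_class = "ldag",
                              n_candidates = 1L),
                         class = "structure_class")
  expect_true(is_correct_discovery(singleton))
  tied <- singleton; tied$ambiguous <- TRUE
  expect_false(is_correct_discovery(tied))
  tri <- cpdag_of(dag(c("C1", "C2", "O"),
                      rbind(c("C1", "C2"), c("C1", "O"), c("C2", "O"))))
  tri_members <- lapply(enumerate_class(tri), function(g)
    ldag(g, three_binary))
  tri_cls <- structure(list(members = tri_members, score = 0,
                            ambiguous = FALSE, model_class = "dag",
                            n_candidates = 25L),
                       class = "structure_class")
  expect_false(is_correct_discovery(tri_cls))
  empty_cls <- structure(list(members = list(ldag(dag(c("C1", "C2", "O")),
                                                  three_binary)),
                              score = 0, ambiguous = FALSE,
                              model_class = "dag", n_candidates = 25L),
                         class = "structure_class")
  expect_false(is_correct_discovery(empty_cls))
})

test_that("csi_orient deduces the remaining edge from the label", {
  known <- dag(c("C", "E", "O"), rbind(c("E", "C"), c("E", "O")))
  res <- csi_orient(known, driver = "E", effect_var = "C",
                    outcome_var = "O", csi = list(context_value = 1L))
  expect_equal(res$status, "oriented")
  expect_equal(res$edge, c("C", "O"))
  # without a context-specific statement the orientation stays open
  res2 <- csi_orient(known, "E", "C", "O", csi = NULL)
  expect_equal(res2$status, "unknown")
  # context variable must be adjacent to both modulated variables
  known2 <- dag(c("C", "E", "O", "Z"), rbind(c("E", "C"), c("E", "O")))
  expect_error(csi_orient(known2, "E", "Z", "O", csi = list(1L)),
               "adjacent")
  # a context variable that is an ancestor of the driver is contradictory
  known4 <- dag(c("C", "E", "O"), rbind(c("C", "E"), c("E", "O")))
  expect_error(csi_orient(known4, "E", "C", "O", csi = list(1L)),
               "ancestor|direct cause")
})

test_that("LDAGs round-trip through JSON", {
  tmp <- withr::local_tempfile(fileext = ".json")
  m <- community_ldag(community_spec(alpha = 1.2, rr = 6))
  write_ldag_json(m, tmp)
  m2 <- read_ldag_json(tmp)
  expect_identical(m2$dag$amat, m$dag$amat)
  expect_identical(m2$card, m$card)
  expect_equal(length(m2$labels), length(m$labels))
  expect_equal(m2$cpts$O, m$cpts$O, tolerance = 1e-12)
  expect_equal(bn_joint(m2)$prob, bn_joint(m)$prob, tolerance = 1e-12)
})
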