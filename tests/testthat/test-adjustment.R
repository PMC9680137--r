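confounded_triple <- function() {
  # E -> C, E -> O, C -> O with arbitrary positive tables
  g <- dag(c("E", "C", "O"), rbind(c("E", "C"), c("E", "O"), c("C", "O")))
  ldag(g, c(E = 2L, C = 2L, O = 2L), cpts = list(
    E = matrix(c(0.3, 0.7), 1),
    C = rbind(c(0.8, 0.2), c(0.35, 0.65)),
    # rows ordered (E, C) = (0,0), (1,0), (0,1), (1,1)
    O = rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.5, 0.5), c(0.15, 0.85))))
}

test_that("discrete_joint validates its table", {
  expect_error(discrete_joint(array(c(0.5, 0.5), 2)), "dimnames")
  bad <- array(c(0.7, 0.5), 2, dimnames = list(x = c("0", "1")))
  expect_error(discrete_joint(bad), "sum to 1")
})

test_that("adjusting for the confounder reproduces the surgery truth
          exactly; ignoring it does not", {
  m <- confounded_triple()
  j <- bn_joint(m)
  est <- backdoor_estimate(j, "C", "O", "E")
  for (lev in 0:1) {
    truth <- joint_marginal(surgery_truth(m, "C", lev), "O")$prob
    expect_equal(unname(est[lev + 1L, ]), as.numeric(truth),
                 tolerance = 1e-12)
  }
  unadj <- backdoor_estimate(j, "C", "O", character())
  truth1 <- joint_marginal(surgery_truth(m, "C", 1), "O")$prob
  expect_gt(max(abs(unadj[2L, ] - as.numeric(truth1))), 1e-3)
})

test_that("with no exposure effect the adjusted distribution is the
          outcome marginal", {
  g <- dag(c("E", "C", "O"), rbind(c("E", "C"), c("E", "O")))
  m <- ldag(g, c(E = 2L, C = 2L, O = 2L), cpts = list(
    E = matrix(c(0.4, 0.6), 1),
    C = rbind(c(0.9, 0.1), c(0.3, 0.7)),
    O = rbind(c(0.8, 0.2), c(0.25, 0.75))))
  j <- bn_joint(m)
  est <- backdoor_estimate(j, "C", "O", "E")
  po <- as.numeric(joint_marginal(j, "O")$prob)
  expect_equal(unname(est[1L, ]), po, tolerance = 1e-12)
  expect_equal(unname(est[2L, ]), po, tolerance = 1e-12)
})

test_that("an exposure independent of the adjustment set reduces to the
          plain conditional", {
  # E and C unconnected; both affect O
  g <- dag(c("E", "C", "O"), rbind(c("E", "O"), c("C", "O")))
  m <- ldag(g, c(E = 2L, C = 2L, O = 2L), cpts = list(
    E = matrix(c(0.45, 0.55), 1),
    C = matrix(c(0.7, 0.3), 1),
    O = rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.4, 0.6), c(0.1, 0.9))))
  j <- bn_joint(m)
  est <- backdoor_estimate(j, "C", "O", "E")
  # plain conditional p(O | C)
  pco <- apply(j$prob, c(2L, 3L), sum)
  cond <- pco / rowSums(pco)
  expect_equal(as.numeric(est), as.numeric(cond), tolerance = 1e-12)
})

test_that("positivity violations are reported with the offending cell", {
  arr <- array(0, c(2, 2, 2),
               dimnames = list(C = c("0", "1"), E = c("0", "1"),
                               O = c("0", "1")))
  arr["0", "0", "0"] <- 0.5   # E = 0 cells never see C = 1
  arr["1", "1", "1"] <- 0.5
  j <- discrete_joint(arr)
  expect_error(backdoor_estimate(j, "C", "O", "E"), "positivity")
})

test_that("surgery on a parentless exposure equals conditioning", {
  m <- confounded_triple()
  j <- bn_joint(m)
  for (lev in 0:1) {
    truth <- joint_marginal(surgery_truth(m, "E", lev), "O")$prob
    pEO <- apply(j$prob, c(1L, 3L), sum)
    cond <- pEO[lev + 1L, ] / sum(pEO[lev + 1L, ])
    expect_equal(as.numeric(truth), unname(cond), tolerance = 1e-12)
  }
})

test_that("clamping the dominant community silences the antibiotic's direct
          effect within the label's context", {
  # the worked label example: E -> C, E -> O, C -> O with the E -> O edge
  # vanishing when C = 1
  g <- dag(c("E", "C", "O"), rbind(c("E", "C"), c("E", "O"), c("C", "O")))
  m <- ldag(g, c(E = 2L, C = 2L, O = 2L),
            labels = list(list(edge = c("E", "O"),
                               contexts = list(c(C = 1L)))),
            cpts = list(
              E = matrix(c(0.5, 0.5), 1),
              C = rbind(c(0.9, 0.1), c(0.2, 0.8)),
              # (E, C) rows (0,0), (1,0), (0,1), (1,1); C = 1 rows equal
              O = rbind(c(0.95, 0.05), c(0.7, 0.3),
                        c(0.2, 0.8), c(0.2, 0.8))))
  post <- surgery_truth(m, "C", 1)
  # with C clamped to 1 the outcome no longer depends on E
  pEO <- apply(post$prob, c(1L, 3L), sum)
  cond <- pEO / rowSums(pEO)
  expect_equal(unname(cond[1L, ]), unname(cond[2L, ]), tolerance = 1e-12)
})

test_that("backdoor adjustment equals surgery across random discrete
          networks whenever the criterion holds, and rows normalise", {
  set.seed(801)
  checked <- 0L
  for (rep in 1:150) {
    m <- random_bn_fixture(sample(3:5, 1))
    j <- bn_joint(m)
    nodes <- m$dag$nodes
    x <- sample(nodes, 1L)
    z <- dag_parents(m$dag, x)       # parents always satisfy the criterion
    rest <- setdiff(nodes, c(x, z))
    if (!length(rest)) next
    y <- sample(rest, 1L)
    expect_true(satisfies_backdoor(m$dag, x, y, z))
    est <- backdoor_estimate(j, x, y, z)
    expect_equal(unname(rowSums(est)), rep(1, nrow(est)), tolerance = 1e-12)
    for (lev in seq_len(m$card[[x]]) - 1L) {
      truth <- joint_marginal(surgery_truth(m, x, lev), y)$prob
      expect_equal(unname(est[lev + 1L, ]), as.numeric(truth),
                   tolerance = 1e-12)
    }
    checked <- checked + 1L
  }
  expect_gt(checked, 120L)
})

test_that("empirical joints feed the adjustment at finite samples", {
  m <- confounded_triple()
  j <- bn_joint(m)
  x <- sample_joint(j, 2e4, seed = 5)
  je <- empirical_joint(x, c(E = 2L, C = 2L, O = 2L))
  expect_equal(sum(je$prob), 1)
  est <- backdoor_estimate(je, "C", "O", "E")
  truth <- joint_marginal(surgery_truth(m, "C", 1), "O")$prob
  expect_lt(max(abs(est[2L, ] - as.numeric(truth))), 0.03)
  js <- empirical_joint(x[1:5, ], c(E = 2L, C = 2L, O = 2L), smooth = TRUE)
  expect_true(all(js$prob > 0))
})

test_that("joint tables round-trip through TSV", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  j <- bn_joint(confounded_triple())
  write_joint_tsv(j, tmp)
  j2 <- read_joint_tsv(tmp)
  expect_identical(j2$vars, j$vars)
  expect_identical(dimnames(j2$prob), dimnames(j$prob))
  expect_equal(as.numeric(j2$prob), as.numeric(j$prob), tolerance = 1e-12)
})
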