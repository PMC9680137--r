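test_that("scenario specs validate their parameters", {
  expect_error(scenario_spec(n_otus = 2), "at least 3")
  expect_error(scenario_spec(expected_neighbors = 100), "expected_neighbors")
  expect_error(scenario_spec(weight_range = c(-1, 1)), "positive")
  expect_error(scenario_spec(effect = Inf), "finite")
  expect_error(scenario_spec(expected_neighbors = 2.5), "whole-number")
  expect_silent(scenario_spec(expected_neighbors = 2.5, graph_model = "er"))
})

test_that("the regular graph model gives every OTU exactly the configured
          number of neighbours", {
  set.seed(11)
  spec <- scenario_spec()
  g <- random_otu_dag(spec)
  deg <- colSums(g$amat) + rowSums(g$amat)
  expect_true(all(deg == 3))
  expect_length(g$nodes, 100L)
  # degree 3 on 4 nodes forces the complete graph
  g4 <- random_otu_dag(scenario_spec(n_otus = 4))
  expect_equal(sum(g4$amat), 6L)
  # degree 0 gives an empty edge set
  g0 <- random_otu_dag(scenario_spec(expected_neighbors = 0))
  expect_equal(sum(g0$amat), 0L)
})

test_that("the ER graph model hits the expected mean degree", {
  set.seed(12)
  spec <- scenario_spec(graph_model = "er")
  degs <- replicate(200, {
    g <- random_otu_dag(spec)
    mean(colSums(g$amat) + rowSums(g$amat))
  })
  expect_gt(mean(degs), 2.8)
  expect_lt(mean(degs), 3.2)
})

test_that("attach_outcome wires each scenario as designed", {
  set.seed(13)
  for (r in 1:20) {
    sA <- scenario_spec("A", "forward")
    gA <- attach_outcome(random_otu_dag(sA), sA)
    expect_equal(dag_parents(gA, "O"), gA$exposure)
    expect_true(is.na(gA$partner))

    sAr <- scenario_spec("A", "reversed")
    gAr <- attach_outcome(random_otu_dag(sAr), sAr)
    expect_length(dag_parents(gAr, "O"), 0L)
    expect_equal(dag_children(gAr, "O"), gAr$exposure)

    sB <- scenario_spec("B", "forward")
    gB <- attach_outcome(random_otu_dag(sB), sB)
    expect_setequal(dag_parents(gB, "O"), c(gB$exposure, gB$partner))
    expect_true(gB$amat[gB$partner, gB$exposure])  # partner -> exposure

    sC <- scenario_spec("C", "forward")
    gC <- attach_outcome(random_otu_dag(sC), sC)
    expect_setequal(dag_parents(gC, "O"), c(gC$exposure, gC$partner))
    expect_false(gC$amat[gC$partner, gC$exposure] ||
                   gC$amat[gC$exposure, gC$partner])
  }
})

test_that("outcome edges carry the scenario effect and OTU weights stay in
          range", {
  set.seed(14)
  spec <- scenario_spec("C", "forward", effect = 0.75,
                        weight_range = c(0.1, 1))
  g <- attach_outcome(random_otu_dag(spec), spec)
  scm <- make_scm(g, spec)
  w_out <- scm$W[, "O"]
  expect_true(all(w_out[w_out != 0] == 0.75))
  w_otu <- scm$W[g$nodes != "O", g$nodes != "O"]
  w_otu <- w_otu[w_otu != 0]
  expect_true(all(w_otu >= 0.1 & w_otu <= 1))
  expect_true(all(scm$noise == 1))
})

test_that("exact_covariance has closed-form special cases and matches a
          Monte-Carlo estimate", {
  empty <- dag(c("a", "b", "c"))
  s0 <- structure(list(dag = empty,
                       W = matrix(0, 3, 3, dimnames = list(empty$nodes,
                                                           empty$nodes)),
                       noise = c(a = 1, b = 1, c = 1)), class = "lg_scm")
  expect_equal(unname(exact_covariance(s0)), diag(3))
  chain <- dag(c("a", "b"), rbind(c("a", "b")))
  sc <- structure(list(dag = chain,
                       W = matrix(c(0, 0, 0.6, 0),
                                  2, 2, dimnames = list(chain$nodes,
                                                        chain$nodes)),
                       noise = c(a = 1, b = 1)), class = "lg_scm")
  S <- exact_covariance(sc)
  expect_equal(S["b", "b"], 1 + 0.6^2)
  expect_equal(S["a", "b"], 0.6)

  set.seed(15)
  g <- random_dag_fixture(5)
  scm <- random_scm_fixture(g, signed = TRUE)
  Sx <- exact_covariance(scm)
  n <- 1e5
  X <- scm_sample(scm, n)
  Se <- stats::cov(X)
  # 3 standard errors of a covariance entry ~ 3 * sqrt((s_ii s_jj + s_ij^2)/n)
  se <- 3 * sqrt((outer(diag(Sx), diag(Sx)) + Sx^2) / n)
  expect_true(all(abs(Se - Sx) < se))
})

test_that("implied covariance is positive definite and adjacent OTUs are
          positively correlated across random systems", {
  set.seed(16)
  for (r in 1:100) {
    spec <- scenario_spec(sample(c("A", "B", "C"), 1),
                          sample(c("forward", "reversed"), 1), n_otus = 30)
    g <- attach_outcome(random_otu_dag(spec), spec)
    scm <- make_scm(g, spec)
    S <- exact_covariance(scm)
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
    idx <- which(g$amat, arr.ind = TRUE)
    expect_true(all(S[idx] > 0))
  }
})

test_that("sampling is reproducible under a fixed seed and matches the
          adjustment oracle at scale", {
  set.seed(17)
  spec <- scenario_spec("A", "forward")
  scm <- make_scm(attach_outcome(random_otu_dag(spec), spec), spec)
  x1 <- scm_sample(scm, 50, seed = 99)
  x2 <- scm_sample(scm, 50, seed = 99)
  expect_identical(x1, x2)
  expect_error(scm_sample(scm, 0), "positive")
  # regression of O on the exposure adjusted for the exposure's parents
  # recovers the structural effect 0.75
  X <- scm_sample(scm, 1e5, seed = 100)
  pa <- dag_parents(scm$dag, scm$exposure)
  v <- c(scm$exposure, pa)
  S <- stats::cov(X)
  b <- solve(S[v, v, drop = FALSE], S[v, "O"])
  expect_lt(abs(b[[1L]] - 0.75), 0.02)
})

test_that("true_effect traces directed paths", {
  g <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  W <- matrix(0, 3, 3, dimnames = list(g$nodes, g$nodes))
  W["a", "b"] <- 0.5; W["b", "c"] <- 0.4; W["a", "c"] <- 0.3
  scm <- structure(list(dag = g, W = W, noise = c(a = 1, b = 1, c = 1)),
                   class = "lg_scm")
  expect_equal(true_effect(scm, "a", "c"), 0.5 * 0.4 + 0.3)
  expect_equal(true_effect(scm, "c", "a"), 0)
  set.seed(18)
  for (r in 1:20) {
    spec <- scenario_spec(sample(c("A", "B", "C"), 1), "forward",
                          n_otus = 20)
    scm <- make_scm(attach_outcome(random_otu_dag(spec), spec), spec)
    expect_equal(true_effect(scm, scm$exposure, "O"), 0.75)
    specr <- spec; specr$direction <- "reversed"
    scmr <- make_scm(attach_outcome(random_otu_dag(specr), specr), specr)
    expect_equal(true_effect(scmr, scmr$exposure, "O"), 0)
  }
})

test_that("abundance tables and scenario specs round-trip through disk", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  set.seed(19)
  spec <- scenario_spec("A", "forward", n_otus = 6)
  scm <- make_scm(attach_outcome(random_otu_dag(spec), spec), spec)
  x <- scm_sample(scm, 20)
  write_abundance_tsv(x, tmp)
  x2 <- read_abundance_tsv(tmp)
  expect_equal(colnames(x2), colnames(x))
  expect_equal(unname(x2), unname(x), tolerance = 1e-12)
  tmp2 <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_yaml(spec, tmp2)
  spec2 <- read_scenario_yaml(tmp2)
  expect_equal(spec2, spec)
})
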