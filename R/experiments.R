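#' Seed stream-splitting
#'
#' All experiment harnesses follow one seed contract: the master seed seeds
#' R's RNG once, from which one sub-seed per replicate (or per grid cell) is
#' drawn up front with `sample.int`. Each replicate then calls
#' `set.seed(its sub-seed)` before its first random draw, so every replicate
#' is reproducible in isolation and results do not depend on execution
#' order.
#'
#' @param master integer master seed.
#' @param n number of sub-seeds required.
#' @return integer vector of `n` sub-seeds.
#' @export
split_seed <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Oracle discovery-rate limits
#'
#' Estimates the theoretical upper limit of the IDA discovery rate for one
#' scenario: for each replicate a random OTU system is generated, and
#' [oracle_ida()] — local IDA on the true CPDAG with the exact model
#' covariance, i.e. the infinite-sample limit — is asked whether the
#' minimum-absolute-value effect of the exposure on the outcome is non-zero.
#' No finite data and no CI tests are involved; the rate is a property of
#' the random structures alone.
#'
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param replicates number of random systems.
#' @param seed master seed (see [split_seed()]).
#' @param spec optionally a full [scenario_spec()]; its `scenario` and
#'   `direction` are overridden by `scenario`/forward.
#' @return list with `rate` (fraction of replicates with a non-zero oracle
#'   estimate), `replicates`, and `ledger` (one row per replicate: seed,
#'   exposure, min_abs, nonzero, true_effect).
#' @export
oracle_limits <- function(scenario = c("A", "B", "C"), replicates = 1000L,
                          seed = 1L, spec = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(spec)) spec <- scenario_spec(scenario, "forward")
  spec$scenario <- scenario
  spec$direction <- "forward"
  seeds <- split_seed(seed, replicates)
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    set.seed(seeds[r])
    g <- attach_outcome(random_otu_dag(spec), spec)
    scm <- make_scm(g, spec)
    res <- oracle_ida(scm, scm$exposure, "O")
    rows[[r]] <- data.frame(
      replicate = r, seed = seeds[r], scenario = scenario,
      exposure = scm$exposure, min_abs = res$min_abs,
      nonzero = res$nonzero,
      true_effect = true_effect(scm, scm$exposure, "O"))
  }
  ledger <- do.call(rbind, rows)
  list(rate = mean(ledger$nonzero), replicates = replicates, ledger = ledger)
}

#' Configuration of the continuous-system study
#'
#' @param scenarios subset of `c("A", "B", "C")`.
#' @param directions subset of `c("forward", "reversed")`.
#' @param n_grid sample sizes.
#' @param replicates random systems per grid cell.
#' @param alpha PC significance level.
#' @param v_structure collider decision rule passed to [pc()].
#' @param seed master seed.
#' @param oracle also run the infinite-sample oracle per replicate.
#' @param spec base [scenario_spec()] carrying the generator settings.
#' @return a list of class `"effect_study_config"`.
#' @export
effect_study_config <- function(scenarios = c("A", "B", "C"),
                                directions = c("forward", "reversed"),
                                n_grid = c(100L, 200L, 400L, 800L, 1600L),
                                replicates = 1000L,
                                alpha = 0.01,
                                v_structure = c("majority", "sepset"),
                                seed = 1L,
                                oracle = TRUE,
                                spec = scenario_spec()) {
  v_structure <- match.arg(v_structure)
  stopifnot(all(scenarios %in% c("A", "B", "C")),
            all(directions %in% c("forward", "reversed")),
            length(n_grid) >= 1L, replicates >= 1L,
            alpha > 0, alpha < 1)
  structure(list(scenarios = scenarios, directions = directions,
                 n_grid = as.integer(n_grid),
                 replicates = as.integer(replicates), alpha = alpha,
                 v_structure = v_structure,
                 seed = as.integer(seed), oracle = oracle, spec = spec),
            class = "effect_study_config")
}

#' Read an experiment configuration from YAML
#'
#' Top-level key `study: effect` or `study: community`; remaining keys match
#' the arguments of [effect_study_config()] or [community_study_config()].
#'
#' @param path YAML file.
#' @return an `"effect_study_config"` or `"community_study_config"`.
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  study <- match.arg(x$study, c("effect", "community"))
  x$study <- NULL
  if (study == "effect") {
    if (!is.null(x$spec)) x$spec <- do.call(scenario_spec, x$spec)
    do.call(effect_study_config, x)
  } else {
    do.call(community_study_config, x)
  }
}

#' Run the continuous-system discovery study
#'
#' For every (scenario, direction, n) cell and replicate: generate a random
#' OTU system, draw `n` observations, learn the CPDAG with stable PC at the
#' configured `alpha`, run local IDA for the (exposure, outcome) pair, and
#' record the minimum-absolute-value estimate; optionally also the
#' per-replicate infinite-sample oracle. Replicates whose estimation fails
#' (e.g. a singular regression at small n) are recorded and excluded from
#' rate denominators.
#'
#' @param config an [effect_study_config()].
#' @param out_dir optional directory; if given, `ledger.csv`, `summary.csv`
#'   and `run-metadata.json` are written there.
#' @param progress print per-cell progress to stderr.
#' @return list with `ledger` (one row per replicate) and `summary` (one row
#'   per cell: discovery rate, failure count, quartiles of the non-zero
#'   estimates, and the oracle rate when enabled).
#' @export
run_effect_study <- function(config, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "effect_study_config"))
  cells <- expand.grid(scenario = config$scenarios,
                       direction = config$directions,
                       n = config$n_grid, stringsAsFactors = FALSE)
  cell_seeds <- split_seed(config$seed, nrow(cells))
  ledgers <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    sc <- cells$scenario[ci]; dir <- cells$direction[ci]; n <- cells$n[ci]
    if (progress)
      message(sprintf("cell %d/%d: scenario %s %s n=%d",
                      ci, nrow(cells), sc, dir, n))
    spec <- config$spec
    spec$scenario <- sc
    spec$direction <- dir
    seeds <- split_seed(cell_seeds[ci], config$replicates)
    rows <- vector("list", config$replicates)
    for (r in seq_len(config$replicates)) {
      set.seed(seeds[r])
      row <- data.frame(scenario = sc, direction = dir, n = n,
                        replicate = r, seed = seeds[r],
                        alpha = config$alpha,
                        v_structure = config$v_structure,
                        min_abs = NA_real_, nonzero = NA,
                        oracle_nonzero = NA, true_effect = NA_real_,
                        failed = FALSE, error = "")
      res <- tryCatch({
        g <- attach_outcome(random_otu_dag(spec), spec)
        scm <- make_scm(g, spec)
        x <- scm_sample(scm, n)
        cp <- pc(x, alpha = config$alpha, v_structure = config$v_structure)
        est <- ida_local(cp, x = x, exposure = scm$exposure, outcome = "O")
        row$min_abs <- est$min_abs
        row$nonzero <- est$nonzero
        row$true_effect <- true_effect(scm, scm$exposure, "O")
        if (config$oracle)
          row$oracle_nonzero <- oracle_ida(scm, scm$exposure, "O")$nonzero
        row
      }, error = function(e) {
        row$failed <- TRUE
        row$error <- conditionMessage(e)
        row
      })
      rows[[r]] <- res
    }
    ledgers[[ci]] <- do.call(rbind, rows)
  }
  ledger <- do.call(rbind, ledgers)
  summary <- summarise_effect_ledger(ledger)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ledger, file.path(out_dir, "ledger.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    meta <- list(study = "effect", seed = config$seed,
                 replicates = config$replicates, alpha = config$alpha,
                 v_structure = config$v_structure,
                 n_grid = config$n_grid, scenarios = config$scenarios,
                 directions = config$directions,
                 r_version = as.character(getRversion()),
                 timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(meta, file.path(out_dir, "run-metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(ledger = ledger, summary = summary)
}

#' Recompute the per-cell summary from an effect-study ledger
#'
#' Kept separate so summaries can always be re-derived from the raw ledger
#' (no hidden state).
#'
#' @param ledger the per-replicate data frame from [run_effect_study()].
#' @return one row per (scenario, direction, n) cell.
#' @export
summarise_effect_ledger <- function(ledger) {
  cells <- unique(ledger[, c("scenario", "direction", "n")])
  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    sel <- ledger$scenario == cells$scenario[ci] &
      ledger$direction == cells$direction[ci] & ledger$n == cells$n[ci]
    d <- ledger[sel, ]
    ok <- !d$failed
    nz <- d$nonzero[ok]
    q <- if (any(nz)) stats::quantile(d$min_abs[ok][nz],
                                      c(0.25, 0.5, 0.75), names = FALSE)
    else rep(NA_real_, 3L)
    data.frame(scenario = cells$scenario[ci],
               direction = cells$direction[ci], n = cells$n[ci],
               replicates = nrow(d), failures = sum(d$failed),
               discovery_rate = mean(nz),
               oracle_rate = if (all(is.na(d$oracle_nonzero))) NA_real_
               else mean(d$oracle_nonzero[ok]),
               q25 = q[1L], q50 = q[2L], q75 = q[3L])
  })
  do.call(rbind, rows)
}

#' Configuration of the community-model study
#'
#' @param alpha_grid coexistence strengths.
#' @param rr_grid risk ratios.
#' @param n_grid sample sizes.
#' @param replicates datasets per cell.
#' @param baseline baseline disease probability.
#' @param ess equivalent sample size of the structure score's prior.
#' @param seed master seed.
#' @return a list of class `"community_study_config"`.
#' @export
community_study_config <- function(alpha_grid = c(1, 2, 4),
                                   rr_grid = c(2, 5, 10),
                                   n_grid = c(250L, 500L, 1000L, 2000L, 4000L),
                                   replicates = 1000L,
                                   baseline = 0.05,
                                   ess = 1,
                                   seed = 1L) {
  stopifnot(length(alpha_grid) >= 1L, length(rr_grid) >= 1L,
            length(n_grid) >= 1L, replicates >= 1L, ess > 0)
  structure(list(alpha_grid = alpha_grid, rr_grid = rr_grid,
                 n_grid = as.integer(n_grid),
                 replicates = as.integer(replicates),
                 baseline = baseline, ess = ess, seed = as.integer(seed)),
            class = "community_study_config")
}

#' Run the community-model discovery study
#'
#' For every (alpha, rr, n) cell and replicate: draw a community dataset,
#' learn the best-scoring equivalence class under both the plain-DAG and the
#' LDAG model class, and record whether each recovered the joint mechanism
#' `C1 -> O <- C2` (every class member must contain both edges; ties count
#' as failures).
#'
#' @param config a [community_study_config()].
#' @param out_dir optional output directory (ledger.csv, summary.csv,
#'   run-metadata.json).
#' @param progress print per-cell progress to stderr.
#' @return list with `ledger` and `summary` (per-cell discovery rates of
#'   both model classes).
#' @export
run_community_study <- function(config, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "community_study_config"))
  cells <- expand.grid(alpha = config$alpha_grid, rr = config$rr_grid,
                       n = config$n_grid, stringsAsFactors = FALSE)
  cell_seeds <- split_seed(config$seed, nrow(cells))
  ledgers <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    al <- cells$alpha[ci]; rr <- cells$rr[ci]; n <- cells$n[ci]
    if (progress)
      message(sprintf("cell %d/%d: alpha=%g rr=%g n=%d",
                      ci, nrow(cells), al, rr, n))
    spec <- community_spec(alpha = al, rr = rr, baseline = config$baseline,
                           n = n)
    seeds <- split_seed(cell_seeds[ci], config$replicates)
    rows <- vector("list", config$replicates)
    for (r in seq_len(config$replicates)) {
      x <- sample_community(spec, seed = seeds[r])
      cnt <- counts_array(x, c("C1", "C2", "O"), c(C1 = 2L, C2 = 2L, O = 2L))
      dag_cls <- learn_structure(cnt, "dag", ess = config$ess)
      ldag_cls <- learn_structure(cnt, "ldag", ess = config$ess)
      rows[[r]] <- data.frame(
        alpha = al, rr = rr, n = n, replicate = r, seed = seeds[r],
        ess = config$ess,
        dag_correct = is_correct_discovery(dag_cls),
        ldag_correct = is_correct_discovery(ldag_cls))
    }
    ledgers[[ci]] <- do.call(rbind, rows)
  }
  ledger <- do.call(rbind, ledgers)
  summary <- summarise_community_ledger(ledger)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ledger, file.path(out_dir, "ledger.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    meta <- list(study = "community", seed = config$seed,
                 replicates = config$replicates, ess = config$ess,
                 baseline = config$baseline,
                 alpha_grid = config$alpha_grid, rr_grid = config$rr_grid,
                 n_grid = config$n_grid,
                 r_version = as.character(getRversion()),
                 timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(meta, file.path(out_dir, "run-metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(ledger = ledger, summary = summary)
}

#' Recompute the per-cell summary from a community-study ledger
#' @param ledger the per-replicate data frame from [run_community_study()].
#' @return one row per (alpha, rr, n) cell with both discovery rates.
#' @export
summarise_community_ledger <- function(ledger) {
  cells <- unique(ledger[, c("alpha", "rr", "n")])
  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    sel <- ledger$alpha == cells$alpha[ci] & ledger$rr == cells$rr[ci] &
      ledger$n == cells$n[ci]
    d <- ledger[sel, ]
    data.frame(alpha = cells$alpha[ci], rr = cells$rr[ci], n = cells$n[ci],
               replicates = nrow(d),
               dag_rate = mean(d$dag_correct),
               ldag_rate = mean(d$ldag_correct))
  })
  do.call(rbind, rows)
}
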