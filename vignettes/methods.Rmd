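---
title: "Causal discovery benchmarks for cross-sectional microbiome data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal discovery benchmarks for cross-sectional microbiome data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microcausal)
```

# The problem

Cross-sectional metagenomic studies routinely find taxa whose abundances
are associated with a disease or phenotype, but association cannot say
whether the community produced the outcome or the outcome selected for the
community. `microcausal` implements two simulation benchmarks that quantify
what graphical causal discovery can — and provably cannot — recover from
observational microbiome data:

1. **A continuous, high-dimensional benchmark.** One hundred OTU abundance
   variables (think log-transformed, normalised titres) follow a random
   linear-Gaussian structural causal model; a continuous outcome is wired to
   the community under three scenarios and in two causal directions. The PC
   algorithm learns the Markov equivalence class (CPDAG) and the IDA
   estimator turns it into a multiset of possible causal effects of a chosen
   exposure OTU on the outcome, summarised by its minimum absolute value.
   An *oracle* variant replaces all statistics with exact population
   quantities, giving the theoretical ceiling on the discovery rate that no
   amount of data can beat.
2. **A discrete community-effect benchmark.** Two binary OTUs that tend to
   co-occur jointly cause a disease, but the risk is raised only when both
   are present. Plain DAGs provably cannot orient this mechanism; labelled
   DAGs (LDAGs), which encode context-specific independence, can. The
   package scores both model classes exhaustively with a Dirichlet-
   multinomial marginal likelihood and measures how often each recovers the
   mechanism.

A small third module implements exact backdoor adjustment for discrete
systems, with an interventional ground truth computed by graph surgery, so
the adjustment identity that justifies all of the above can be verified
mechanically.

# The continuous benchmark

## The generating model

An OTU system is drawn in three steps.

* **Coexistence graph.** Each OTU has exactly `expected_neighbors` (default
  3) neighbours: the undirected graph is a uniformly random simple
  3-regular graph. We read "the number of neighbours of an OTU" literally
  as a degree-regular ensemble; it is the reading under which the oracle
  discovery ceilings the benchmark is calibrated against (52.6% in
  scenario A, 83.6% in scenario B) are reproduced, as the acceptance tests
  verify. An Erdős–Rényi ensemble with the same *expected* degree is
  available via `graph_model = "er"`. Edges are oriented along a uniformly
  random topological order.
* **Outcome wiring.** Scenario A links a uniformly chosen exposure OTU
  directly to the outcome `O`. Scenario B picks a uniformly random
  *existing* directed OTU edge `C -> C*` and makes both ends parents of
  `O`; the community partner being a parent of the exposure creates the
  open backdoor path `C* <- C -> O` that makes this scenario hard.
  Scenario C picks a uniformly random non-adjacent pair, so `C* -> O <- C`
  is a v-structure — the one configuration observational data can always
  orient. In scenario C the exposure is taken to be the pair member that is
  not an ancestor of the other, so the total causal effect stays exactly at
  the structural coefficient. Under `direction = "reversed"` the same edges
  point from `O` into the community and the true effect is exactly 0.
* **Structural equations.** Every variable is a weighted sum of its parents
  plus unit-variance Gaussian noise. Edges incident to `O` carry the effect
  0.75; OTU–OTU weights are uniform on `weight_range` — positive, so
  adjacent OTUs are positively correlated (symbiosis). The range is a
  tunable the data do not pin down; see *Numerical choices* below.

`exact_covariance()` gives the implied covariance in closed form,
`true_effect()` the path-tracing total effect, and `scm_sample()` draws
subject-by-variable abundance tables.

What the generator deliberately does *not* emulate: compositional closure
(relative abundances summing to one), zero inflation, sequencing noise, or
negative (antagonistic) interactions. Passing benchmarks here therefore
show what the estimators do when their multivariate-normal assumptions
hold, not how they behave on raw relative-abundance data; that idealisation
is the point of the exercise.

## Structure learning and effect estimation

`pc()` implements the stable-variant PC algorithm: the skeleton phase
freezes adjacency sets at the start of each conditioning-set size, making
the learned skeleton independent of column order; conditional independence
is decided by the Fisher-z partial-correlation test at level `alpha`
(default 0.01). Unshielded triples are decided by the majority rule by
default: all separating subsets of the two endpoints' adjacency sets are
re-examined and the triple becomes a collider only when the middle node
appears in fewer than half of them, ambiguous triples staying undirected.
The classic single-sepset rule is available as `v_structure = "sepset"`;
it is faster but orients on the evidence of one test, and a single spurious
separating set then manufactures a collider. The majority rule is the
default because the benchmark's calibrated behaviours — near-certain
discovery in the v-structure scenario at moderate samples with low
false-positive rates in the reversed direction, properties the test suite
asserts — hold under it, and are not guaranteed under the single-sepset
rule. Conflicting arrowheads
cancel and the edge stays undirected (conservative and order-independent);
Meek's orientation rules are then applied to closure. Rules 1–3 are
implemented; rule 4 cannot fire when every initial orientation comes from a
v-structure, which is the only source of orientations here. `pc_oracle()`
runs the same machinery with d-separation in a known DAG as the test
(where the two collider rules coincide), and equals `cpdag_of()` exactly —
a property the test suite checks on a thousand random graphs.

`ida_local()` is the local IDA estimator: for every subset `S` of the
exposure's undirected neighbours whose promotion to parents creates no new
collider at the exposure, it returns the regression coefficient of the
exposure in the regression of the outcome on the exposure, its directed
parents, and `S`. A configuration in which the outcome itself acts as a
parent contributes an *exact structural zero* — zeros never arise from
thresholding. The minimum absolute value over the multiset is the reported
lower bound, and a replicate counts as a discovery when it is non-zero.
`oracle_ida()` evaluates the same estimator on the true CPDAG with the
exact covariance: the infinite-sample limit.

## What the oracle ceilings mean

In scenario A the exposure–outcome edge is compelled precisely when the
exposure has a compelled incoming OTU edge, so even infinite data discover
the effect in only ~52% of random systems. Scenario B's forced community
edge supplies extra v-structures and lifts the ceiling to ~84%. Scenario
C's v-structure is always compelled: the ceiling is exactly 1. These
quantities depend only on graph structure, not on weights or noise, and
`oracle_limits()` recomputes them by brute enumeration over random systems.

## Finite-sample behaviour and its artifacts

At finite n the pipeline both misses discoveries (power) and manufactures
spurious ones: a weakly weighted true edge `u -> C*` can be detected as an
adjacency while the induced correlation between `u` and another neighbour
of `C*` stays below detection, so the pair is "separated" by the empty set
and the triple is falsely compelled into a collider at `C*`. False
compelled edges inflate the discovery rate above the oracle ceiling in the
forward direction and create false positives in the reversed direction.
This is a known property of sepset-based PC at a fixed test level, not an
implementation choice; it is why the reversed-direction false-positive
rates reported by `run_effect_study()` are low but not negligible, and why
the weight range matters (see below).

# The community-effect benchmark

## The generating model

`community_joint()` builds the joint law of `(C1, C2, O)`:
`P(C1 = c1, C2 = c2) ∝ exp(alpha · 1[c1 = c2])` and
`P(O = 1 | c1, c2) = rr · baseline` when both OTUs are present, `baseline`
(default 0.05) otherwise. The symmetric log-linear coexistence law is the
simplest form reproducing the model's two stated limits: independent
uniform OTUs at `alpha = 0`, and a deterministic single binary cause as
`alpha → ∞` (which destroys identifiability, since `C -> O` and `C <- O`
are then Markov equivalent). The ground-truth structure is the LDAG
returned by `community_ldag()`: `C1 -> C2`, both OTUs parents of `O`, and
a label on each OTU→outcome edge saying its effect vanishes when the other
OTU is absent.

## Scoring and structure learning

`ldag_marginal_likelihood()` scores a structure by the product over nodes
of Dirichlet-multinomial marginal likelihoods in which the parent
configurations merged by a label share one parameter row. Hyperparameters
follow the BDeu convention with equivalent sample size `ess` (default 1):
`ess / (q · r)` per cell of the unmerged table, a merged row inheriting the
sum of what it absorbs. With no labels this is exactly the standard BDeu
score — Markov-equivalent plain DAGs score identically — and a fully
labelled edge scores exactly like the graph without the edge.

`learn_structure()` enumerates all 25 DAGs over the three variables; under
`model_class = "ldag"` it adds every admissible labelling of edges whose
child has two parents (labels are non-empty proper subsets of the
co-parent's states). Candidates are grouped into statistical-equivalence
classes by their induced set of conditional *and* context-specific
independence statements, the latter checked by d-separation in the
label-reduced graph of each context. The class of the top-scoring candidate
is returned; a top class tied with a distinct runner-up within `1e-9` log
units is flagged ambiguous. `is_correct_discovery()` accepts only an
unambiguous class in which *every* member contains both `C1 -> O` and
`C2 -> O` — the strictest reading of "the class contains the mechanism".

The plain-DAG class can never satisfy this on community data: the OTUs'
marginal dependence forces the `C1–C2` adjacency into the skeleton, and the
resulting triangle class always contains members without the collider. The
LDAG class can, because the two labels break the tie; its success rate
rises with `n` and `rr` and falls with `alpha`.

## The coexistence grid

The benchmark grid defaults to `alpha ∈ {1, 2, 4}`, `rr ∈ {2, 5, 10}`,
`n ∈ {250, 500, 1000, 2000, 4000}`. `alpha = 0` is excluded deliberately:
there the OTUs are marginally independent, the truth degenerates to a plain
collider, and even the DAG class discovers it — contradicting the model's
own premise that the OTUs co-occur. The grid spans weak-to-near-
deterministic coexistence instead.

## The orientation deduction from a label

`csi_orient()` packages the qualitative argument that makes LDAGs more than
a scoring trick. Given prior knowledge `E -> C` and `E -> O` (a treatment
that is a direct cause of both a community state and an outcome), plain
Markov-equivalence reasoning cannot orient a remaining `C – O` adjacency.
But if the data exhibit the context-specific independence "`O` is
independent of `E` once `C = 1`", then `C` modulates the `E`–`O`
dependence, which only a cause of `E` or of `O` can do; since `C` is known
to be an *effect* of `E`, it must be a cause of `O`. With no such statement
the function honestly returns `"unknown"`.

# Backdoor adjustment

`backdoor_estimate()` computes `p(outcome | do(exposure)) =
Σ_z p(outcome | exposure, z) p(z)` from a joint table alone, refusing on
positivity violations and naming the empty cell. `surgery_truth()` computes
the same quantity by definition — sever the exposure's incoming edges,
clamp, re-multiply the conditional tables — and the two agree to 1e-12
whenever `satisfies_backdoor()` holds, a property the suite checks across
hundreds of random discrete networks. Finite-sample use goes through
`empirical_joint()` (plug-in frequencies, optional add-half smoothing, off
by default).

# Numerical choices and conventions

* **Node identity and order.** Nodes are strings; declaration order drives
  all deterministic iteration and matrix coordinates.
* **Seed contract.** Every harness seeds R's RNG once with the master seed
  and draws one sub-seed per replicate (and per grid cell) up front via
  `split_seed()`; each replicate re-seeds from its own sub-seed, so any
  replicate can be reproduced in isolation and results are independent of
  execution order.
* **PC test level.** `alpha = 0.01` by default; the benchmark's source does
  not state one, and the value is logged in every result ledger. Smaller
  levels trade discoveries at n = 400 for fewer false compelled edges at
  n = 1600.
* **Edge-weight range.** Uniform on [0.1, 1] by default, the convention of
  the random-DAG utilities this benchmark family descends from. The range
  is configurable, but moving it is no free lunch in either direction:
  weak weights leave some length-two correlations below the detection
  threshold (false colliders by missed dependence), while strong weights
  densify the correlation structure so that separating-set searches try
  more subsets and stumble on spurious ones (false colliders by multiple
  testing).
* **Zeros are structural.** An IDA estimate is zero only when the outcome
  enters the exposure's parent configuration; no epsilon thresholding
  anywhere.
* **Conflicting v-structures** cancel and stay undirected rather than
  overwrite; this is conservative and order-independent.
* **Degenerate inputs.** Scenario B requires at least one OTU edge and
  scenario C a non-adjacent pair; impossible draws raise errors that the
  experiment harnesses record as per-replicate failures, excluded from
  rate denominators and counted in the summaries.
* **Tie-breaking in structure learning** is conservative: tied top classes
  are never counted as discoveries.
* **Capacity guards.** Equivalence-class enumeration is exhaustive and
  capped at 15 undirected edges; LDAG learning is exhaustive and restricted
  to 3 variables by design — there is no heuristic search.

# Problem sizes used by the shipped tests

The test suite and the acceptance script run the full 100-OTU systems but
scale replicate counts to desk size: 1000 replicates for the oracle
ceilings (binomial SE ≈ 1.6 points), 300 for the finite-sample scenario-A
rates at n = 400 and 1600, 200 per grid cell for the DAG-nullity check,
and 300 per point for the LDAG monotonicity checks, with two-binomial-SE
slack on all stochastic comparisons. Property-style identities (oracle PC
vs CPDAG computation, local vs global IDA, adjustment vs surgery, score
equivalence) run on thousands of small random instances where the answer
is exact.

# Known limitations

* The abundance model is multivariate normal by construction; nothing here
  validates the estimators under compositionality, zero inflation or
  library-size variation.
* Plain PC with sepset orientation retains a finite-sample false-collider
  rate at any fixed `alpha`; conservative or majority-rule orientation
  variants would trade power for calibration and are out of scope.
* LDAG learning beyond three variables, latent-confounder machinery, and
  time-indexed extensions are out of scope by design.
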