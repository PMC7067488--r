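---
title: "Anchored Bayesian networks versus Mendelian randomization: models, design choices, and what the simulations show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored Bayesian networks versus Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorbn)
```

## The problem

Given individual-level data on two or more phenotypes and genetic variants
associated with them, which causal directions are supported? Two families of
answers are compared throughout this package:

* **Mendelian randomization (MR)**: treat a genetic variant (or a weighted
  allele score) as an instrumental variable for one phenotype and estimate
  its causal effect on another by two-stage least squares (2SLS), optionally
  gated by a Steiger directionality test that first asks which trait the
  variant actually instruments.
* **Bayesian-network structure learning (BN)**: score directed acyclic
  graphs over all measured variables with a decomposable BIC and search for
  the best-fitting structure, with genetic variables constrained to act as
  *directional anchors* (edges may leave them, never enter them). Bootstrap
  model averaging turns the search into edge-existence probabilities
  ("strengths") and direction probabilities.

Both approaches rest on assumptions that the simulation studies deliberately
violate: hidden non-genetic confounding, hidden genetic confounding
(horizontal pleiotropy), and dense pleiotropic SNP effects.

## Synthetic data: what the generators emulate

### Quantitative traits (`simulate_study1`)

Three linear structural models over a SNP G (coded 0/1/2, Hardy-Weinberg
at `maf_g`), a continuous instrument Z, and phenotypes X and Y; every
equation has residual SD 1:

* model 1, no confounding: `X = b_GX G + e`, `Y = b_XY X + b_ZY Z + e`;
* model 2 adds a shared confounder C (`C -> X`, `C -> Y`);
* model 3 adds a second phenotype S on `G -> S -> Y`, so G is pleiotropic.

Defaults follow the study design: n = 2500, `b_GX = 0.1`, `b_ZY = 0.075`,
confounding coefficients 0.25 ("weak") or 0.5 ("strong"), effect
`b_XY` in 0 to 0.5, with a `y_to_x` mode that swaps the structural roles of
X and Y for wrong-direction null simulations. The generating laws of G, Z,
C and S are not pinned down by the study design beyond "SNP-like" and
"continuous"; this package's choices - HWE binomial with `maf_g = 0.3`
default, standard normal Z and C, `S ~ N(b_GS G, 1)` - are configurable and
documented here precisely because they are choices.

### Binary traits (`simulate_study2`)

Four binary variables on `Q -> W -> H -> Y` (with `Q -> H`, `Q -> Y`,
`W -> Y`, `H -> Y`), n = 5000, four scenario presets A-D. The scenario
tables give regression coefficients, some negative, so an
additive-probability reading is infeasible; a **logistic link** is used for
every conditional (`P(W=1|Q) = plogis(delta_0 + delta_q Q)` and so on).
This is the one place where the upstream description is genuinely
ambiguous, and the choice materially affects one printed quantity (see
"Known limitations").

### Pleiotropic design (`simulate_study3`)

10,000 SNPs (MAF uniform on 0.01-0.5, HWE), 12 metabolites, one outcome Y:
150 SNPs carry metabolite effects, 75 distinct SNPs affect Y directly, and
9775 are null. Four metabolites are causal on Y (coefficient 0.3), four
receive a reverse effect from Y (0.3), four are null; all residual SDs
are 1. Real GWAS coefficient tables are external data, so
`generate_snp_effects` builds a synthetic stand-in: each SNP has one
primary metabolite (cyclic assignment guarantees coverage) plus extra
targets with probability `sparsity = 0.1`, and per-allele magnitudes are
`|N(0.3, 0.1)|` in allele-SD units, sized so that instruments are reliably
re-discoverable at the p < 5e-6 selection threshold at n = 1000. The
outcome-SNP coefficients are drawn from the same law (standing in for
coefficients that were, upstream, borrowed from a discarded metabolite).

What the generators do **not** emulate: linkage disequilibrium between
SNPs (instruments are independent by design), family/twin structure,
measurement error, and real metabolite correlation structure. Passing
tests therefore demonstrate correctness of the machinery and
reproduction of the simulated phenomena, not performance on real cohort
data.

## MR engines

`fit_2sls` runs both flavours of 2SLS. The point estimate is the same in
both; the modes differ only in the residual variance behind the standard
error: the corrected mode (the `ivreg` convention) uses residuals of the
outcome against the fitted structural equation evaluated at the *observed*
exposure; the uncorrected mode ("MR prime") uses the naive second-stage
residuals. For a single instrument the uncorrected p-value is
algebraically identical to that from regressing the outcome directly on
the instrument - an identity the test suite checks to 1e-12. p-values use
a t distribution with n - 2 degrees of freedom.

`steiger_direction_test` compares the two instrument-trait correlations
with Steiger's (1980) Z-bar test for dependent correlations sharing one
variable, computed on **correlation magnitudes**: allele coding makes the
sign of a genetic association arbitrary, and instrument suitability is a
question of explained variance. (An early signed version of this test
validated the outcome's instrument for the exposure in about 1.5% of
replicates purely through sign flips; the magnitude form brings that to
0/1000, matching the expected behaviour.) `mr_steiger` gates a standard
2SLS run on first-stage association and direction, both at the same
threshold by default; a failed gate returns a flagged non-detection with
sentinel p-value 1, never an exception, so replicate loops stay alive.

`build_allele_score` rebuilds weighted allele scores within each
replicate: marginal regressions of the target on each SNP, selection at
p < 5e-6, weights equal to the estimated coefficients. An empty selection
is a flagged invalid score.

## Network scoring, search, and averaging

Local scores are BIC on the "higher is better" scale,
`loglik - (d/2) log n`. Gaussian nodes use the MLE residual variance
(divisor n) from the regression on their parents, with d = #parents + 2
(intercept, slopes, variance); the conditional variance is computed from
centered cross-products through an eigenvalue pseudo-inverse so that
exactly collinear parents (e.g. duplicated bootstrap columns) only pay
the extra penalty, and a variance floor of 1e-12 guards degenerate
columns. Multinomial nodes use parent-configuration counts with
d = (levels - 1) x prod(parent levels); empty configurations contribute
zero. Networks are homogeneous (all-Gaussian or all-multinomial): the
quantitative studies score every variable, including the SNP, as
Gaussian; the binary study scores everything as multinomial. Mixed
networks are out of scope.

`hill_climb` is plain greedy search from the whitelist-only graph over
single-edge additions, deletions and reversals, respecting acyclicity,
the blacklist, and whitelist protection, with local-score caching. Two
numerical design points deserve emphasis:

* **Exact ties.** Within a Markov equivalence class the two orientations
  of an edge have *identical* scores; in floating point they tie exactly
  in roughly 40% of bootstrap resamples. A fixed lexicographic tie-break
  funnels all of these into one orientation and biases bootstrap
  direction probabilities to ~0.7 where the data contain no directional
  information. Single fits therefore default to the deterministic
  lexicographic rule (reproducibility), but `bootstrap_average` resolves
  exact ties uniformly at random from the replicate's seeded RNG stream,
  so equivalence-class direction probabilities estimate their true value,
  1/2. Everything remains bit-reproducible given the seed.
* **Local optima.** Greedy search can terminate in genuine local optima:
  on random 4-node linear-SEM fixtures about one dataset in ten needs a
  coordinated multi-edge rearrangement that no single improving move can
  start. `restarts = k` climbs additionally from k random
  constraint-respecting DAGs; with 10 restarts the exhaustive optimum is
  recovered on 100/100 fixture datasets. `exhaustive_search` (limited to
  5 nodes; 543 DAGs at 4 nodes) is the oracle for that check.

Anchors are expressed as constraints: `no_incoming` for genetic
variables, `no_children` for outcomes known to be terminal, and
`single_outgoing` for allele-score nodes, which must have exactly their
one edge into the instrumented variable.

`bootstrap_average` draws B = 1000 nonparametric resamples (replicate b
is seeded `seed + b`, so replicates are order-invariant and could run
concurrently; degenerate resamples with a constant column are redrawn
under a derived sub-seed and counted). Edge strength is the fraction of
best-fit networks containing the pair in either orientation; the
direction probability conditions on existence. `edge_strength_threshold`
implements the L1 criterion for "sufficiently strong" edges: the
inclusion cut minimizes the L1 distance between the empirical CDF of the
observed strengths and the ideal degenerate CDF in which every edge has
strength 0 or 1, by brute-force search over observed values.

## Evaluation harness

`run_experiment` loops replicates (replicate r derives all randomness
from `seed + r`), records per-replicate p-values and directed edge
probabilities, and aggregates detection proportions with
`estimate_power` (strict inequalities: p < alpha, probability >
threshold; ties occur only at machine precision) at the grids alpha in
{0.01, 0.05, 0.1} and probability in {0.7, 0.8, 0.9}. `roc_curve` sweeps
the pooled threshold grid, supporting both no-effect and wrong-direction
null sets; `direction_probability_summary` gives the box-plot five-number
summaries. No multiple-testing adjustment is applied anywhere: thresholds
are heuristics for comparing methods, not inferential claims.

## Problem sizes used by the shipped tests and scripts

The full-scale study design (R = 1000 replicates, B = 1000 bootstrap
networks, 10,000 SNPs) is preserved in the configuration defaults. The
shipped test suite and analysis scripts run the same structures at desk
scale, chosen once: R = 1000 for the pure-MR calibration and recovery
checks (they are cheap), R = 200 and B = 100 for the network ordering and
ROC checks, B = 1000 for the single-dataset scenario-C network, and a
120-600 SNP panel with the 150:75 structure preserved proportionally for
the pleiotropic design. Monte Carlo error bands quoted in tests follow
binomial standard errors at those scales.

## Known limitations

* Greedy hill-climbing without restarts can miss the global BIC optimum
  (about 10% of small dense fixtures); restarts mitigate but do not
  prove optimality.
* Under hidden genetic confounding (model 3), direction is genuinely
  unidentifiable for the anchored network when the pleiotropic leak
  mimics the causal path: even the exhaustive-search optimum orients the
  X-Y edge the same way under the true effect and under the
  reverse-effect null in about 60% of datasets. The package reports this
  honestly; the corresponding wrong-direction ROC comparison favours MR
  there, and the no-effect ROC comparisons favour the network.
* The binary-scenario direction probability for the Y-W edge depends
  delicately on the balance between the chain and v-structure scores
  around the anchor, which in turn depends on the (ambiguous) link
  function and on search details: under the logistic link with standard
  BIC the chain wins by ~12 score units on average (dataset SD ~2.3), so
  the averaged network orients Y->W with probability near 1. The
  qualitative findings around that quantity - unit strengths for the two
  strong edges, and the orientation flip to W->Y when the outcome is
  constrained childless - reproduce exactly.
* Only individual-level data are supported (as for the underlying BN
  methodology); two-sample/summary-statistic MR variants are out of
  scope, as are constraint-based learners, latent-variable models, and
  cyclic structures.
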