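---
title: "Risk-scenario mapping for fall-from-height accidents: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-scenario mapping for fall-from-height accidents: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffhbn)
```

## The modelling problem

Construction falls from height (FFH) arise from interacting
organisational, environmental and behavioural deficiencies rather than
from isolated causes. `ffhbn` models this with a discrete Bayesian
network over 20 binary risk factors (coded A1–E3 in five dimensions:
illegal construction practices, safety-management failures, hazardous
site conditions, protection deficiencies, and worker-level risks) plus
a binary outcome node `FFHA`. Every node has states TRUE/FALSE —
present/absent in a given project situation. The network supports
*predictive* inference (probability of an accident under a combination
of deficiencies) and *diagnostic* inference (how prevalent each
deficiency is among accidents), and its central product is the **risk
scenario table**: the exhaustive list of all `2^k` TRUE/FALSE
assignments of the outcome's parents with the exact accident
probability of each.

The structure of the network is deliberately *not* learned from data
alone. Accident corpora are outcome-selected (every report is an
accident), which cripples purely data-driven structure search; instead
the structure originates from elicited expert judgment, and data enter
twice — to prune elicited links that the evidence calls conditionally
independent, and to estimate all probabilities.

## Stage 1: fusing two panels' edge judgments

Two respondent panels (senior experts and frontline practitioners)
score each candidate causal link on a 0–10 scale. Panel support is the
mean score divided by ten — the simplest estimator consistent with
published two-to-three-decimal panel values; nothing in the elicitation
justifies a more elaborate pooling rule.

Fusion uses Dempster's rule on the two-element frame
\{link exists, link does not exist\} with **Bayesian mass assignment**:
each source puts mass `m_i` on "exists", `1 - m_i` on "not exists", and
nothing on the whole frame. Under that convention belief and
plausibility coincide with the fused mass, which is exactly the pattern
the published fusion table shows (`Bel = Pl` on every row); had any
mass been reserved for the frame, `Pl` would exceed `Bel`. The
two-source combination reduces to

$$k = m_1(1-m_2) + (1-m_1)m_2, \qquad m = \frac{m_1 m_2}{1-k}.$$

All 25 published rows reproduce to four decimals:

```{r}
fused <- fuse_edges(ffh_edge_support())
head(fused[, c("from", "to", "m1", "m2", "Bel4", "Pl4", "k4")], 4)
```

Screening keeps links with `Bel, Pl >= 0.8` (inclusive — the published
survivors reach down to 0.8439) and `k < 0.5` (exclusive — the largest
surviving conflict is 0.4228). A mass of exactly 0.5 is neutral under
this rule (`dempster_combine(0.5, x)$m == x`), and total conflict
(`(0, 1)` or `(1, 0)`) is an error rather than a silent `NaN`.

Computation is in full precision; the `*4` columns are round-half-even
displays at four decimals for table comparison only.

## Stage 2: conditional-independence pruning

The screened links form a DAG. Wherever an edge `X -> Y` coexists with
a mediated route `X -> Z -> Y` through a single mediator, d-separation
suggests the direct edge may be spurious; the package emits the triple
`(X -> Y, Z)` for every such configuration and accepts user-supplied
triples besides (the elicitation can motivate tests that no mediator
rule generates, so triples are first-class inputs, not only a derived
set).

Each triple is tested with the plug-in conditional mutual information
over the eight joint cells of the incidence matrix, with `0 log 0 := 0`.
An edge is removed when **any** tested conditioner yields
`I < 0.02`. Only this laxer variant is determined by the reference
analysis (the one removed edge with two tests was below threshold on
both); the rule, the threshold, and the base are all configuration.
The default base is 2 (bits); natural log is available because the
threshold originates in prior literature that does not state its base,
and sensitivity runs should be able to try both. Pruning a DAG can
only delete edges, so acyclicity is preserved and the operation is
idempotent.

```{r}
g <- ffh_topology("preliminary")
candidate_cmi_tests(g)
```

## Stage 3: Laplace-smoothed parameters

With `N` reports, `X_A` of them showing factor A, and `alpha > 0`:

$$P(A{=}T) = \frac{X_A + \alpha}{N + 2\alpha}, \qquad
  P(A{=}T \mid C) = \frac{X_{A|C} + \alpha}{N_C + 2\alpha}.$$

`alpha` defaults to 1 (add-one smoothing — the canonical choice where
the source analysis leaves it unstated) and is exposed for sensitivity
runs. Smoothing keeps every probability strictly inside (0, 1), which
the inference engine and the geometric-mean fallback both rely on.

**Unseen parent combinations.** A node with several parents can have
combinations that never occur in the corpus. Such rows are estimated
from the single-parent conditionals `p_i = P(node=T | parent_i = c_i)`
(each from pairwise counts via the smoothed conditional) as

$$p = \frac{g_T}{g_T + g_F}, \qquad
  g_T = \Big(\prod_i p_i\Big)^{1/k},\;
  g_F = \Big(\prod_i (1-p_i)\Big)^{1/k}.$$

A bare geometric mean of the `p_i` and of the `(1-p_i)` would not sum
to one; the normalization is the minimal completion that restores a
valid two-state distribution while preserving the geometric-mean idea.
Every CPT row carries a provenance flag (`observed`/`fallback`) so
downstream consumers can see how much of the table rests on fallback
estimation. A `uniform` fallback (0.5) is available as a baseline.

**The outcome node.** An accident-only corpus contains no FFHA column:
the outcome is TRUE in every report. Fitting the outcome CPT under
that implicit all-TRUE column gives `(N_C + alpha)/(N_C + 2 alpha)` for
observed combinations — values that approach 1 as support grows and
that *cannot* produce mid-range scenario probabilities. This is an
inherent gap of outcome-selected data, not of the estimator: published
scenario tables with sub-50% entries must have used additional
information that an accident-only corpus does not contain. The package
therefore makes the convention explicit and lets the caller supply an
explicit 0/1 `outcome_column` (e.g. synthetic or matched controls),
which switches the outcome CPT to ordinary estimation. Simulated
corpora exercise both paths.

## Stage 4: exact inference

Inference is exact variable elimination over factor tables, with a
greedy min-fill elimination order and deterministic tie-breaks by node
id (reproducibility over micro-optimization; the 21-node network has
small induced width, so exactness is cheap). Evidence is absorbed by
slicing factors before elimination; a normalizing constant of zero —
evidence impossible under the model — raises an error instead of
returning a silent 0/0. Approximate propagation is deliberately out of
scope: exactness makes every posterior checkable against brute-force
enumeration, and the test suite does exactly that (200 random models up
to 12 nodes, plus the full 21-node topology against a `2^21`-cell joint
table, at `1e-10`).

Scenario probabilities need no elimination at all: conditioning on all
parents d-separates the outcome from the rest of the network, so each
scenario's probability is the matching CPT row; the equivalence with
`posterior()` is asserted in tests rather than recomputed 128 times at
run time. Ranking ties break by canonical enumeration order (all-TRUE
first, leftmost parent most significant), making the top-N list
deterministic.

## The synthetic-data generators

`make_ground_truth()` supplies the sampling distribution for all
simulation tests. The `"paper21"` preset is the reference final
topology — 21 nodes, 24 edges, outcome parents
\{A2, D1, C3, E1, E2, E3, C1\}. Random CPTs draw priors from
(0.15, 0.85) and conditional rows from (0.05, 0.95): wide enough to
cover skewed tables, bounded away from determinism so that
outcome-conditioned rejection sampling stays feasible and smoothed
estimation is identifiable. The preset's CPTs are illustrative — the
real corpus's co-occurrence structure is only partially visible in its
published 16-row excerpt (`ffh_incidence_excerpt()`), so no calibration
to it is attempted.

`sample_reports()` performs ancestral sampling in topological order;
with `condition_outcome_true = TRUE` it rejection-samples until `N`
accident rows are kept and then drops the outcome column, mirroring an
accident-only corpus (the acceptance rate is attached as an attribute).
`simulate_questionnaires()` draws integer scores from a clipped,
round-half-even-rounded normal centred at 8.5 for true links and 2.0
for non-links (defaults: panels of 11 and 41, sd 1.5, matching the
study-scale elicitation). Under these conditions fused support for a
true link concentrates near 0.97 and for a non-link near 0.06, so
screening recovers the true edge set at study sample sizes in nearly
every seed — the end-to-end recovery test requires at least 8 of 10.

What the simulations do *not* emulate: coding noise (misclassified
factors in reports), respondent reliability differences, and any
real-world deviation of the corpus from a Bayesian-network
distribution. Passing recovery tests therefore demonstrates
correctness of the pipeline's algorithms under its own assumptions, not
validity of the reference analysis's empirical conclusions.

## Numerical choices and problem sizes

- Probabilities are kept in full double precision end to end; rounding
  happens only in display columns and serialized reports.
- CPT rows enumerate parent states canonically: leftmost parent most
  significant, TRUE before FALSE; scenario tables may reorder columns
  for presentation (`ffh_scenario_parents()` gives the published
  layout) while preserving that enumeration semantics.
- The CMI estimator skips zero cells exactly and clamps at zero from
  below (plug-in CMI is non-negative; floating-point sums can land at
  `-1e-16`).
- Test problem sizes were chosen as the smallest that make each
  property statistically decisive: 368-report corpora for study-scale
  behaviour, 1,000 rows for coarse CPT recovery (±0.05), 50,000 rows
  for tight recovery (±0.02) on a five-node network designed so every
  parent configuration has expected support of several thousand rows —
  at boundary supports of a few hundred, one binomial standard error
  already exceeds 0.02, so a uniform ±0.02 claim is only meaningful
  with comfortable support.
- The deterministic head/tail `split_samples()` mirrors the
  258-preliminary / 110-saturation partitioning convention and is
  provided for workflow parity; the saturation analysis itself is
  qualitative and out of computational scope.

## Known limitations

- The outcome CPT from accident-only data is a convention, not an
  estimate of accident risk (see Stage 3); absolute scenario
  probabilities are only meaningful with an explicit outcome column or
  an externally supplied outcome CPT.
- Only binary nodes and the two-element evidence frame are supported;
  multi-state factors, respondent weighting and general Dempster–Shafer
  focal structures are out of scope.
- The mediator rule generates single-conditioner tests only; richer
  conditioning sets must be supplied as extra triples.
- Exact inference scales exponentially with induced width; the engine
  targets expert-elicited networks of a few dozen nodes, not
  machine-learned structures with thousands.
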