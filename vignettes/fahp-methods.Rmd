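---
title: "Methods: the improved fuzzy AHP evaluation engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the improved fuzzy AHP evaluation engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fahp)
```

## The model

`fahp` evaluates a set of alternatives against a layered indicator
hierarchy — a target node, one or more criterion layers, and leaf indicators
at a common depth — and scores each alternative with the linear-weighted
comprehensive index

$$P = \sum_{i=1}^{n} x_i \lambda_i + c,$$

where $x_i \in [0,1]$ is the standardized value of leaf $i$, $\lambda_i$ its
composite weight, and $c$ a correction for interference effects outside the
hierarchy. The weights come from an improved fuzzy analytic hierarchy
process built on the **three-scale complementary calculus** rather than
Saaty's 1–9 reciprocal scale: each expert compares a pair of sibling
criteria with a single score in $\{0, 0.5, 1\}$ ("less important", "equally
important", "more important").

Per hierarchy node the pipeline is:

1. **Aggregation.** The score chosen by the most experts becomes the entry
   $f_{ij}$ of the fuzzy judgment matrix $F$; $f_{ji} = 1 - f_{ij}$,
   $f_{ii} = 0.5$. When no score has a strict plurality the entry is 0.5.
   Equal importance is the only tie-break that is symmetric in the two
   criteria and independent of the order in which scores arrive: any rule
   preferring an extreme would let the panel's labelling of the pair decide
   the outcome. (The alternative reading — requiring at least three
   concordant experts — is not well defined for small panels, so the
   plurality rule is used throughout and documented here rather than
   asserted as the only possible convention.)
2. **Consistent transform.** With row sums $r_i = \sum_j f_{ij}$,
   $$r_{ij} = \frac{r_i - r_j}{2n} + 0.5 .$$
   The result satisfies additive consistency
   $r_{ij} = r_{ik} - r_{jk} + 0.5$ for every triple *by construction*, so
   no consistency-ratio check is performed anywhere in the package — the
   transform is the consistency repair.
3. **Closed-form priorities.** Either row-normalization,
   $w_i = \sum_j r_{ij} / \sum_{ij} r_{ij}$ (`weights_normalizing()`), or
   the geometric-mean ("square root") form
   $w_i \propto (\prod_j r_{ij})^{1/n}$ (`weights_sqrt()`). Both preserve
   the importance ordering given by the row sums.
4. **Reciprocal refinement.** $e_{ij} = r_{ij}/r_{ji}$ maps the
   complementary matrix onto the multiplicative scale
   ($e_{ij} e_{ji} = 1$), and the principal eigenvector of $E$ — found by
   power iteration — is the refined ranking vector. This `"iterative"`
   method is the default: both closed forms are kept because neither is
   canonical in the literature, but the refined eigenvector is what the
   bundled case study's published weights correspond to, so it is treated
   as the arbiter.

Composite leaf weights are the **path products** of local weights from the
root to each leaf. The product rule is the unique synthesis consistent with
per-leaf contributions of the form $\lambda_i x_i$ whose weights sum to 1
whenever every sibling group's weights do; the bundled case's published
per-leaf integrated values confirm it cell by cell (77 of 78 cells agree at
4 decimals; the worst deviation is $8\times10^{-5}$, i.e. printed-rounding
noise).

## Numerical choices

* **Power iteration** uses $V^{(k+1)} = E\,Y^{(k)}$ with
  $Y^{(k)} = V^{(k)} / \|V^{(k)}\|_\infty$, stops when
  $\|Y^{(k+1)} - Y^{(k)}\|_\infty < \text{tol}$ (default $10^{-4}$,
  `max_iter = 100`), and reports $\lambda_{\max} = \|V_{\text{final}}\|_\infty$
  — the infinity-norm estimator, not a Rayleigh quotient, matching the
  convention of the worked example it reproduces (3.0061 for the bundled
  3×3 criteria matrix; full-precision arithmetic gives 3.00560, inside the
  0.002 band that printed 4-decimal intermediates induce).
* **Seeding** uses the full-precision normalizing vector, not its 3-decimal
  truncation; with that seed every fixture in the package converges in at
  most 6 iterations. A uniform seed is the fallback when none is given.
* **Intermediate state is never rounded.** All printed 3–4-decimal values in
  tests are compared with explicit tolerances; reports round only at the
  output boundary (4 decimals, the conventional table precision).
* **Degenerate inputs.** The ratio $r_{ij}/r_{ji}$ is undefined at
  $r_{ij} \in \{0, 1\}$ and `to_reciprocal()` then fails with the offending
  pair named. Note that matrices produced by `to_consistent()` can never hit
  this: row sums lie in $[0.5, n-0.5]$, so
  $|r_{ij} - 0.5| \le (n-1)/2n < 0.5$. The error path exists for
  complementary matrices supplied directly (e.g. feeding a raw extreme
  judgment matrix into the ratio conversion). The same applies to the zero
  entries that break the geometric mean in `weights_sqrt()`.
* **Degenerate standardization.** If all alternatives tie on a leaf,
  min-max scaling is undefined; the package returns 0.5 (the indifference
  point of the scale) for every alternative and warns, so a constant
  indicator contributes identically to every alternative instead of
  aborting the evaluation.
* **Ties in ranking** keep input order (stable sort), and `delta_next`
  reports the adjacent score gaps.

## Standardization

Three routes, selected per leaf by its `direction` flag:

* `positive` — threshold (min-max) scaling across alternatives; the best
  alternative gets 1, the worst 0.
* `reverse` — the raw data are negated first, so *smaller* raw values score
  higher (costs, damages).
* `graded` — qualitative indicators scored directly by experts on the
  five-grade scale (excellent 0.80–1.00, good 0.60–0.79, middle 0.40–0.59,
  poor 0.20–0.39, very poor 0.00–0.19); the values are already fractions
  and bypass threshold scaling.

`fraction_standardize()` covers data already expressed as percentages.
With $c = 0$ and all $x_i \in [0,1]$, $P \in [0,1]$ and is monotone
non-decreasing in every leaf value.

The correction defaults to $c = 0$, the assumption that positive and
negative interference effects offset each other; callers with evidence of a
net bias can shift all scores by a common constant, which changes no
ranking.

## The ecological indicator calculators

The leaves of a sustainability hierarchy are fed from heterogeneous
sources: field measurements, statistics-bureau series, expert grades, and a
handful of closed-form ecological benefit formulas implemented in
`simpson_diversity()`, `shannon_stability()`, `landscape_integrity()`,
`plantation_productivity()`, `restoration_force()`, `water_conservation()`,
`soil_water_conservation()`, `air_purification()`, `soil_improvement()` and
`future_generations_value()`. They are deliberately optional front-ends —
the evaluation pipeline accepts values from any source.

Two conventions deserve a note. The willingness-to-pay valuation
(`future_generations_value()`) divides grade counts by the *total* number of
respondents, the only reading under which the grade shares sum to at most 1.
And the soil-improvement formula takes three per-component factor triples
whose semantics (nutrient content, fertilizer equivalent, price) are a
documented convention rather than a fixed definition — any consistent
factorization works. Symbols that recur across formulas (several prices and
rates share letters in the field's notation) are disambiguated by argument
name, each scoped to one indicator.

## What the synthetic fixtures emulate — and what they do not

`generate_panel()` draws each expert's pair score i.i.d. from
$\{0, 0.5, 1\}$, uniform by default, with 7 experts per panel — the panel
size of the bundled case study — and `random_hierarchy()` grows
balanced-depth trees with 3 levels below the root and 3–9 children per
node, the conventional span for pairwise comparison. The uniform score
distribution is a deliberate neutral default: no distributional model of
expert behaviour is implied by the method itself, and a skew parameter
(`prob`) covers strong-consensus or unanimous-extreme panels when needed.

What the generator does **not** emulate: correlated opinions within a panel
(real experts share schools of thought), systematic intransitivity across
pairs, dependence of scores on the criteria's meaning, or missing
judgments. Passing the property suite on generated panels therefore
establishes the *algebraic* guarantees — complementarity, additive
consistency to $10^{-12}$, reciprocity to $10^{-9}$, eigen-oracle agreement
to $10^{-6}$, the Perron bound $\lambda_{\max} \ge n$, and order
preservation — not the behavioural validity of any particular expert panel.

Problem sizes in the default suite: 1000 random panels at $n \in [3, 9]$
for the consistency identities, a 50-panel subsample against the dense
eigen-decomposition oracle, exhaustive enumeration of all 27 complementary
3×3 matrices for order preservation, and the full 39-leaf case study for
the end-to-end reproduction. The whole suite runs in well under a minute on
one core.

## Limitations

* The calculus is specific to the three-scale complementary scale; Saaty
  1–9 inputs and classic consistency ratios are out of scope.
* Hierarchies must be layered (all leaves at equal depth); ragged trees are
  rejected rather than silently padded.
* The linear-weighted index assumes preferential independence between
  leaves; strongly interacting indicators should be merged or modelled
  upstream.
* Sensitivity analysis of the ranking to terrain, cutting area or single
  weights is not built in, though `predict()` on perturbed value tables
  makes one-at-a-time scans straightforward.
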