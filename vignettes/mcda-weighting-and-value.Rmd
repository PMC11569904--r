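---
title: "Weighting, value aggregation and sensitivity analysis with mcdahta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighting, value aggregation and sensitivity analysis with mcdahta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdahta)
```

## The decision model

`mcdahta` implements a quantitative multi-criteria decision analysis (MCDA)
framework of the kind used by health services to prioritize high-impact
health technologies. The framework has three ingredients:

1. **A criteria hierarchy.** Evaluation criteria are organized in three
   levels: *domains* (e.g. need for intervention, outcomes of the
   intervention, knowledge of the intervention, economic impact,
   feasibility), *criteria* within each domain, and optional *subcriteria*
   within each criterion. The packaged default configuration has 5 domains,
   15 criteria and 15 subcriteria; nodes whose exact published wording or
   placement is not publicly available are explicitly labelled
   `(placeholder)` and the configuration is plain YAML that users are
   expected to replace with their own framework.

2. **Weights elicited by 100-point allocation.** Each respondent
   distributes 100 points among the domains, 100 points among the criteria
   of each domain, and 100 points among the subcriteria of each criterion.
   Allocations are therefore compositional by construction. Two stakeholder
   samples are surveyed — healthcare professionals and the general
   population — and the framework's final weight for each item is the
   *equal-weighted average of the two sample means*, deliberately not the
   pooled-respondent mean: with 494 population respondents against 35
   professionals, pooling respondents would drown the professional
   perspective (the population would contribute more than 93 % of the
   observations).

3. **An additive multi-attribute value function.** After normalizing each
   sibling group's weights to sum to one, the composite value of a
   technology with leaf scores $s_{ijk}$ is

   $$V \;=\; \sum_i \hat w_i \sum_j \hat w_{ij} \sum_k \hat w_{ijk}\, s_{ijk},$$

   where $i$, $j$, $k$ index domains, criteria and subcriteria and the
   inner sum collapses for criteria without subcriteria. Equivalently, $V$
   is the sum over leaves of the *effective leaf weight* (the product of
   the normalized weights along the leaf's path) times the leaf score;
   effective leaf weights always sum to one.

### Where scores live

The formula's description of "scores assigned to each domain, criterion and
subcriterion" is ambiguous: read literally it would let a decision maker
score internal nodes independently of their descendants, which
double-counts. `mcdahta` adopts the standard additive multi-attribute value
reading: scores are attached to **leaves only** (all subcriteria, plus
criteria that have no subcriteria), and a domain's or criterion's "score"
is the weighted sum of its descendants. Scoring itself — building evidence
matrices for real technologies — is out of scope; score sheets declare
their own scale (default $[0,1]$) and no implicit rescaling is ever
applied.

## Elicitation data and validation

Survey responses are long-format CSV (`respondent_id, sample_id, group_id,
node_id, points`), one row per respondent and node. A record (one
respondent × one sibling group) is valid iff its keys are exactly the
group's children, all points are non-negative, and the points sum to
exactly 100. Because the survey interface enforces the budget, a file row
violating it is treated as an entry error and **rejected**, with a reasoned
rejection report, rather than silently corrected; an opt-in
`repair = "proportional"` mode rescales off-budget rows to 100 and re-rounds
them by the largest-remainder method, logging each repair. Respondents may
answer some groups and not others; all statistics are per group with their
own $n$.

Per-sample summaries report $n$, mean, standard deviation (always the
$n-1$ denominator) and median per node. Within any group answered
completely, means sum to 100 by linearity — this invariant is tested, and
it is what makes equal-weighted pooling budget-preserving.

## From two samples to one weight table

`build_weight_table()` composes four steps:

* **Comparison** (reported alongside, not used to modify weights): per
  node, a two-sided Welch *t*-test and a Mann–Whitney–Wilcoxon rank-sum
  test with normal approximation and tie correction (no continuity
  correction). Welch is the default *t* form because the two samples have
  very different sizes (35 vs 494) and visibly different dispersion;
  a pooled-variance flag is deliberately not offered since nothing
  downstream depends on it. Raw p-values are reported by default (a Holm
  option exists but is off), with 0.05 two-sided as the conventional
  reporting threshold. Degenerate input — both samples constant and equal —
  is reported as $p = 1$ with a flag rather than `NaN`.

* **Pooling**: $\bar w = \lambda\,\bar w_A + (1-\lambda)\,\bar w_B$ with
  $\lambda = 0.5$ by default (the equal-weighted average of the two sample
  means). Pooling is affine, so sibling sums stay at 100 exactly.

* **Rounding**: published weight tables print integers, but independent
  nearest-integer rounding does not guarantee a 100 sum (R's half-to-even
  rule makes this easy to hit). The default is **largest-remainder
  (Hamilton) rounding per sibling group**: floor everything, then hand the
  leftover units to the largest fractional parts, ties broken by document
  order. Among integer vectors with the correct sum this minimizes total
  absolute deviation from the unrounded values, and no component ever moves
  by a whole unit. A `rounding = "naive"` mode reproduces plain
  `round()` and flags any group whose sum breaks.

* **Normalization**: $\hat w = W / \sum_{\text{group}} W$ over the
  *rounded* integers by default (equal to $W/100$ under largest-remainder
  rounding), because the published presentation normalizes the printed
  integer table; `normalize = "pooled"` normalizes the unrounded percents
  instead, which is what the probabilistic sensitivity analysis uses
  internally.

Users who already hold a published integer weight table can skip
elicitation entirely via `weight_table_from_weights()`.

## Sensitivity analysis

The framework phase "sensitivity analysis" is prescribed generically in the
HTA literature (deterministic or probabilistic) without a specific
algorithm, so the package implements the two standard MCDA practices:

* **One-way deterministic reweighting**
  (`one_way_weight_sensitivity()`): one domain's or criterion's percent
  weight sweeps a grid; its siblings are rescaled proportionally so the
  group still sums to 100. $V$ is linear in the varied weight, so the
  curves are straight lines, the baseline grid point reproduces the
  baseline $V$ bit-for-bit (the table is reused unmodified there), and
  top-rank crossovers are located exactly by linear interpolation between
  grid neighbours.

* **Probabilistic analysis** (`probabilistic_sensitivity()`): the primary
  method is a **stratified respondent bootstrap** — each draw resamples
  respondents with replacement within each sample, recomputes per-node
  means, pools with the same $\lambda$, and normalizes the *unrounded*
  pooled weights. Integer rounding is skipped inside draws because it is a
  presentation step; re-rounding every draw would inject ±0.5-point
  quantization noise that can swamp genuine sampling variation in small
  sibling groups. For users without microdata a **Dirichlet alternative**
  draws each group's mean weight vector from a Dirichlet whose
  concentration is the profile's concentration scaled by $n$,
  approximating the sampling distribution of a mean of $n$ respondents
  (moment-matched profiles can be fitted from data with
  `moment_match_profiles()`). Both routes are seeded and bit-reproducible.

  Output is a rank-acceptability table (fraction of draws in which each
  technology attains each rank) plus mean and 2.5/97.5 percentile values.
  Within draws, ranks break ties by document order rather than competition
  ranking: this makes each draw's ranks a permutation, so rank fractions
  sum to one both per technology and per rank. The user-facing
  `rank_technologies()` keeps competition ranking with an explicit tie
  flag, where that property is not needed.

## The synthetic survey generator

Real respondent-level allocations behind published weight tables are
generally unavailable, so `simulate_allocations()` generates them with the
structure point-allocation surveys actually exhibit:

* **Compositional draws.** Per respondent and sibling group, proportions
  come from a Dirichlet distribution; the budget constraint holds by
  construction and low concentration produces the dispersed, right-skewed
  allocations seen in general-population samples (skewness is induced by
  low concentration rather than an explicit skew family precisely to keep
  the budget exact).
* **Equalizing bias.** The Dirichlet mean is
  $(1-b)\cdot\text{target} + b\cdot\text{uniform}$: respondents tend to
  spread points more evenly than their "true" priorities. Because this
  shifts the generated mean by construction, parameter-recovery checks
  compare against the *implied* mean (`profile_implied_means()`), not the
  raw target.
* **Round-number bias.** With a configurable probability the allocation is
  snapped to multiples of 5. Snapping is *stochastic* (down or up with
  probability equal to the fractional distance) rather than
  nearest-multiple: deterministic snapping visibly biases the mean of
  tightly concentrated samples, while stochastic snapping preserves the
  mean exactly and still produces the 5-point clustering the bin-width-5
  histograms of `distribution_report()` are designed to expose. The 100
  budget is then repaired in on-grid ±5 steps, so a fully snapped record
  has at most (in practice zero) one off-grid value.
* **Integerization.** Unsnapped draws are rounded to integers by the
  largest-remainder method, so every emitted record passes validation
  exactly.

The default profiles encode the study conditions of the motivating
application: professionals $n = 35$ with concentration 150 (allocations
mostly within a narrow band), general population $n = 494$ with
concentration 12 (wide, right-skewed); domain-level target means are the
published per-sample values where printed, with the one unprinted domain
per sample taking the residual to 100, and uniform targets at the
criterion/subcriterion levels where nothing is printed. Concentrations and
the bias parameters (round-number 0.3/0.5, equalizing 0.10/0.15 for
professionals/population) are calibration defaults chosen once to
qualitatively match the described dispersion contrast; they are **not**
published values. What the generator deliberately does not emulate:
respondent demographics, nonresponse mechanisms, item-level missingness
patterns, or correlation of a respondent's answers across sibling groups —
so passing tests demonstrate the pipeline's correctness on realistic
compositional data, not fidelity to any particular real population.

## Numerical choices

* Budget tolerance: allocation sums are compared to 100 at $10^{-9}$
  (exact for integer data); pooled sibling sums at $10^{-9}$; normalized
  fractions at $10^{-12}$.
* `round_preserving_sum()` guards floats near integers with a $10^{-9}$
  nudge before flooring; ties on fractional parts break by document order,
  the canonical tie-break everywhere in the package.
* Degenerate two-sample comparisons (both samples constant) report
  $p = 1$ (equal means) or $p = 0$ (different means) with a `degenerate`
  flag instead of propagating `NaN`.
* One-way sensitivity refuses to rescale when the varied node's siblings
  carry zero total weight (the budget cannot be redistributed), and reuses
  the unmodified table at the baseline grid point so the baseline value is
  reproduced exactly, not merely to tolerance.
* All stochastic code paths take an explicit integer seed, run under a
  temporarily swapped RNG state, and restore the caller's RNG afterwards.

## Problem sizes used by the test suite

The suite checks the value function against a recursive brute-force oracle
on 1,000 random trees (up to 5 domains × 4 criteria × 4 subcriteria),
largest-remainder rounding against an exhaustive floor/ceiling
minimal-deviation search on 500 random sibling groups of size ≤ 5, the
Welch and rank-sum implementations against hand-coded textbook formulas on
100 random integer-valued two-sample problems, budget compliance on 1,000
simulated respondents, and parameter recovery of the domain-level means at
$n = 500$ per sample across five fixed seeds, comparing the estimate
pooled over the five runs to the implied means within two standard errors.
These sizes were chosen as the smallest that exercise every code path with
comfortable statistical resolution.

## Known limitations

* The default criteria configuration fills unpublished table cells with
  labelled placeholders; counts and structure are faithful, labels of
  placeholder nodes are not data.
* Weight elicitation supports exactly the 100-point allocation method;
  discrete-choice, AHP/pairwise and matching methods are out of scope.
* Aggregation is additive only; multiplicative and outranking models are
  not implemented.
* The Dirichlet route of the probabilistic analysis approximates the
  sampling distribution of a sample mean by a rescaled Dirichlet; for very
  small $n$ or near-zero mean components the bootstrap route on real
  microdata is preferable.
* Structural uncertainty over the tree itself (adding/removing criteria)
  is not modelled.
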