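---
title: "MACBETH elicitation and additive value frameworks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MACBETH elicitation and additive value frameworks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macbethvaf)
```

This vignette documents the models and numerical choices behind
`macbethvaf`: how qualitative pairwise judgments become cardinal value
scales, how reference levels, value functions and swing weights compose
into an additive scoring model, what the reliability statistics assume,
and what the synthetic generators do and do not emulate.

## The elicitation model

MACBETH elicits *differences of attractiveness*. For a set of items
(performance reference levels of one criterion, or hypothetical
criterion-swing alternatives), a stakeholder judges selected pairs on a
seven-category semantic scale: no difference, very weak, weak, moderate,
strong, very strong, extreme (codes 0–6). The package represents these
as a `judgment_matrix`: a partial map over unordered pairs, each stored
with the non-less-attractive item first. Completeness is not required —
an unjudged pair simply leaves the corresponding difference
unconstrained.

A judgment set is *consistent* when some real item values
$v_1, \dots, v_n$ and strictly increasing category thresholds
$t_1 < \dots < t_6$ satisfy every judgment simultaneously:

$$
\text{code } k \text{ on } (i, j):\quad v_i - v_j \ge t_k,
\qquad v_i - v_j \le t_{k+1} - \delta \;\; (k \le 5),
\qquad \text{code } 0: v_i = v_j,
$$

with $t_1 \ge \delta$, $t_{k+1} \ge t_k + \delta$. The category
separation $\delta$ is a pure scale factor of this system; it is fixed
at 1. `check_consistency()` decides feasibility by linear programming
and, on failure, reports a conflict witness: judgments are given slack
variables, total slack is minimised, and the judgment carrying the
largest slack is removed repeatedly until the system is feasible. The
witness is greedily minimal — an exactly minimal witness would require
exponential search — and is intended as the set of judgments a
facilitator should revisit with the panel.

### From feasibility to a unique scale

A feasible system has infinitely many solutions, so `derive_scale()`
makes a canonical choice: first minimise the largest raw value (the
minimax solution uses the fewest distinguishable steps compatible with
the judgments), then, holding that optimum, lexicographically minimise
each item value in item order and finally each threshold. The result is
unique and bitwise reproducible. Raw values are then rescaled affinely
so the designated top item sits at exactly 100 and the bottom at 0;
thresholds rescale by the same factor and are returned as diagnostics.
Items tied by a code-0 judgment are merged into a single LP variable
before solving, so elicited equalities hold exactly rather than within a
tolerance.

Two numerical choices matter here. Equality and anchor comparisons use
a tolerance of 1e-9 on the 0–100 scale. And every LP variable carries a
large box bound (1e4) that no optimum approaches: the bounded polytope
keeps the simplex solver away from degenerate pivots along unbounded
rays (the thresholds otherwise have no upper limit). Solving uses the
three-phase simplex of the `boot` package; an exhaustive integer-grid
search (`grid_feasible()`, compiled code) provides an independent
feasibility oracle for small matrices and is cross-checked against the
LP throughout the test suite.

### Group elicitation

Panels are handled one stakeholder at a time: each stakeholder's matrix
yields a scale (or weight vector), and group results are arithmetic
means of the per-stakeholder results. Deriving first and averaging
after preserves each stakeholder's internal consistency; averaging
judgment categories across people before solving has no such guarantee.

## Reference levels and value functions

Five reference levels anchor each numeric criterion's value function —
enough to bend the function where preferences bend, few enough for a
questionnaire a panel can answer reliably. `compute_reference_levels()`
builds them from collected drug performance data with a direction-aware
bracketing rule: the best observed performance becomes Level 2, the
worst Level 4, the sample median Level 3, and Levels 1 and 5 extend 20%
beyond the respective extremes (for a harm criterion,
$L1 = 0.8 \min$, $L2 = \min$, $L3 = \text{median}$, $L4 = \max$,
$L5 = 1.2 \max$; mirrored for benefit criteria). The outer levels exist
so that a new therapy slightly better or worse than anything yet
observed still falls on the elicited part of the scale. Two conventions
fill gaps the rule leaves open: the median of an even-sized sample is
the midpoint of the two central order statistics, and a median that
coincides with an extreme (heavily skewed samples) is nudged to the
range midpoint to keep the five levels strictly monotone. Categorical
criteria (dosage and administration; number of alternatives) do not use
the rule: their five levels are enumerated categories supplied in
configuration.

`build_value_function()` joins the levels with the MACBETH scale
elicited over them (anchored $v(L1) = 100$, $v(L5) = 0$, weakly
monotone in between — flat segments are legitimate elicitation
outcomes) into a piecewise-linear interpolant. Outside $[L5, L1]$ the
value is clamped to 0 or 100 rather than extrapolated: the function is
defined only over the elicited range, and clamping keeps overall scores
in $[0, 100]$.

## Swing weights and the additive score

Weights are elicited by qualitative swing weighting. The hypothetical
alternatives are: one per criterion with that criterion at its upper
reference level and all others at their lower levels, plus an all-lower
baseline. The MACBETH scale over these alternatives, with the baseline
anchored at 0 (the standard reference-profile convention), gives
$w_j \propto \text{scale}(\text{swing}_j) - \text{scale}(\text{baseline})$,
normalised to sum to 1 — so weights are invariant to any positive
rescaling of the swing scale. An alternative's overall score is then
the weighted sum of its per-criterion value scores, linear in each with
coefficient $w_j$.

## The packaged lymphoma framework

`packaged_lymphoma_model()` ships the nine-criterion framework with its
elicited mean stakeholder weights (stored as normalised fractions;
percentages are the canonical display). The mPFS value function embeds
its published linear segment of 1.58 value-points per month with
intercept 20.75, placed on the breakpoint interval 20–35 months so the
interpolant reproduces it exactly there:

```{r}
model <- packaged_lymphoma_model()
evaluate_value(model$value_functions$mpfs, 25.7)
```

The segment's published validity is a single point (25.7 months); its
surrounding breakpoints, and the value functions of the other eight
criteria, are configuration rather than elicited results and carry the
provenance flag `"placeholder"` (`"printed segment"` for mPFS). Every
placeholder can be replaced by re-deriving the value function from a
real judgment matrix; the framework's structure and weights remain.

The two-stage criteria selection that produced the framework is
replayable: `lymphoma_candidate_criteria()` carries the 25 candidate
criteria in their importance-survey rank order,
`filter_by_importance()` applies the exclusion boundary (mean score of
3.5 or below is excluded — the boundary itself excludes), and
`lymphoma_selection_ledger()` applies the nine reasoned exclusions and
four operational substitutions that yield the final nine criteria. The
individual survey scores were not published; the candidate fixture's
`mean_score` column is a synthetic, evenly spaced stand-in consistent
with the published rank order and threshold outcome, and is labelled as
such in its documentation.

## Inter-rater reliability

`icc()` computes the intraclass correlation from the two-way ANOVA mean
squares of a complete raters-by-items grid. The form is two-way
random-effects with absolute agreement — raters are a sample from a
population of plausible panelists, and systematic rater severity should
count against reliability. Average measures, ICC(A,k), is the default
because the quantity of interest is the reliability of the panel mean;
single measures, ICC(A,1), is available via `type = "single"`, and the
form label is always part of the result. Confidence intervals are
F-based (McGraw–Wong): the single-measures interval uses
Satterthwaite-style degrees of freedom, and the average-measures
interval is its Spearman–Brown step-up. On a perfect-agreement panel
(zero rater and residual mean squares) the estimate and both interval
ends are 1, the analytic limit of those formulas. Interpretation bands
follow the usual convention: below 0.4 poor, above 0.75 good, moderate
between.

## Synthetic data: what it emulates, and what it does not

The generators provide ground-truth test data in the same formats the
elicitation functions consume. `generate_consistent_judgments()` bins
true value differences under given thresholds (category 0 only for
exact ties; a positive difference below $t_1$ is binned to category 1,
so noiseless generation always preserves the true ranking).
`perturb_judgments()` moves each judgment one category up or down with
a given probability — the minimal perturbation respecting the ordinal
scale, with reflection at the ends (0 to 1, 6 to 5) so a perturbed
judgment always differs by exactly one category.
`generate_rater_panel()` adds independent Gaussian noise to true item
means; `generate_performance_table()` draws drug performances uniformly
within per-criterion ranges. All generators take explicit seeds,
restore the caller's RNG state, and are byte-reproducible.

These emulate the *structure* of stakeholder data, not its psychology:
real judgment errors are correlated within a stakeholder, panels show
systematic severity differences (the rater main effect the ICC's
absolute-agreement form exists to penalise), and real drug performance
is not uniform. Passing round-trip tests therefore demonstrates the
correctness of the elicitation and scoring machinery, not the validity
of any particular elicited framework.

## Problem sizes used in the tests

The suite cross-checks LP feasibility against the exhaustive grid
oracle on 5000 sampled matrices of up to four items (the grid search is
exact for integer values up to 24 with integer thresholds), calibrates
the ICC estimator on 1000 Monte-Carlo panels of 50 items by 6 raters
against the closed-form ICC of the generating variance components (the
tolerance covers three Monte-Carlo standard errors plus the estimator's
O(1/n) small-sample bias), and probes weight-recovery degradation over
500 perturbation seeds per noise level. Noise-trend assertions are
made in the small-noise regime: at large flip probabilities a coherent
shift of all judgments can remain consistent, so monotone degradation
is a small-noise property.

## Known limitations

- The LP's canonical objective (minimax plus lexicographic clean-up) is
  one defensible uniqueness rule; commercial MACBETH implementations do
  not publish theirs, and no bit-for-bit agreement with them is
  claimed.
- The conflict witness is greedy-minimal, not exactly minimal.
- The packaged framework's non-mPFS value functions are placeholders
  (flagged as such), pending elicited judgment matrices.
- Scores are value points on an interval scale: ratios of scores are
  not meaningful, and scores from differently anchored frameworks are
  not comparable.
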