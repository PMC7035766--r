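---
title: "Methods: flexible and interactive tradeoff elicitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flexible and interactive tradeoff elicitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitradeoff)
```

## The decision model

The package supports choice among a small set of alternatives evaluated on
multiple criteria under an **additive multi-attribute value model**:

$$ v(a) = \sum_{i=1}^{n} k_i \, v_i(x_{ai}), \qquad \sum_i k_i = 1,
   \quad k_i \ge 0, $$

where $x_{ai}$ is alternative $a$'s consequence on criterion $i$, $v_i$ is a
marginal value function, and the $k_i$ are *scale constants* ("weights").
Marginal value functions are affine min–max normalizations over the observed
column range,

$$ v_i(x) = \frac{x - \min_a x_{ai}}{\max_a x_{ai} - \min_a x_{ai}}, $$

so every criterion contributes on a common $[0,1]$ scale.  A criterion whose
column is constant carries no preferential information; `decision_problem()`
rejects it (error class `fitradeoff_degenerate`) rather than silently
dividing by zero.

## Partial information about the scale constants

Instead of eliciting point weights, the package works with the *weight
space*: the polytope of scale-constant vectors compatible with what the
decision maker has said so far.

1. **Ranking.**  A strict importance ranking $k_1 > k_2 > \dots > k_n$
   together with $\sum k_i = 1$, $k \ge 0$ defines the initial space
   (`weight_space()`).
2. **Tradeoff statements.**  Each elicitation question compares a
   hypothetical consequence at normalized level $v \in (0,1)$ on a
   higher-ranked criterion $i$ (worst on all others) against the best
   consequence on a lower-ranked criterion $j$ (worst on all others).  The
   answer adds a linear constraint (`add_statement()`):

   * prefer the hypothetical (answer "A"): $k_j \le k_i v - \delta$;
   * prefer the best-on-lower (answer "B"): $k_j \ge k_i v + \delta$;
   * indifference: the two-sided band $|k_j - k_i v| \le \text{band}$.

Strict inequalities are closed with a separation $\delta$ so that every
linear program is over a compact polytope.

## Potential optimality

An alternative stays in play while *some* feasible weight vector makes it at
least as good as every rival.  `is_potentially_optimal()` decides this with a
slack linear program: maximize $s$ subject to
$v(a,k) \ge v(b,k) + s$ for all rivals $b$ and $k$ in the space.  A
non-negative optimum certifies potential optimality and returns the witness
weights; a negative optimum is the margin by which the alternative is beaten
everywhere.  `filter_potentially_optimal()` applies this to every
alternative and attaches each survivor's maximum attainable value
(`max_additive_value()`), the "possible solutions" view shown to decision
makers.

## The elicitation loop

`run_session()` alternates questions and filtering until a unique survivor
remains (or a stop condition fires).  The default question strategy is
**bisection on weight ratios**: for every adjacent-or-not ranked pair the
feasible interval of $k_j / k_i$ is computed exactly with a Charnes–Cooper
transformed linear program (`ratio_bounds()`); the widest interval is
queried at its midpoint.  Answer sources are interchangeable closures:
`scripted_answers()` (replay), `simulated_dm()` (answers derived from hidden
true weights), or `interactive_answers()` (console).

Inconsistent answers — a statement that empties the space — raise an error
of class `fitradeoff_inconsistent` carrying the offending statement and the
session log, rather than returning a half-valid result.

## Numerical choices

* **Strictness `delta = 1e-6`** closes strict inequalities.  It must be
  well above linear-program tolerances (~1e-9) so "strictly worse" is
  distinguishable from round-off, yet far below question resolution (~1e-3)
  so it never influences which alternative survives.
* **Indifference `band = 1e-6`** mirrors `delta`; an indifference answer
  pins a weight ratio only up to this half-width.
* **Elimination tolerance `tol = 1e-7`** on the optimal slack keeps
  boundary ties: an alternative is dropped only when it is beaten by more
  than `tol` everywhere.  Elimination is deliberately conservative.
* **Linear programming.**  All programs have at most ~15 variables and a
  few dozen rows, so the package carries its own dense two-phase simplex
  (`R/lp.R`) using Bland's rule in both phases — deterministic and immune
  to cycling.  It is validated in the test suite against ranked-simplex
  vertex enumeration and a dense grid oracle.
* **Tie-break.**  When a session ends with several survivors (question cap,
  script exhausted, or the decision maker stops), the recommendation is the
  survivor with the greatest maximum attainable value, ties broken
  lexicographically — a reproducible, documented convention, not a claim of
  optimality.
* **Ratio bounds** are computed by an exact fractional-programming
  transformation instead of sampling, so bisection midpoints are exact.

## The synthetic decision maker

`recovery_experiment()` checks the loop end to end: draw a problem, draw
hidden true weights, let a simulated decision maker answer every question
from those weights, and test whether the session returns the true best
alternative.

* **Problem generator** (`generate_problem()`): integer consequences drawn
  uniformly over `score_range` (default 0–30), the range that a panel
  scoring ~6 subcriteria on a 0–5 scale can produce; constant columns are
  redrawn.  Default size is 5 alternatives x 4 criteria, matching the small
  problems this elicitation style is designed for.
* **True weights** (`draw_true_weights()`): a symmetric Dirichlet draw
  sorted decreasingly — the uniform distribution on the ranked simplex, so
  no region of the weight space is favoured.
* **Decision maker** (`simulated_dm()`): answers "A" when
  $k_i v > k_j + \text{band}$, "B" when $k_i v < k_j - \text{band}$,
  indifferent inside the band.  With `band = 0` the simulated decision
  maker is perfectly decisive, the idealized condition under which recovery
  of the true best alternative should be (and is, in the test suite)
  universal.

**Limits of realism.**  The generator draws criteria independently, while
real questionnaire criteria are often correlated; the simulated decision
maker never errs, never reverses itself and answers any number of
questions, so recovery rates here are an upper bound on what inconsistent
humans would achieve.  Positive `band` models blunted sensitivity but not
random response error.

## Bundled case study

The package ships a complete worked data set from an emergency-triage
protocol selection exercise (`triage_*()` functions): a validated
four-criterion / 27-subcriterion tree, specialist scores, the aggregated
decision matrix, the criteria ranking, and the recorded seven-answer
elicitation script.  `reproduce_case_study()` replays it end to end; the
acceptance tests pin its recorded intermediate and final results.
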