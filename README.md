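# fitradeoff

Flexible and interactive tradeoff elicitation for multi-criteria choice
problems.

Choosing one alternative among a handful, evaluated on several conflicting
criteria, usually runs through an additive value model

> v(a) = Σᵢ kᵢ · vᵢ(xₐᵢ),  Σᵢ kᵢ = 1,  kᵢ ≥ 0,

whose scale constants kᵢ are the hard part: decision makers rarely hold
precise weights. `fitradeoff` never asks for them. It starts from a simple
importance **ranking** of the criteria, treats every weight vector
compatible with that ranking as still possible, and shrinks this **weight
space** one tradeoff question at a time — each answer becomes a linear
constraint — while a linear-programming filter discards every alternative
that can no longer be optimal anywhere in the space. The session ends, often
after a handful of questions, when a single alternative survives.

The package provides, tidyverse-style (tibbles in and out, `tidy()` /
`glance()` / `autoplot()` methods):

* questionnaire aggregation into a decision matrix (`criteria_tree()`,
  `aggregate_specialist_sum()`, `aggregate_likert_mean()`);
* the decision model (`decision_problem()`, `additive_value()`);
* the weight space and its geometry (`weight_space()`, `add_statement()`,
  `weight_bounds()`, `ratio_bounds()`, `max_additive_value()`);
* potential-optimality filtering (`filter_potentially_optimal()`,
  `is_potentially_optimal()`, `survivors()`);
* the elicitation loop with scripted, simulated or interactive answers
  (`run_session()`, `next_question()`, `scripted_answers()`,
  `simulated_dm()`);
* a synthetic decision-maker testbed (`synthetic_spec()`,
  `generate_problem()`, `recovery_experiment()`);
* file formats and a command-line front end (`read_scores_csv()`,
  `problem_to_json()`, `write_session_log()`, …; `inst/cli/fitradeoff.R`);
* a fully worked emergency-triage protocol selection case study
  (`triage_problem()`, `reproduce_case_study()`).

See `vignettes/fitradeoff-methods.Rmd` for the model, the numerical choices
and the synthetic-generator design.

## Worked example

The bundled case study selects a triage protocol among five candidates
(ATS, CTAS, ESI, MTS, SET) scored by specialists on four criteria.

```r
library(fitradeoff)

problem <- triage_problem()
problem
#> <decision_problem> 5 alternatives x 4 criteria
#>      Ease of Evaluation Ease of Implementation Ease of Use Guidelines
#> ATS                  24                      5          17         25
#> CTAS                 29                      8          20         15
#> ESI                   5                      5          13         15
#> MTS                  10                     12          22         13
#> SET                  15                     12          26         10
```

Ranking the criteria already eliminates two alternatives:

```r
space <- weight_space(triage_ranking())
space
#> <weight_space> 4 criteria, ranking: Guidelines > Ease of Use > Ease of Implementation > Ease of Evaluation
#>   3 linear constraints (0 from tradeoff statements), delta = 1e-06

set <- filter_potentially_optimal(space, problem)
set
#> <potential_optimal_set> 3 of 5 alternatives potentially optimal
#> # A tibble: 5 × 6
#>   alternative potentially_optimal    slack max_value weights   witness
#>   <chr>       <lgl>                  <dbl>     <dbl> <list>    <list>
#> 1 ATS         TRUE                 0.667       1.000 <dbl [4]> <dbl [4]>
#> 2 CTAS        FALSE               -0.00244    NA     <dbl [4]> <dbl [4]>
#> 3 ESI         FALSE               -0.392      NA     <dbl [4]> <dbl [4]>
#> 4 MTS         TRUE                 0.00833     0.631 <dbl [4]> <dbl [4]>
#> 5 SET         TRUE                 0.0703      0.667 <dbl [4]> <dbl [4]>

survivors(set)
#> [1] "ATS" "MTS" "SET"
```

Replaying the case study's recorded answers drives the session to a unique
recommendation in seven questions:

```r
session <- run_session(problem, triage_ranking(),
                       scripted_answers(triage_answer_script()))
session
#> <fitradeoff_session> recommendation: SET after 7 question(s) [unique_survivor]

session$log$bounds[[nrow(session$log)]]
#> # A tibble: 4 × 3
#>   criterion              lower upper
#>   <chr>                  <dbl> <dbl>
#> 1 Guidelines             0.306 0.339
#> 2 Ease of Use            0.261 0.282
#> 3 Ease of Implementation 0.216 0.239
#> 4 Ease of Evaluation     0.170 0.188
```

`autoplot()` has methods for weight bounds, survivor sets and sessions.

## Command line

A thin CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "fitradeoff.R", package = "fitradeoff"))')
Rscript "$CLI" reproduce-case-study --out out/
#> survivors after ranking: ATS, MTS, SET
#> recommendation: SET after 7 questions
```

Subcommands: `aggregate`, `filter`, `bounds`, `elicit`, `simulate`,
`reproduce-case-study`. Exit codes: 0 success, 2 usage error,
3 inconsistent preference information.

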