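# Bundled emergency-triage case study: selection of a triage protocol for
# Brazilian fixed emergency care units (UPAs).  Five candidate protocols
# (ATS, CTAS, MTS, ESI, SET) are scored by a triage specialist on 27
# subcriteria under 4 criteria; the criteria ranking and the recorded
# 7-answer elicitation session drive the pipeline to a recommendation.

triage_subcriteria <- function() {
  list(
    "Guidelines" = c(
      "Adult", "Pediatric", "Senior", "Pregnant", "Disabled", "Aggressive",
      "Alcoholics", "Nurses Attendance in Simple Cases (Guidelines)"
    ),
    "Ease of Evaluation" = c(
      "Medical History", "Pain Scale", "Use of Medications", "Allergies",
      "Physical Evaluation", "Mental Evaluation", "Vital Signs", "Re-triage"
    ),
    "Ease of Use" = c(
      "Use of Color Scale", "Maximum Waiting Time", "Maximum Triage Time",
      "Maximum Service Time", "Total Triage (5 levels)",
      "Partial Triage (2 + 3 levels)",
      "Nurses Attendance in Simple Cases (Ease of Use)",
      "Use of Computer and Software"
    ),
    "Ease of Implementation" = c(
      "Training of employees", "Need for computer", "Use of specific software"
    )
  )
}

#' Criteria tree of the triage case study
#'
#' The validated tree: 4 criteria and 27 subcriteria.  The label "Nurses
#' Attendance in Simple Cases" occurs under two criteria in the source
#' questionnaires; ids here carry a parenthesised parent suffix so each
#' subcriterion id is unique.
#'
#' @return A [criteria_tree()].
#' @export
triage_criteria_tree <- function() {
  subs <- triage_subcriteria()
  criteria_tree(tibble::tibble(
    criterion = rep(names(subs), lengths(subs)),
    subcriterion = unlist(subs, use.names = FALSE)
  ))
}

#' Protocol ranking of the triage case study criteria
#'
#' The importance order chosen by the decision makers.
#'
#' @return Character vector, most important criterion first.
#' @export
triage_ranking <- function() {
  c("Guidelines", "Ease of Use", "Ease of Implementation", "Ease of Evaluation")
}

#' @keywords internal
#' @noRd
triage_alternatives <- function() c("ATS", "CTAS", "MTS", "ESI", "SET")

#' @keywords internal
#' @noRd
triage_long <- function(values) {
  subs <- triage_subcriteria()
  leaves <- unlist(subs, use.names = FALSE)
  m <- matrix(values, ncol = 5, byrow = TRUE,
              dimnames = list(leaves, triage_alternatives()))
  tibble::tibble(
    alternative = rep(colnames(m), times = nrow(m)),
    criterion = rep(rep(names(subs), lengths(subs)), each = 5),
    subcriterion = rep(leaves, each = 5),
    score = as.numeric(t(m))
  )
}

#' Specialist scores of the triage case study
#'
#' The triage specialist's 0-5 rating of how well each protocol covers each
#' subcriterion, informed by the protocols' documentation and the nurses'
#' questionnaire.
#'
#' @return A tibble with columns `alternative`, `criterion`,
#'   `subcriterion`, `score` (135 rows).
#' @export
triage_specialist_scores <- function() {
  triage_long(c(
    # Guidelines                      ATS CTAS MTS ESI SET
    5, 5, 5, 5, 5,   # Adult
    5, 5, 1, 5, 0,   # Pediatric
    5, 0, 1, 0, 0,   # Senior
    5, 3, 0, 5, 0,   # Pregnant
    0, 2, 2, 0, 0,   # Disabled
    5, 0, 2, 0, 0,   # Aggressive
    0, 0, 2, 0, 0,   # Alcoholics
    0, 0, 0, 0, 5,   # Nurses Attendance in Simple Cases
    # Ease of Evaluation
    5, 5, 5, 5, 5,   # Medical History
    5, 5, 5, 0, 5,   # Pain Scale
    0, 5, 0, 0, 0,   # Use of Medications
    0, 5, 0, 0, 0,   # Allergies
    4, 4, 0, 0, 0,   # Physical Evaluation
    4, 0, 0, 0, 0,   # Mental Evaluation
    1, 0, 0, 0, 5,   # Vital Signs
    5, 5, 0, 0, 0,   # Re-triage
    # Ease of Use
    5, 5, 5, 5, 5,   # Use of Color Scale
    4, 4, 0, 0, 0,   # Maximum Waiting Time
    0, 0, 4, 4, 4,   # Maximum Triage Time
    5, 5, 5, 0, 5,   # Maximum Service Time
    3, 0, 3, 0, 3,   # Total Triage (5 levels)
    0, 4, 0, 4, 0,   # Partial Triage (2 + 3 levels)
    0, 0, 0, 0, 4,   # Nurses Attendance in Simple Cases
    0, 2, 5, 0, 5,   # Use of Computer and Software
    # Ease of Implementation
    5, 5, 5, 5, 5,   # Training of employees
    0, 3, 3, 0, 3,   # Need for computer
    0, 0, 4, 0, 4    # Use of specific software
  ))
}

#' Literature coverage of the five triage protocols
#'
#' How well each protocol's literature covers each subcriterion: 1 =
#' satisfactory citation, 0.5 = few citations, 0 = none.  Context for the
#' specialist's scoring; not an input to the decision matrix.
#'
#' @return A tibble with columns `alternative`, `criterion`,
#'   `subcriterion`, `score`.
#' @export
triage_protocol_features <- function() {
  triage_long(c(
    1, 1, 1, 1, 1,
    1, 1, 0.5, 1, 0,
    1, 0, 0.5, 0, 0,
    1, 0.5, 0, 1, 0,
    0, 0.5, 0.5, 0, 0,
    1, 0, 0.5, 0, 0,
    0, 0, 0.5, 0, 0,
    0, 0, 0, 0, 1,
    1, 1, 1, 1, 1,
    1, 1, 1, 0, 1,
    0, 1, 0, 0, 0,
    0, 1, 0, 0, 0,
    1, 1, 0, 0, 0,
    1, 0, 0, 0, 0,
    0.5, 0, 0, 0, 1,
    1, 1, 0, 0, 0,
    1, 1, 1, 1, 1,
    1, 1, 0, 0, 0,
    1, 1, 0, 0, 0,
    1, 1, 1, 0, 1,
    1, 0, 1, 0, 1,
    0, 1, 0, 1, 0,
    0, 0, 0, 0, 1,
    0, 0.5, 1, 0, 1,
    1, 1, 1, 1, 1,
    0, 1, 1, 0, 1,
    0, 0, 1, 0, 1
  ))
}

#' Nurse questionnaire means of the triage case study
#'
#' Mean five-point Likert relevance score given by the twenty triage nurses
#' to each subcriterion of the three operational criteria.  These means
#' informed the specialist's scoring qualitatively; they do not enter the
#' decision matrix numerically.
#'
#' @return A tibble with columns `criterion`, `subcriterion`, `mean_score`.
#' @export
triage_nurse_means <- function() {
  subs <- triage_subcriteria()
  subs <- subs[c("Guidelines", "Ease of Evaluation", "Ease of Use")]
  tibble::tibble(
    criterion = rep(names(subs), lengths(subs)),
    subcriterion = unlist(subs, use.names = FALSE),
    mean_score = c(
      4.90, 4.10, 4.65, 3.60, 3.95, 3.75, 3.75, 3.45,
      4.90, 4.55, 4.55, 4.95, 4.40, 4.40, 4.95, 4.65,
      4.65, 3.75, 3.90, 4.30, 2.60, 4.40, 4.00, 4.60
    )
  )
}

#' Criterion-level consequence table of the triage case study
#'
#' The decision matrix: each protocol's specialist scores summed over the
#' subcriteria of each criterion.
#'
#' @return A tibble with columns `alternative`, `criterion`, `score`.
#' @export
triage_consequences <- function() {
  aggregate_specialist_sum(triage_specialist_scores(), triage_criteria_tree())
}

#' Decision problem of the triage case study
#'
#' @return A [decision_problem()] with 5 alternatives and 4 criteria.
#' @export
triage_problem <- function() {
  decision_problem(triage_consequences())
}

#' Recorded elicitation session of the triage case study
#'
#' The pair/answer sequence of the seven questions answered by the decision
#' makers.  Answer "A" means the hypothetical consequence on the
#' higher-ranked criterion was preferred, "B" the best consequence on the
#' lower-ranked criterion; the on-screen hypothetical levels were not
#' recorded, so replays place them by the bisection strategy.
#'
#' @return A tibble with columns `higher`, `lower`, `answer`.
#' @export
triage_answer_script <- function() {
  tibble::tribble(
    ~higher,        ~lower,                   ~answer,
    "Guidelines",   "Ease of Evaluation",     "B",
    "Guidelines",   "Ease of Use",            "B",
    "Guidelines",   "Ease of Use",            "A",
    "Ease of Use",  "Ease of Implementation", "B",
    "Ease of Implementation", "Ease of Evaluation", "indifferent",
    "Ease of Use",  "Ease of Implementation", "A",
    "Guidelines",   "Ease of Use",            "B"
  )
}

#' Replay the full triage case study
#'
#' Runs the whole pipeline offline: aggregate the specialist scores into the
#' decision matrix, rank the criteria, filter the dominated protocols, and
#' replay the recorded seven-answer session to the final recommendation.
#'
#' @param delta Strictness separation of the weight space.
#' @param band Indifference band half-width.
#' @return A `fitradeoff_session`; its log's step 0 row holds the
#'   ranking-only survivor set and weight bounds.
#' @export
reproduce_case_study <- function(delta = 1e-6, band = 1e-6) {
  run_session(
    problem = triage_problem(),
    ranking = triage_ranking(),
    answers = scripted_answers(triage_answer_script()),
    delta = delta,
    band = band
  )
}
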