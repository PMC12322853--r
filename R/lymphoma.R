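#' The packaged nine-criterion lymphoma value framework
#'
#' Returns the reusable additive value framework for lymphoma therapies:
#' nine criteria spanning effectiveness (QALYs, median progression-free
#' survival, objective response rate), safety (serious adverse events
#' grade 3-4, treatment discontinuation rate due to adverse events), cost
#' (annual direct medical costs), convenience (dosage and administration),
#' clinical irreplaceability (number of alternative medicines with the
#' same indication and mechanism) and disease severity (mortality of
#' disease), with the elicited mean stakeholder weights 17.43, 16.11,
#' 14.39, 13.54, 11.83, 11.30, 7.08, 4.59 and 3.73 percent respectively.
#'
#' The mPFS value function carries the published linear segment of
#' 1.58 value-points per month with intercept 20.75 on the breakpoint
#' interval 20-35 months (provenance `"printed segment"`); its remaining
#' breakpoints, and the value functions of the other eight criteria, are
#' plausible placeholders flagged by provenance `"placeholder"` — replace
#' them via [build_value_function()] when elicited judgment matrices are
#' available.
#'
#' @return A [framework_model()].
#' @export
#' @examples
#' model <- packaged_lymphoma_model()
#' model
#' evaluate_value(model$value_functions$mpfs, 25.7)  # 61.356
packaged_lymphoma_model <- function() {
  crit <- list(
    qalys = criterion_spec("qalys", "quality-adjusted life years",
                           "benefit", "numeric", "QALYs"),
    mpfs = criterion_spec("mpfs", "median progression-free survival",
                          "benefit", "numeric", "months"),
    orr = criterion_spec("orr", "objective response rate",
                         "benefit", "numeric", "%"),
    sae34 = criterion_spec("sae34",
                           "incidence of serious adverse events (grade 3-4)",
                           "harm", "numeric", "%"),
    aetdr = criterion_spec("aetdr",
                           "treatment discontinuation rate due to adverse events",
                           "harm", "numeric", "%"),
    admc = criterion_spec("admc", "annual direct medical costs",
                          "harm", "numeric", "10k CNY/year"),
    dosage_admin = criterion_spec("dosage_admin", "dosage and administration",
                                  "benefit", "categorical"),
    n_alternatives = criterion_spec(
      "n_alternatives",
      "number of alternative medicines with the same indication and mechanism",
      "harm", "categorical"),
    mortality = criterion_spec("mortality", "mortality of disease",
                               "benefit", "numeric", "%")
  )
  weights <- c(qalys = 17.43, mpfs = 16.11, orr = 14.39, sae34 = 13.54,
               aetdr = 11.83, admc = 11.30, dosage_admin = 7.08,
               n_alternatives = 4.59, mortality = 3.73) / 100

  pl <- function(cid, levels, values, provenance = "placeholder") {
    build_value_function(reference_levels(crit[[cid]], levels),
                         structure(list(values = stats::setNames(values,
                                                                 paste0("L", 1:5)),
                                        anchors = c(top = "L1", bottom = "L5"),
                                        thresholds = numeric(6)),
                                   class = "cardinal_scale"),
                         provenance = provenance)
  }
  vfs <- list(
    qalys = pl("qalys", c(3.0, 2.5, 1.5, 0.8, 0.4), c(100, 75, 50, 25, 0)),
    # segment between L3 = 20 and L2 = 35 months reproduces the published
    # formula v(x) = 1.58 x + 20.75 exactly; outer breakpoints are
    # configuration, not published values
    mpfs = pl("mpfs", c(50, 35, 20, 10, 5),
              c(100, 1.58 * 35 + 20.75, 1.58 * 20 + 20.75, 25, 0),
              provenance = "printed segment"),
    orr = pl("orr", c(90, 75, 55, 35, 20), c(100, 75, 50, 25, 0)),
    sae34 = pl("sae34", c(8, 10, 25, 40, 48), c(100, 75, 50, 25, 0)),
    aetdr = pl("aetdr", c(1.6, 2, 8, 15, 18), c(100, 75, 50, 25, 0)),
    admc = pl("admc", c(64, 80, 150, 300, 360), c(100, 75, 50, 25, 0)),
    dosage_admin = categorical_value_function(
      crit$dosage_admin,
      c("oral fixed-dose" = 100, "oral with monitoring" = 75,
        "short outpatient infusion" = 50, "long infusion" = 25,
        "inpatient administration" = 0),
      provenance = "placeholder"),
    n_alternatives = categorical_value_function(
      crit$n_alternatives,
      c("0" = 100, "1" = 75, "2" = 50, "3" = 25, ">=4" = 0),
      provenance = "placeholder"),
    mortality = pl("mortality", c(60, 45, 30, 15, 5), c(100, 75, 50, 25, 0))
  )
  framework_model(crit, vfs, weights)
}

#' Candidate criteria for the lymphoma framework
#'
#' The 25 candidate criteria considered for the lymphoma framework, in the
#' rank order produced by the stakeholder importance survey (most
#' important first). The published record preserves the rank order and
#' which criteria cleared the 3.5-point importance threshold, but not the
#' individual survey scores; the `mean_score` column is therefore a
#' synthetic, evenly spaced stand-in consistent with that outcome (the
#' first 18 criteria above 3.5, the last seven at or below it).
#'
#' @return Data frame with columns `name` and `mean_score`.
#' @seealso [filter_by_importance()], [lymphoma_selection_ledger()]
#' @export
lymphoma_candidate_criteria <- function() {
  nm <- c(
    "median overall survival",
    "annual direct medical costs",
    "health-related quality of life",
    "improvement in tumor-related symptoms",
    "clinical irreplaceability",
    "median progression-free survival",
    "treatment discontinuation rate due to adverse events",
    "objective response rate",
    "complete response",
    "cost-utility",
    "duration of response",
    "incidence of serious adverse events (grade 3-4)",
    "unmet clinical needs",
    "severity of disease",
    "treatment-free interval",
    "tail of the curve",
    "innovation in therapeutic mechanisms",
    "changes in drug delivery modalities",
    "sequence of clinical treatments",
    "budget impact",
    "prevalence",
    "burden on caregivers",
    "equity",
    "increase in social productivity",
    "incidence of adverse events (grade 1-2)"
  )
  scores <- c(round(seq(4.8, 3.6, length.out = 18), 2),
              round(seq(3.5, 3.0, length.out = 7), 2))
  data.frame(name = nm, mean_score = scores)
}

#' The exclusion and substitution ledger of the lymphoma framework
#'
#' The second selection stage applied to the 18 criteria that cleared the
#' importance threshold: nine exclusions (reasons: sparse trial reporting,
#' redundancy with a higher-ranked criterion, lack of an operational
#' definition, or confounding by trial design) and four substitutions that
#' replace a construct with its operational measure.
#'
#' @return An object of class `selection_ledger` (see [selection_ledger()]).
#' @export
lymphoma_selection_ledger <- function() {
  selection_ledger(
    exclusions = data.frame(
      name = c("median overall survival",
               "improvement in tumor-related symptoms",
               "duration of response",
               "treatment-free interval",
               "complete response",
               "cost-utility",
               "unmet clinical needs",
               "tail of the curve",
               "innovation in therapeutic mechanisms"),
      reason = c("data-unavailable", "data-unavailable", "data-unavailable",
                 "data-unavailable", "redundant", "redundant",
                 "undefined/unquantifiable", "confounded",
                 "undefined/unquantifiable")),
    substitutions = data.frame(
      from = c("health-related quality of life",
               "changes in drug delivery modalities",
               "severity of disease",
               "clinical irreplaceability"),
      to = c("quality-adjusted life years",
             "dosage and administration",
             "mortality of disease",
             paste("number of alternative medicines with the same",
                   "indication and mechanism")))
  )
}
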