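# macbethvaf

Multi-criteria value assessment for therapies with the MACBETH method
(Measuring Attractiveness by a Categorical Based Evaluation Technique),
packaged around a reusable nine-criterion value framework for lymphoma
treatments.

## Who this is for

Health-technology-assessment analysts and decision scientists who elicit
value judgments from stakeholder panels (clinicians, pharmacists, health
economists, payers) and need to turn them into a quantitative, reusable
drug-scoring model: for reimbursement-list adjustment, hospital formulary
decisions, or comparative value studies of oncology therapies.

## The model

The framework is an additive multi-attribute value model. A therapy with
performance x = (x_1, ..., x_n) on n criteria scores

    V(x) = sum_j w_j * v_j(x_j),    sum_j w_j = 1,  v_j : performance -> [0, 100]

where each v_j is a piecewise-linear value function through five
performance reference levels (L1 best ... L5 worst, bracketing observed
drug performance by 20% beyond each extreme) and the w_j are swing
weights. Both the v_j breakpoint values and the weights come from MACBETH
elicitation: stakeholders judge, for pairs of reference levels (or of
hypothetical criterion-swing alternatives), the *difference of
attractiveness* on a seven-category semantic scale — no difference, very
weak, weak, moderate, strong, very strong, extreme. A linear program with
item values v_i and rising category thresholds t_1 < ... < t_6,

    judgment of category k on (i, j):  t_k <= v_i - v_j  (and <= t_{k+1} - 1 for k <= 5)

converts those ordinal judgments into a cardinal 0–100 interval scale (or
reports the judgments inconsistent, with a minimal set of conflicting
judgments to revisit). Inter-rater reliability of panel questionnaires is
quantified by a two-way random-effects, absolute-agreement intraclass
correlation coefficient.

The packaged lymphoma framework weighs quality-adjusted life years
(17.43%), median progression-free survival (16.11%), objective response
rate (14.39%), serious adverse events grade 3–4 (13.54%), treatment
discontinuation due to adverse events (11.83%), annual direct medical
costs (11.30%), dosage and administration (7.08%), number of alternative
medicines (4.59%) and mortality of disease (3.73%). The mPFS value
function carries its published linear segment v(x) = 1.58 x + 20.75
(value points per month); the other eight value functions are clearly
flagged placeholders that can be re-derived from elicited judgment
matrices with this package.

## Worked example

```r
library(macbethvaf)

# elicitation: qualitative judgments over the five mPFS reference levels
m <- read_judgment_matrix(system.file("extdata", "mpfs_judgments.csv",
                                      package = "macbethvaf"))
check_consistency(m)$consistent
#> [1] TRUE
derive_scale(m, top = "L1", bottom = "L5")$values
#>  L1  L2  L3  L4  L5
#> 100  75  50  25   0

# scoring a therapy with the packaged lymphoma framework
model <- packaged_lymphoma_model()
evaluate_value(model$value_functions$mpfs, 25.7)
#> [1] 61.356
score_alternative(model, list(qalys = 2.1, mpfs = 25.7, orr = 70,
                              sae34 = 20, aetdr = 6, admc = 150,
                              dosage_admin = "oral fixed-dose",
                              n_alternatives = "2", mortality = 30))
#>  criterion_id     performance  value weight contribution
#>         qalys             2.1 65.000 0.1743       11.330
#>          mpfs            25.7 61.356 0.1611        9.884
#>           orr              70 68.750 0.1439        9.893
#>         sae34              20 58.333 0.1354        7.898
#>         aetdr               6 58.333 0.1183        6.901
#>          admc             150 50.000 0.1130        5.650
#>  dosage_admin oral fixed-dose 100.000 0.0708        7.080
#> n_alternatives              2 50.000 0.0459        2.295
#>     mortality              30 50.000 0.0373        1.865
#> overall value score: 62.796
```

A therapy at 25.7 months of median progression-free survival earns 61.356
of 100 value points on that criterion; weighting all nine per-criterion
scores gives the overall value score of 62.8 for this profile. A
command-line front end (`inst/exec/macbethvaf`) exposes `score` and
`simulate` subcommands over the same functions.

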