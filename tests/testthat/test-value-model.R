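mk_scale <- function(values) {
  structure(list(values = stats::setNames(values, paste0("L", 1:5)),
                 anchors = c(top = "L1", bottom = "L5"),
                 thresholds = 1:6),
            class = "cardinal_scale")
}
mpfs_spec <- criterion_spec("mpfs", "median PFS", "benefit", units = "months")

test_that("value functions interpolate through their breakpoints", {
  rl <- reference_levels(mpfs_spec, c(50.2, 40, 25, 10, 5))
  vf <- build_value_function(rl, mk_scale(c(100, 80, 60, 20, 0)))
  # passes exactly through all five breakpoints
  expect_equal(evaluate_value(vf, c(50.2, 40, 25, 10, 5)),
               c(100, 80, 60, 20, 0))
  # slope of the 25-40 month segment
  slope <- (evaluate_value(vf, 40) - evaluate_value(vf, 25)) / (40 - 25)
  expect_equal(slope, (80 - 60) / (40 - 25))
  expect_equal(evaluate_value(vf, 32.5), 60 + (80 - 60) / 2)
})

test_that("flat segments are allowed, non-monotone values are not", {
  rl <- reference_levels(mpfs_spec, c(50, 40, 25, 10, 5))
  vf <- build_value_function(rl, mk_scale(c(100, 60, 60, 20, 0)))
  expect_equal(evaluate_value(vf, c(30, 35)), c(60, 60))
  expect_error(build_value_function(rl, mk_scale(c(100, 50, 60, 20, 0))),
               class = "mv_invariant_violation")
  expect_error(build_value_function(rl, mk_scale(c(90, 60, 50, 20, 0))),
               class = "mv_invalid_input")
})

test_that("evaluation clamps outside the elicited range and rejects bad input", {
  rl <- reference_levels(mpfs_spec, c(50, 40, 25, 10, 5))
  vf <- build_value_function(rl, mk_scale(c(100, 80, 60, 20, 0)))
  expect_equal(evaluate_value(vf, 60), 100)
  expect_equal(evaluate_value(vf, 1), 0)
  expect_true(all(evaluate_value(vf, seq(-10, 80, 0.5)) >= 0))
  expect_true(all(evaluate_value(vf, seq(-10, 80, 0.5)) <= 100))
  expect_error(evaluate_value(vf, Inf), class = "mv_invalid_input")
})

test_that("categorical value functions look up categories and reject unknowns", {
  dose <- criterion_spec("dose", kind = "categorical")
  vf <- categorical_value_function(dose, c(oral = 100, infusion = 40,
                                           inpatient = 0))
  expect_equal(evaluate_value(vf, c("infusion", "oral")), c(40, 100))
  expect_error(evaluate_value(vf, "topical"), class = "mv_invalid_input")
})

test_that("symmetric swings get equal weights", {
  m <- jm(c("s1", "s2", "s3", "baseline"),
          c("s1", "s1", "s2", "s1", "s2", "s3"),
          c("s2", "s3", "s3", "baseline", "baseline", "baseline"),
          c(0, 0, 0, 4, 4, 4))
  w <- derive_weights(m)
  expect_equal(unname(as.numeric(w)), rep(1 / 3, 3))
  expect_equal(sum(w), 1)
})

test_that("a stronger swing gets the larger weight", {
  m <- jm(c("sA", "sB", "baseline"),
          c("sA", "sA", "sB"), c("sB", "baseline", "baseline"),
          c(3, 5, 2))
  w <- derive_weights(m)
  expect_gt(w[["sA"]], w[["sB"]])
  expect_equal(sum(w), 1)
})

test_that("noiseless swing judgments recover the true weights", {
  truth <- c(sA = 50, sB = 30, sC = 20, baseline = 0)
  m <- generate_consistent_judgments(truth, thresholds = seq(5, 55, 10))
  w <- derive_weights(m)
  expect_identical(order(-as.numeric(w)), 1:3)
  expect_equal(unname(as.numeric(w)), c(0.5, 0.3, 0.2), tolerance = 1e-9)
})

test_that("weight derivation enforces its preconditions", {
  m <- jm(c("sA", "baseline"), "sA", "baseline", 3)
  expect_error(derive_weights(m), class = "mv_invalid_input")  # one swing
  m2 <- jm(c("sA", "sB", "base"),
           c("sA", "base"), c("sB", "sA"), c(2, 3))
  expect_error(derive_weights(m2, baseline = "base"),
               class = "mv_invalid_input")  # baseline preferred to a swing
  expect_error(derive_weights(m2, baseline = "nope"),
               class = "mv_invalid_input")
})

test_that("additive scores combine value and weight and hit the anchors", {
  specs <- list(eff = criterion_spec("eff", direction = "benefit"),
                tox = criterion_spec("tox", direction = "harm"))
  vfs <- list(
    eff = build_value_function(reference_levels(specs$eff, c(12, 10, 6, 2, 0)),
                               mk_scale(c(100, 75, 50, 25, 0))),
    tox = build_value_function(reference_levels(specs$tox, c(0.8, 1, 5, 9, 10.8)),
                               mk_scale(c(100, 75, 50, 25, 0))))
  model <- framework_model(specs, vfs, c(eff = 0.5, tox = 0.5))

  best <- score_alternative(model, list(eff = 12, tox = 0.8))
  expect_equal(attr(best, "overall"), 100)
  worst <- score_alternative(model, list(eff = 0, tox = 10.8))
  expect_equal(attr(worst, "overall"), 0)

  # equal weights over scores 80 and 40 average to 60
  br <- score_alternative(model, list(eff = 10.4, tox = 6.6))
  expect_equal(br$value, c(80, 40))
  expect_equal(attr(br, "overall"), 60)
  expect_equal(br$contribution, br$weight * br$value)

  expect_error(score_alternative(model, list(eff = 5)),
               class = "mv_invalid_input")
})

test_that("framework weights are normalised and validated", {
  specs <- list(a = criterion_spec("a"), b = criterion_spec("b"))
  vfs <- list(
    a = build_value_function(reference_levels(specs$a, c(5, 4, 3, 2, 1)),
                             mk_scale(c(100, 75, 50, 25, 0))),
    b = build_value_function(reference_levels(specs$b, c(5, 4, 3, 2, 1)),
                             mk_scale(c(100, 75, 50, 25, 0))))
  model <- framework_model(specs, vfs, c(a = 2, b = 2))
  expect_equal(unname(as.numeric(model$weights)), c(0.5, 0.5))
  expect_error(framework_model(specs, vfs, c(a = 1)),
               class = "mv_invalid_input")
  expect_error(framework_model(specs, vfs, c(a = -1, b = 2)),
               class = "mv_invalid_input")
})

test_that("model configuration round-trips through JSON losslessly", {
  model <- packaged_lymphoma_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_framework_model(model, path)
  model2 <- read_framework_model(path)
  expect_identical(names(model2$criteria), names(model$criteria))
  expect_equal(as.numeric(model2$weights), as.numeric(model$weights))
  for (cid in names(model$criteria)) {
    f1 <- model$value_functions[[cid]]; f2 <- model2$value_functions[[cid]]
    if (!is.null(f1$breakpoints)) {
      expect_equal(f2$breakpoints$performance, f1$breakpoints$performance)
      expect_equal(f2$breakpoints$value, f1$breakpoints$value)
    } else {
      expect_equal(f2$categories, f1$categories)
    }
    expect_identical(f2$provenance, f1$provenance)
  }
})

test_that("the packaged lymphoma model matches its published quantities", {
  model <- packaged_lymphoma_model()
  expect_identical(length(model$criteria), 9L)
  expect_equal(sum(model$weights), 1, tolerance = 1e-9)
  w <- 100 * as.numeric(model$weights)
  expect_equal(max(w), 17.43)
  expect_identical(names(model$weights)[which.max(w)], "qalys")
  expect_equal(min(w), 3.73)
  expect_identical(names(model$weights)[which.min(w)], "mortality")
  # published mPFS segment: 1.58 value-points/month + 20.75 at 25.7 months
  expect_equal(evaluate_value(model$value_functions$mpfs, 25.7), 61.356,
               tolerance = 1e-12)
  expect_identical(model$value_functions$mpfs$provenance, "printed segment")
  other <- setdiff(names(model$value_functions), "mpfs")
  expect_true(all(vapply(model$value_functions[other],
                         function(f) f$provenance, "") == "placeholder"))
})

test_that("scoring a performance table yields one overall score per drug", {
  model <- packaged_lymphoma_model()
  num_ids <- names(model$criteria)[
    vapply(model$criteria, function(cr) cr$kind == "numeric", TRUE)]
  ranges <- list(qalys = c(0.5, 2.8), mpfs = c(6, 48), orr = c(25, 88),
                 sae34 = c(9, 45), aetdr = c(2, 16), admc = c(70, 340),
                 mortality = c(6, 55))
  tab <- generate_performance_table(model$criteria[num_ids], 4, ranges,
                                    seed = 9)
  cats <- expand.grid(drug_id = unique(tab$drug_id),
                      criterion_id = c("dosage_admin", "n_alternatives"),
                      stringsAsFactors = FALSE)
  cats$value <- rep(c("oral fixed-dose", "2"), each = 4)
  tab <- rbind(tab, cats)
  res <- score_table(model, tab)
  overall <- attr(res, "overall")
  expect_identical(nrow(overall), 4L)
  expect_true(all(overall$score >= 0 & overall$score <= 100))
  expect_identical(nrow(res), 36L)
})
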