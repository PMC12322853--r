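# The MACBETH engine: consistency checking, scale derivation, rescaling.
# The exhaustive integer-grid search (grid_feasible) is the independent
# oracle for LP feasibility throughout.

test_that("consistency matches the exhaustive grid oracle on worked cases", {
  # two weak gaps composing to a strong difference: feasible
  m1 <- jm(c("A", "B", "C"), c("A", "B", "A"), c("B", "C", "C"), c(2, 2, 4))
  expect_true(grid_feasible(m1))
  expect_true(check_consistency(m1)$consistent)

  # an equality judgment alone is always satisfiable
  m2 <- jm(c("A", "B"), "A", "B", 0)
  r2 <- check_consistency(m2)
  expect_true(r2$consistent)
  expect_identical(nrow(r2$witness), 0L)

  # two strong gaps cannot compose to a very weak difference
  m3 <- jm(c("A", "B", "C"), c("A", "B", "A"), c("B", "C", "C"), c(4, 4, 1))
  expect_false(grid_feasible(m3))
  r3 <- check_consistency(m3)
  expect_false(r3$consistent)
  expect_gt(nrow(r3$witness), 0L)
})

test_that("cyclic strict preferences are inconsistent, not an error", {
  m <- jm(c("A", "B", "C"), c("A", "B", "C"), c("B", "C", "A"), c(2, 2, 2))
  r <- check_consistency(m)
  expect_false(r$consistent)
  expect_false(grid_feasible(m))
})

test_that("consistency check rejects matrices without judgments", {
  m <- judgment_matrix(c("A", "B"), NULL)
  expect_error(check_consistency(m), class = "mv_invalid_input")
})

test_that("removing the witness restores feasibility", {
  set.seed(101)
  found <- 0L
  for (q in 1:40) {
    m <- random_judgment_matrix(4)
    if (is.null(m)) next
    r <- check_consistency(m)
    if (r$consistent) next
    found <- found + 1L
    keep <- !(paste(m$judgments$i, m$judgments$j) %in%
                paste(r$witness$i, r$witness$j))
    m2 <- judgment_matrix(m$items, m$judgments[keep, ])
    if (nrow(m2$judgments) == 0L) next
    expect_true(check_consistency(m2)$consistent)
  }
  expect_gt(found, 3L)
})

test_that("LP feasibility equals grid feasibility on random small matrices", {
  set.seed(7)
  tested <- 0L
  for (q in 1:150) {
    m <- random_judgment_matrix(sample(2:4, 1))
    if (is.null(m)) next
    tested <- tested + 1L
    expect_identical(check_consistency(m)$consistent, grid_feasible(m),
                     info = paste(utils::capture.output(print(m)),
                                  collapse = "\n"))
  }
  expect_gt(tested, 100L)
})

test_that("monotone repair: dropping any judgment keeps a consistent matrix consistent", {
  set.seed(11)
  checked <- 0L
  for (q in 1:40) {
    m <- random_judgment_matrix(4)
    if (is.null(m) || nrow(m$judgments) < 2L) next
    if (!check_consistency(m)$consistent) next
    for (drop in seq_len(nrow(m$judgments))) {
      m2 <- judgment_matrix(m$items, m$judgments[-drop, ])
      expect_true(check_consistency(m2)$consistent)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 10L)
})

test_that("two items with a strict judgment anchor to 100 and 0", {
  m <- jm(c("A", "B"), "A", "B", 3)
  s <- derive_scale(m, "A", "B")
  expect_equal(unname(s$values), c(100, 0))
})

test_that("equal category gaps place the middle item at the midpoint", {
  m <- jm(c("A", "B", "C"), c("A", "B", "A"), c("B", "C", "C"), c(2, 2, 4))
  s <- derive_scale(m, "A", "C")
  expect_equal(unname(s$values[["B"]]), 50)
  expect_valid_scale(s, m)
})

test_that("derive_scale is deterministic", {
  m <- jm(c("A", "B", "C", "D"),
          c("A", "A", "A", "B", "B", "C"),
          c("B", "C", "D", "C", "D", "D"),
          c(2, 4, 6, 2, 4, 2))
  expect_identical(derive_scale(m, "A", "D"), derive_scale(m, "A", "D"))
})

test_that("derive_scale enforces its preconditions", {
  m <- jm(c("A", "B", "C"), c("A", "B", "A"), c("B", "C", "C"), c(2, 2, 4))
  expect_error(derive_scale(m, "A", "A"), class = "mv_invalid_input")
  expect_error(derive_scale(m, "A", "Z"), class = "mv_invalid_input")
  expect_error(derive_scale(m, "B", "C"), class = "mv_invalid_input")  # B dominated
  expect_error(derive_scale(m, "A", "B"), class = "mv_invalid_input")  # B dominates C

  bad <- jm(c("A", "B", "C"), c("A", "B", "A"), c("B", "C", "C"), c(4, 4, 1))
  err <- tryCatch(derive_scale(bad, "A", "C"), condition = identity)
  expect_s3_class(err, "mv_inconsistent")
  expect_s3_class(err$report, "consistency_report")
  expect_false(err$report$consistent)
})

test_that("noiseless round trip recovers the true ranking within a category width", {
  truth <- c(A = 100, B = 70, C = 30, D = 0)
  m <- generate_consistent_judgments(truth, thresholds = seq(15, 90, 15))
  expect_true(check_consistency(m)$consistent)
  s <- derive_scale(m, "A", "D")
  expect_identical(order(-s$values), order(-truth))
  # each recovered value within one category width (15 true units -> the
  # judgments cannot resolve finer than that)
  expect_true(all(abs(s$values - truth) <= 15 + 1e-9))
})

test_that("rescale is affine and preserves difference ratios", {
  m <- jm(c("A", "B", "C"), c("A", "B", "A"), c("B", "C", "C"), c(2, 2, 4))
  s <- derive_scale(m, "A", "C")
  expect_equal(rescale(s, 100, 0)$values, s$values)
  s01 <- rescale(s, 1, 0)
  expect_equal(unname(s01$values), c(1, 0.5, 0))
  s2 <- rescale(s, 37, 12)
  ratio <- function(v) (v[["A"]] - v[["B"]]) / (v[["B"]] - v[["C"]])
  expect_equal(ratio(s2$values), ratio(s$values))
  expect_error(rescale(s, 0, 0), class = "mv_invalid_input")
  expect_error(rescale(s, 0, 10), class = "mv_invalid_input")
})
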