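test_that("generated judgments bin true differences and are always consistent", {
  m <- generate_consistent_judgments(c(A = 100, B = 50, C = 0),
                                     thresholds = seq(10, 60, 10))
  expect_true(check_consistency(m)$consistent)
  # d = 50 falls in the band [t5, t6) -> very strong; d = 100 beyond t6
  codes <- stats::setNames(m$judgments$code,
                           paste(m$judgments$i, m$judgments$j))
  expect_identical(codes[["A B"]], 5L)
  expect_identical(codes[["B C"]], 5L)
  expect_identical(codes[["A C"]], 6L)
})

test_that("ties generate category 0 and sub-threshold gaps category 1", {
  m <- generate_consistent_judgments(c(A = 10, B = 10, C = 9),
                                     thresholds = seq(5, 30, 5))
  codes <- stats::setNames(m$judgments$code,
                           paste(m$judgments$i, m$judgments$j))
  expect_identical(codes[["A B"]], 0L)
  expect_identical(codes[["A C"]], 1L)  # gap 1 below t1 = 5: weakest strict
  expect_error(generate_consistent_judgments(c(A = 1, B = 0),
                                             thresholds = c(1, 1, 2, 3, 4, 5)),
               class = "mv_invalid_input")
})

test_that("noiseless round trips reproduce the ground-truth ranking", {
  set.seed(19)
  for (q in 1:200) {
    n <- sample(3:5, 1)
    truth <- stats::setNames(sort(stats::runif(n, 0, 100), decreasing = TRUE),
                             LETTERS[1:n])
    m <- generate_consistent_judgments(truth, thresholds = seq(15, 90, 15))
    expect_true(check_consistency(m)$consistent)
    s <- derive_scale(m, top = "A", bottom = LETTERS[n])
    expect_identical(order(-s$values), seq_len(n))
  }
})

test_that("perturbation is seeded, bounded to one category, and identity at p = 0", {
  m <- generate_consistent_judgments(c(A = 90, B = 50, C = 10),
                                     thresholds = seq(10, 60, 10))
  expect_identical(perturb_judgments(m, 0, seed = 4)$judgments, m$judgments)
  p1a <- perturb_judgments(m, 1, seed = 4)
  expect_identical(p1a$judgments, perturb_judgments(m, 1, seed = 4)$judgments)
  expect_true(all(abs(p1a$judgments$code - m$judgments$code) == 1L))
  m2 <- jm(c("A", "B"), "A", "B", 0)
  expect_identical(perturb_judgments(m2, 1, seed = 1)$judgments$code, 1L)
  m6 <- jm(c("A", "B"), "A", "B", 6)
  expect_identical(perturb_judgments(m6, 1, seed = 1)$judgments$code, 5L)
})

test_that("consistency degrades with the judgment flip probability", {
  # probed in the small-noise regime, where every additional flip chance
  # adds conflict risk; at large flip probabilities a coherent shift of
  # all judgments can remain consistent, so the trend is not global
  truth <- stats::setNames(c(90, 60, 30, 0), LETTERS[1:4])
  m <- generate_consistent_judgments(truth, thresholds = seq(15, 90, 15))
  rate <- vapply(c(0, 0.15, 0.3), function(p) {
    ok <- vapply(1:500, function(s) {
      check_consistency(perturb_judgments(m, p, seed = s))$consistent
    }, logical(1))
    mean(ok)
  }, numeric(1))
  expect_equal(rate[1], 1)
  expect_true(all(diff(rate) < 0))
})

test_that("rater panels have the right shape, seeding and noiseless limit", {
  p <- generate_rater_panel(c(a = 1, b = 2, c = 3), rater_sd = 0.5,
                            n_raters = 6, seed = 8)
  expect_identical(dim(p), c(6L, 3L))
  expect_identical(colnames(p), c("a", "b", "c"))
  expect_identical(p, generate_rater_panel(c(a = 1, b = 2, c = 3), 0.5, 6, 8))
  p0 <- generate_rater_panel(c(5, 10, 20, 40), rater_sd = 0, n_raters = 3,
                             seed = 2)
  expect_equal(icc(p0)$estimate, 1)
  expect_error(generate_rater_panel(1:3, 1, n_raters = 1, seed = 1),
               class = "mv_invalid_input")
})

test_that("performance tables respect ranges and feed the level rule", {
  specs <- list(sae = criterion_spec("sae", direction = "harm"),
                mpfs = criterion_spec("mpfs", direction = "benefit"))
  ranges <- list(sae = c(5, 40), mpfs = c(10, 50))
  expect_identical(nrow(generate_performance_table(specs, 0, ranges, 1)), 0L)
  tab <- generate_performance_table(specs, 8, ranges, seed = 31)
  expect_identical(tab, generate_performance_table(specs, 8, ranges, seed = 31))
  for (cid in names(specs)) {
    v <- tab$value[tab$criterion_id == cid]
    expect_true(all(v >= ranges[[cid]][1] & v <= ranges[[cid]][2]))
    rl <- compute_reference_levels(specs[[cid]], v)
    lo <- min(v); hi <- max(v)
    expect_true(min(rl$levels) == 0.8 * lo && max(rl$levels) == 1.2 * hi)
  }
  expect_error(generate_performance_table(specs, 2, list(sae = c(5, 40)), 1),
               class = "mv_invalid_input")
})
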