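# Shared helpers for the test suite.

# Shorthand judgment-matrix constructor.
jm <- function(items, i, j, code) {
  judgment_matrix(items, data.frame(i = i, j = j, code = code))
}

# Random judgment matrix over n items: each unordered pair judged with
# probability p_pair, random orientation, category uniform in 0..6.
# Mixes consistent and inconsistent systems.
random_judgment_matrix <- function(n, p_pair = 0.8) {
  items <- LETTERS[seq_len(n)]
  prs <- t(utils::combn(n, 2L))
  prs <- prs[stats::runif(nrow(prs)) < p_pair, , drop = FALSE]
  if (!nrow(prs)) return(NULL)
  swap <- stats::runif(nrow(prs)) < 0.5
  ii <- ifelse(swap, prs[, 2], prs[, 1])
  jj <- ifelse(swap, prs[, 1], prs[, 2])
  jm(items, items[ii], items[jj], sample(0:6, nrow(prs), replace = TRUE))
}

# Anchor candidates of a matrix: top = an item never judged strictly less
# attractive, bottom = an item never judged strictly more attractive.
anchor_candidates <- function(m) {
  jd <- m$judgments
  list(top = setdiff(m$items, jd$j[jd$code > 0L])[1L],
       bottom = setdiff(m$items, jd$i[jd$code > 0L])[1L])
}

# Check every cardinal_scale invariant against its source matrix.
expect_valid_scale <- function(scale, m, tol = 1e-9) {
  expect_equal(unname(scale$values[scale$anchors[["top"]]]), 100)
  expect_equal(unname(scale$values[scale$anchors[["bottom"]]]), 0)
  expect_true(all(scale$values >= 0 & scale$values <= 100))
  expect_true(all(diff(scale$thresholds) > 0))
  jd <- m$judgments
  for (r in seq_len(nrow(jd))) {
    di <- scale$values[[jd$i[r]]] - scale$values[[jd$j[r]]]
    if (jd$code[r] > 0L) expect_gt(di, 0) else expect_lt(abs(di), tol)
  }
}
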