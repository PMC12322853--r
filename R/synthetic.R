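# Seeded generators for ground-truth test data: judgment matrices binned
# from a known scale, noise-perturbed variants, rater panels and drug
# performance tables. All generators take an explicit seed and restore the
# caller's RNG state (no global side effects).

#' Generate a consistent judgment matrix from a known scale
#'
#' For every ordered pair with `value(i) >= value(j)`, the judgment
#' category is the bin of the true difference under the thresholds:
#' category 0 for an exact tie, otherwise the largest `k` with
#' `difference >= t_k`, at least 1 (a positive difference below `t_1`
#' is a very weak, not a null, difference). Matrices built this way are
#' always consistent, and noiseless round trips through [derive_scale()]
#' reproduce the true ranking.
#'
#' @param true_values Named numeric vector of true item values.
#' @param thresholds Strictly increasing numeric vector of length 6
#'   (category boundaries on the true difference scale).
#' @return A [judgment_matrix()].
#' @export
#' @examples
#' m <- generate_consistent_judgments(c(A = 100, B = 50, C = 0),
#'                                    thresholds = seq(10, 60, 10))
#' check_consistency(m)$consistent
generate_consistent_judgments <- function(true_values, thresholds) {
  if (is.null(names(true_values)) || anyDuplicated(names(true_values))) {
    stop_invalid("true_values must be uniquely named")
  }
  if (length(thresholds) != 6L || any(diff(thresholds) <= 0)) {
    stop_invalid("thresholds must be 6 strictly increasing values")
  }
  items <- names(true_values)
  n <- length(items)
  recs <- list()
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      d <- true_values[[a]] - true_values[[b]]
      i <- if (d >= 0) a else b
      j <- if (d >= 0) b else a
      d <- abs(d)
      code <- if (d == 0) 0L else max(1L, findInterval(d, thresholds))
      code <- min(code, 6L)
      recs[[length(recs) + 1L]] <- data.frame(i = items[i], j = items[j],
                                              code = code)
    }
  }
  judgment_matrix(items, do.call(rbind, recs))
}

#' Perturb a judgment matrix with ordinal noise
#'
#' Each judgment independently moves one category up or down with the
#' given probability, the minimal perturbation that respects the ordinal
#' judgment scale. Moves falling outside 0..6 are reflected (0 becomes 1,
#' 6 becomes 5), so a perturbed judgment always differs by exactly one
#' category.
#'
#' @param matrix A [judgment_matrix()].
#' @param flip_prob Probability in `[0, 1]` that a judgment moves.
#' @param seed Integer seed; same seed, same output.
#' @return A [judgment_matrix()].
#' @export
perturb_judgments <- function(matrix, flip_prob, seed) {
  stopifnot(inherits(matrix, "judgment_matrix"))
  if (!is_scalar_number(flip_prob) || flip_prob < 0 || flip_prob > 1) {
    stop_invalid("flip_prob must be a probability")
  }
  jd <- matrix$judgments
  withr::with_seed(seed, {
    move <- stats::runif(nrow(jd)) < flip_prob
    dir <- sample(c(-1L, 1L), nrow(jd), replace = TRUE)
    prop <- jd$code + dir
    prop[prop < 0L] <- 1L   # reflect at the ends
    prop[prop > 6L] <- 5L
    jd$code[move] <- prop[move]
  })
  judgment_matrix(matrix$items, jd)
}

#' Generate a synthetic rater panel
#'
#' Each rating is the true item mean plus independent Gaussian rater
#' noise: `x[r, i] = mean_i + e`, `e ~ N(0, rater_sd^2)`.
#'
#' @param item_means Numeric vector of true item means.
#' @param rater_sd Non-negative noise standard deviation.
#' @param n_raters Number of raters (>= 2).
#' @param seed Integer seed.
#' @return Numeric matrix `n_raters` x `length(item_means)`.
#' @seealso [icc()]
#' @export
generate_rater_panel <- function(item_means, rater_sd, n_raters, seed) {
  if (n_raters < 2L) stop_invalid("need at least 2 raters")
  if (!is_scalar_number(rater_sd) || rater_sd < 0) {
    stop_invalid("rater_sd must be non-negative")
  }
  n <- length(item_means)
  withr::with_seed(seed, {
    noise <- matrix(stats::rnorm(n_raters * n, sd = rater_sd), n_raters, n)
  })
  m <- matrix(rep(as.numeric(item_means), each = n_raters), n_raters, n)
  out <- m + noise
  dimnames(out) <- list(paste0("rater", seq_len(n_raters)),
                        names(item_means) %||% paste0("item", seq_len(n)))
  out
}

#' Generate a synthetic drug performance table
#'
#' Uniform draws within per-criterion ranges; the output has the standard
#' performance-table layout (`drug_id`, `criterion_id`, `value`) consumed
#' by [reference_levels_from_table()] and [score_table()].
#'
#' @param criteria Named list of [criterion_spec()] (numeric criteria).
#' @param n_drugs Number of drugs (0 gives an empty table).
#' @param ranges Named list of `c(min, max)` per criterion id.
#' @param seed Integer seed.
#' @return Data frame `drug_id`, `criterion_id`, `value`.
#' @export
generate_performance_table <- function(criteria, n_drugs, ranges, seed) {
  if (n_drugs < 0) stop_invalid("n_drugs must be non-negative")
  missing_r <- setdiff(names(criteria), names(ranges))
  if (length(missing_r)) {
    stop_invalid(sprintf("no range for: %s", paste(missing_r, collapse = ", ")))
  }
  if (n_drugs == 0L) {
    return(data.frame(drug_id = character(), criterion_id = character(),
                      value = numeric()))
  }
  for (cid in names(criteria)) {
    r <- ranges[[cid]]
    if (length(r) != 2L || r[1] >= r[2]) {
      stop_invalid(sprintf("invalid range for %s", cid))
    }
    if (criteria[[cid]]$direction == "harm" && r[1] < 0) {
      stop_invalid(sprintf("harm criterion %s cannot have negative range", cid))
    }
  }
  drugs <- sprintf("drug%02d", seq_len(n_drugs))
  withr::with_seed(seed, {
    rows <- lapply(names(criteria), function(cid) {
      r <- ranges[[cid]]
      data.frame(drug_id = drugs, criterion_id = cid,
                 value = stats::runif(n_drugs, r[1], r[2]))
    })
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$drug_id, out$criterion_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
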