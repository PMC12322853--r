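#' Intraclass correlation coefficient for a rater panel
#'
#' Two-way random-effects, absolute-agreement ICC from the two-way ANOVA
#' mean squares of a complete raters-by-items rating grid, with an
#' F-distribution-based confidence interval (McGraw-Wong). The default is
#' the average-measures form ICC(A,k) — the reliability of the panel mean —
#' since every rater rates every item and panel-level reliability is the
#' quantity of interest; the single-measures form ICC(A,1) is available via
#' `type = "single"`. The model form label is always part of the result.
#'
#' @param ratings Numeric matrix, raters in rows, items in columns; at
#'   least 2 of each, no missing cells.
#' @param confidence Confidence level of the interval (default 0.95).
#' @param type `"average"` (ICC(A,k), default) or `"single"` (ICC(A,1)).
#' @return An object of class `icc_result`: list with `estimate`, `ci`
#'   (lower, upper), `confidence`, `form` (label), `band`
#'   (`poor`/`moderate`/`good`, see [interpret_icc()]), and the mean
#'   squares `ms` (MSR items, MSC raters, MSE residual).
#' @details With `n` items and `k` raters, `MSR`, `MSC` and `MSE` the item,
#'   rater and residual mean squares:
#'   `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` and
#'   `ICC(A,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)`. The interval for
#'   ICC(A,1) uses the Satterthwaite-style degrees of freedom of McGraw &
#'   Wong; the average-measures interval is its Spearman-Brown step-up.
#'   When the residual and rater mean squares are exactly zero (perfect
#'   agreement) the estimate and both interval ends are 1, their analytic
#'   limit.
#' @export
#' @examples
#' set.seed(1)
#' panel <- generate_rater_panel(c(10, 20, 30, 40), rater_sd = 2,
#'                               n_raters = 5, seed = 1)
#' icc(panel)
icc <- function(ratings, confidence = 0.95, type = c("average", "single")) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  if (!is.numeric(ratings) || anyNA(ratings) || !all(is.finite(ratings))) {
    stop_invalid("ratings must be a complete finite numeric matrix")
  }
  k <- nrow(ratings)  # raters
  n <- ncol(ratings)  # items
  if (k < 2L || n < 2L) stop_invalid("need at least 2 raters and 2 items")
  gm <- mean(ratings)
  mi <- colMeans(ratings)
  mr <- rowMeans(ratings)
  if (max(mi) - min(mi) <= 0) {
    stop_degenerate("zero between-item variance: ICC undefined")
  }
  msr <- k * sum((mi - gm)^2) / (n - 1)
  msc <- n * sum((mr - gm)^2) / (k - 1)
  mse <- sum((ratings - outer(mr, mi, "+") + gm)^2) / ((n - 1) * (k - 1))

  icc_a1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icc_ak <- (msr - mse) / (msr + (msc - mse) / n)

  if (mse <= 0 && msc <= 0) {
    ci1 <- c(1, 1)  # analytic limit of the F interval at perfect agreement
  } else {
    alpha <- 1 - confidence
    fj <- msc / mse
    vn <- (k - 1) * (n - 1) *
      (k * icc_a1 * fj + n * (1 + (k - 1) * icc_a1) - k * icc_a1)^2
    vd <- (n - 1) * k^2 * icc_a1^2 * fj^2 +
      (n * (1 + (k - 1) * icc_a1) - k * icc_a1)^2
    v <- vn / vd
    fu <- stats::qf(1 - alpha / 2, n - 1, v)
    fl <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fu * mse) /
      (fu * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fl * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fl * msr)
    ci1 <- c(lo, hi)
  }
  sb <- function(r) r * k / (1 + r * (k - 1))  # Spearman-Brown step-up
  if (type == "average") {
    est <- icc_ak; ci <- sb(ci1); form <- "ICC(A,k): two-way random, absolute agreement, average measures"
  } else {
    est <- icc_a1; ci <- ci1; form <- "ICC(A,1): two-way random, absolute agreement, single measures"
  }
  structure(list(estimate = est, ci = stats::setNames(ci, c("lower", "upper")),
                 confidence = confidence, form = form,
                 band = interpret_icc(est),
                 ms = c(MSR = msr, MSC = msc, MSE = mse),
                 n_items = n, n_raters = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, digits = 3, ...) {
  cat(sprintf("%s\n", x$form))
  cat(sprintf("estimate %.3f (%d%% CI %.3f-%.3f), %d raters x %d items: %s reliability\n",
              x$estimate, round(100 * x$confidence), x$ci[["lower"]],
              x$ci[["upper"]], x$n_raters, x$n_items, x$band))
  invisible(x)
}

#' Interpret an ICC estimate
#'
#' Conventional reliability bands: below 0.4 poor, above 0.75 good,
#' moderate in between.
#'
#' @param estimate Finite ICC value.
#' @return `"poor"`, `"moderate"` or `"good"`.
#' @export
#' @examples
#' interpret_icc(0.944)
interpret_icc <- function(estimate) {
  if (!is_scalar_number(estimate)) stop_invalid("estimate must be finite")
  if (estimate < 0.4) "poor" else if (estimate > 0.75) "good" else "moderate"
}

#' Read a rating matrix from CSV
#'
#' One row per rater (first column `rater`), one column per item.
#'
#' @param path Path to the CSV file.
#' @return Numeric matrix raters x items with rater row names.
#' @export
read_rating_matrix <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  raters <- if ("rater" %in% names(raw)) raw$rater else rownames(raw)
  m <- as.matrix(raw[, setdiff(names(raw), "rater"), drop = FALSE])
  if (!is.numeric(m)) stop_invalid("ratings must be numeric")
  rownames(m) <- raters
  m
}
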