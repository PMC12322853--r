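#' Define a criterion
#'
#' @param id Short unique token (e.g. `"mpfs"`).
#' @param name Human-readable name.
#' @param direction `"benefit"` (higher performance is better) or `"harm"`
#'   (lower is better).
#' @param kind `"numeric"` or `"categorical"`.
#' @param units Free-text units (e.g. `"months"`).
#' @return An object of class `criterion_spec`.
#' @export
#' @examples
#' criterion_spec("mpfs", "median progression-free survival",
#'                "benefit", units = "months")
criterion_spec <- function(id, name = id, direction = c("benefit", "harm"),
                           kind = c("numeric", "categorical"), units = "") {
  direction <- match.arg(direction)
  kind <- match.arg(kind)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, name = name, direction = direction,
                 kind = kind, units = units),
            class = "criterion_spec")
}

#' @export
print.criterion_spec <- function(x, ...) {
  cat(sprintf("criterion %s: %s (%s, %s%s)\n", x$id, x$name,
              x$direction, x$kind,
              if (nzchar(x$units)) paste0(", ", x$units) else ""))
  invisible(x)
}

#' Build the five performance reference levels for a criterion
#'
#' Reference levels anchor the value function of a numeric criterion. They
#' bracket the observed drug performance data: the best observed
#' performance becomes Level 2, the worst observed becomes Level 4, the
#' median becomes Level 3, and Levels 1 and 5 extend 20% beyond the
#' respective extremes. Concretely, for a harm criterion (lower is better)
#' `L1 = 0.8 * min`, `L2 = min`, `L3 = median`, `L4 = max`,
#' `L5 = 1.2 * max`; for a benefit criterion the rule is mirrored
#' (`L1 = 1.2 * max`, ..., `L5 = 0.8 * min`). Level 1 is always the most
#' attractive performance and Level 5 the least.
#'
#' @param criterion A [criterion_spec()] with `kind = "numeric"`.
#' @param values Numeric vector of observed performances (length >= 2, all
#'   finite; non-negative for harm criteria).
#' @return An object of class `reference_levels`: list with `criterion` and
#'   `levels`, a named numeric `c(L1 = ..., ..., L5 = ...)`, strictly
#'   monotone in performance.
#' @details The median of an even-sized sample is the midpoint of the two
#'   central order statistics. If the sample median coincides with an
#'   extreme (heavily skewed data), Level 3 is nudged to the midpoint of
#'   the observed range so the five levels stay strictly monotone.
#' @export
#' @examples
#' sae <- criterion_spec("sae34", "serious adverse events, grade 3-4",
#'                       "harm", units = "%")
#' compute_reference_levels(sae, c(10, 20, 30))
compute_reference_levels <- function(criterion, values) {
  stopifnot(inherits(criterion, "criterion_spec"))
  if (criterion$kind != "numeric") {
    stop_invalid(paste0("reference levels are computed for numeric criteria; ",
                        "categorical criteria enumerate their levels in ",
                        "configuration"))
  }
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop_invalid("need at least 2 performance observations")
  }
  if (!all(is.finite(values))) stop_invalid("performance values must be finite")
  if (criterion$direction == "harm" && any(values < 0)) {
    stop_invalid("harm criterion performances must be non-negative")
  }
  lo <- min(values); hi <- max(values)
  if (hi - lo <= 0) {
    stop_degenerate("zero-width performance range cannot yield 5 distinct levels")
  }
  med <- stats::median(values)
  if (med <= lo || med >= hi) med <- (lo + hi) / 2  # keep strict monotonicity
  lv <- if (criterion$direction == "harm") {
    c(L1 = 0.8 * lo, L2 = lo, L3 = med, L4 = hi, L5 = 1.2 * hi)
  } else {
    c(L1 = 1.2 * hi, L2 = hi, L3 = med, L4 = lo, L5 = 0.8 * lo)
  }
  d <- diff(lv)
  if (!(all(d < 0) || all(d > 0))) {
    # reachable only for harm data touching 0 (0.8 * 0 == 0)
    stop_degenerate("levels are not strictly monotone for these data")
  }
  structure(list(criterion = criterion, levels = lv),
            class = "reference_levels")
}

#' @export
print.reference_levels <- function(x, digits = 4, ...) {
  cat(sprintf("reference levels for %s (%s):\n", x$criterion$id,
              x$criterion$direction))
  print(round(x$levels, digits))
  invisible(x)
}

#' Manually specify reference levels
#'
#' For criteria whose levels come from configuration rather than from the
#' bracketing rule (or to reproduce an existing framework).
#'
#' @param criterion A [criterion_spec()].
#' @param levels Numeric vector of length 5 (`L1` most attractive), strictly
#'   monotone in the direction of the criterion.
#' @return A `reference_levels` object.
#' @export
reference_levels <- function(criterion, levels) {
  stopifnot(inherits(criterion, "criterion_spec"))
  levels <- as.numeric(levels)
  if (length(levels) != 5L || !all(is.finite(levels))) {
    stop_invalid("exactly five finite levels are required")
  }
  d <- diff(levels)
  ok <- if (criterion$direction == "harm") all(d > 0) else all(d < 0)
  if (!ok) {
    stop_invalid("levels must be strictly monotone: L1 most attractive")
  }
  structure(list(criterion = criterion,
                 levels = stats::setNames(levels, paste0("L", 1:5))),
            class = "reference_levels")
}

#' Compute reference levels for many criteria from a performance table
#'
#' @param performance Data frame with columns `drug_id`, `criterion_id`,
#'   `value` (one row per observation), as read from the standard CSV.
#' @param criteria Named list of [criterion_spec()], indexed by id.
#' @return Named list of `reference_levels`, one per criterion present.
#' @export
reference_levels_from_table <- function(performance, criteria) {
  need <- c("drug_id", "criterion_id", "value")
  if (!all(need %in% names(performance))) {
    stop_invalid("performance table needs columns drug_id, criterion_id, value")
  }
  ids <- unique(performance$criterion_id)
  unknown <- setdiff(ids, names(criteria))
  if (length(unknown)) {
    stop_invalid(sprintf("no criterion spec for: %s",
                         paste(unknown, collapse = ", ")))
  }
  out <- lapply(ids, function(cid) {
    compute_reference_levels(criteria[[cid]],
                             performance$value[performance$criterion_id == cid])
  })
  stats::setNames(out, ids)
}

#' Write reference levels to CSV
#'
#' Emits columns `criterion_id`, `level` (1-5), `performance_value`.
#'
#' @param x A `reference_levels` object or a named list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference_levels <- function(x, path) {
  if (inherits(x, "reference_levels")) x <- list(x)
  rows <- do.call(rbind, lapply(x, function(rl) {
    data.frame(criterion_id = rl$criterion$id, level = 1:5,
               performance_value = unname(rl$levels))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
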