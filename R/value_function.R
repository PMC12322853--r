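#' Build a piecewise-linear value function
#'
#' Joins the five performance reference levels of a numeric criterion with
#' the 0-100 cardinal values elicited for them: the value function is the
#' piecewise-linear interpolant through the five breakpoints
#' `(performance of L_k, value of L_k)`, anchored at `value(L1) = 100` and
#' `value(L5) = 0`.
#'
#' @param levels A [reference_levels()] object.
#' @param scale A `cardinal_scale` (from [derive_scale()]) whose items are
#'   exactly `L1..L5`, anchored at L1 = 100 and L5 = 0. Values must be
#'   weakly decreasing from L1 to L5 (flat segments are allowed).
#' @param provenance Free-text provenance note (e.g. `"elicited"`).
#' @return An object of class `value_function` with a `breakpoints` data
#'   frame (`level`, `performance`, `value`).
#' @seealso [evaluate_value()], [categorical_value_function()]
#' @export
#' @examples
#' mpfs <- criterion_spec("mpfs", direction = "benefit", units = "months")
#' rl <- reference_levels(mpfs, c(50.2, 40, 25, 10, 5))
#' sc <- structure(list(
#'   values = c(L1 = 100, L2 = 80, L3 = 60, L4 = 20, L5 = 0),
#'   anchors = c(top = "L1", bottom = "L5"), thresholds = 1:6 * 10),
#'   class = "cardinal_scale")
#' vf <- build_value_function(rl, sc)
#' evaluate_value(vf, 30)
build_value_function <- function(levels, scale, provenance = "elicited") {
  stopifnot(inherits(levels, "reference_levels"),
            inherits(scale, "cardinal_scale"))
  lev_names <- paste0("L", 1:5)
  if (!setequal(names(scale$values), lev_names)) {
    stop_invalid("scale items must be exactly L1..L5")
  }
  v <- scale$values[lev_names]
  if (abs(v[["L1"]] - 100) > 1e-9 || abs(v[["L5"]]) > 1e-9) {
    stop_invalid("scale must be anchored at L1 = 100 and L5 = 0")
  }
  if (any(diff(unname(v)) > 1e-9)) {
    mv_stop("level values must decrease weakly from L1 to L5",
            "mv_invariant_violation")
  }
  structure(list(criterion = levels$criterion,
                 breakpoints = data.frame(level = lev_names,
                                          performance = unname(levels$levels),
                                          value = unname(v)),
                 provenance = provenance),
            class = "value_function")
}

#' Build a categorical value function
#'
#' Categorical criteria (e.g. dosage and administration) carry an explicit
#' finite category-to-value map instead of interpolated breakpoints.
#'
#' @param criterion A [criterion_spec()] with `kind = "categorical"`.
#' @param values Named numeric vector mapping each category label to a
#'   value in `[0, 100]`.
#' @param provenance Free-text provenance note.
#' @return An object of class `value_function`.
#' @export
categorical_value_function <- function(criterion, values,
                                       provenance = "elicited") {
  stopifnot(inherits(criterion, "criterion_spec"))
  if (criterion$kind != "categorical") {
    stop_invalid("criterion must be categorical")
  }
  if (is.null(names(values)) || anyDuplicated(names(values)) ||
      !all(is.finite(values))) {
    stop_invalid("values must be a named numeric vector with unique names")
  }
  if (any(values < 0 | values > 100)) {
    stop_invalid("category values must lie in [0, 100]")
  }
  structure(list(criterion = criterion, categories = values,
                 provenance = provenance),
            class = "value_function")
}

#' @export
print.value_function <- function(x, ...) {
  cat(sprintf("value function for %s [%s]\n", x$criterion$id, x$provenance))
  if (!is.null(x$breakpoints)) print(x$breakpoints) else print(x$categories)
  invisible(x)
}

#' Evaluate a value function
#'
#' Numeric criteria: linear interpolation between the breakpoints; outside
#' the elicited range `[L5, L1]` the value is clamped to 0 or 100 (value
#' functions are defined only over the elicited range, and clamping keeps
#' overall scores in `[0, 100]`). Categorical criteria: direct lookup.
#'
#' @param fn A [build_value_function()] or [categorical_value_function()].
#' @param x Performance: finite numeric vector, or category labels.
#' @return Numeric value score(s) in `[0, 100]`.
#' @export
evaluate_value <- function(fn, x) {
  stopifnot(inherits(fn, "value_function"))
  if (!is.null(fn$categories)) {
    x <- as.character(x)
    unknown <- setdiff(unique(x), names(fn$categories))
    if (length(unknown)) {
      stop_invalid(sprintf("unknown category for %s: %s", fn$criterion$id,
                           paste(unknown, collapse = ", ")))
    }
    return(unname(fn$categories[x]))
  }
  if (!is.numeric(x) || !all(is.finite(x))) {
    stop_invalid("performance must be finite numeric")
  }
  bp <- fn$breakpoints
  ord <- order(bp$performance)
  # rule = 2: clamp to the nearest anchor value outside the elicited range
  stats::approx(bp$performance[ord], bp$value[ord], xout = x, rule = 2,
                ties = "ordered")$y
}
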