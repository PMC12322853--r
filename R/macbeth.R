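#' Check the consistency of a judgment matrix
#'
#' A set of qualitative judgments is consistent when some cardinal scale and
#' some increasing category thresholds satisfy all of them simultaneously,
#' i.e. when the MACBETH linear program is feasible. When it is not, a
#' conflict witness is reported: a (greedily minimal) set of judgments whose
#' removal restores feasibility. Cyclic strict preferences are one source of
#' inconsistency and are reported, not raised as an error.
#'
#' @param matrix A [judgment_matrix()] with at least one judgment.
#' @return An object of class `consistency_report`: list with elements
#'   `consistent` (logical) and `witness` (data frame `i`, `j`, `code` of
#'   removed judgments; empty when consistent).
#' @details The witness is found by repeatedly solving the feasibility
#'   program with one slack variable per judgment, minimising total slack,
#'   and removing the judgment carrying the largest slack until the system
#'   is feasible. This greedy repair is a heuristic: an exactly minimal
#'   witness would require exponential search.
#' @seealso [derive_scale()]
#' @export
#' @examples
#' m <- judgment_matrix(c("A", "B", "C"),
#'   data.frame(i = c("A", "B", "A"), j = c("B", "C", "C"),
#'              code = c(4, 4, 1)))
#' check_consistency(m)
check_consistency <- function(matrix) {
  stopifnot(inherits(matrix, "judgment_matrix"))
  if (nrow(matrix$judgments) == 0L) {
    stop_invalid("consistency check needs at least one judgment")
  }
  jd <- indexed_judgments(matrix)
  keep <- seq_len(nrow(jd))
  removed <- integer(0)
  repeat {
    sl <- min_slack(length(matrix$items), jd[keep, , drop = FALSE])
    if (sl$total <= MACBETH_TOL) break
    worst <- which.max(sl$per_judgment)  # first index on ties: deterministic
    removed <- c(removed, keep[worst])
    keep <- keep[-worst]
    if (!length(keep)) break
  }
  witness <- matrix$judgments[removed, , drop = FALSE]
  rownames(witness) <- NULL
  structure(list(consistent = length(removed) == 0L, witness = witness),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  if (x$consistent) {
    cat("Judgments are consistent (MACBETH LP feasible).\n")
  } else {
    cat("Judgments are INCONSISTENT. Conflict witness (judgments whose",
        "removal restores feasibility):\n")
    labs <- macbeth_categories()
    cat(sprintf("  %s over %s: %s\n", x$witness$i, x$witness$j,
                labs[x$witness$code + 1L]), sep = "")
  }
  invisible(x)
}

#' @export
format.consistency_report <- function(x, ...) {
  jsonlite::toJSON(list(consistent = x$consistent, witness = x$witness),
                   auto_unbox = TRUE, pretty = TRUE)
}

#' Derive a cardinal value scale from qualitative judgments
#'
#' Solves the MACBETH linear program for a consistent judgment matrix and
#' returns a 0-100 interval scale: raw values minimising the scale spread
#' (with a lexicographic clean-up pass for uniqueness) are rescaled
#' affinely so that `top` maps exactly to 100 and `bottom` to 0.
#'
#' @param matrix A consistent [judgment_matrix()].
#' @param top,bottom Item identifiers anchored at 100 and 0. `top` must not
#'   be judged strictly less attractive than any item, and `bottom` must
#'   not be judged strictly more attractive than any item.
#' @return An object of class `cardinal_scale`: list with `values` (named
#'   numeric, one per item, in `[0, 100]`), `anchors` (named character of
#'   top/bottom) and `thresholds` (the six category-boundary values on the
#'   rescaled difference scale, strictly increasing; diagnostic output).
#' @details For a judgment of category k on the pair (i, j) the derived
#'   scale satisfies `value(i) > value(j)` when k > 0 and
#'   `value(i) == value(j)` when k = 0. Output is deterministic: the same
#'   matrix always yields the identical scale.
#' @export
#' @examples
#' m <- judgment_matrix(c("A", "B", "C"),
#'   data.frame(i = c("A", "B", "A"), j = c("B", "C", "C"),
#'              code = c(2, 2, 4)))
#' derive_scale(m, top = "A", bottom = "C")
derive_scale <- function(matrix, top, bottom) {
  stopifnot(inherits(matrix, "judgment_matrix"))
  items <- matrix$items
  if (!top %in% items || !bottom %in% items) {
    stop_invalid("top and bottom must be items of the matrix")
  }
  if (identical(top, bottom)) {
    stop_invalid("top and bottom anchors must differ")
  }
  jd <- matrix$judgments
  if (any(jd$j == top & jd$code > 0L)) {
    stop_invalid("top anchor is judged less attractive than another item")
  }
  if (any(jd$i == bottom & jd$code > 0L)) {
    stop_invalid("bottom anchor is judged more attractive than another item")
  }
  report <- check_consistency(matrix)
  if (!report$consistent) {
    mv_stop("cannot derive a scale from inconsistent judgments",
            "mv_inconsistent", report = report)
  }
  sol <- macbeth_solve(length(items), indexed_judgments(matrix))
  v <- stats::setNames(sol$values, items)
  span <- v[[top]] - v[[bottom]]
  if (span <= MACBETH_TOL) {
    stop_degenerate("top and bottom anchors receive equal values; no scale span")
  }
  vals <- (v - v[[bottom]]) / span * 100
  vals[abs(vals) < MACBETH_TOL] <- 0
  vals[abs(vals - 100) < MACBETH_TOL] <- 100
  if (any(vals < 0 | vals > 100)) {
    stop_invalid("derived values fall outside [0, 100]; check the anchors")
  }
  structure(list(values = vals,
                 anchors = c(top = top, bottom = bottom),
                 thresholds = sol$thresholds / span * 100),
            class = "cardinal_scale")
}

#' @export
print.cardinal_scale <- function(x, digits = 3, ...) {
  cat("MACBETH cardinal scale (anchors:", x$anchors[["top"]], "= 100,",
      x$anchors[["bottom"]], "= 0)\n")
  print(round(x$values, digits))
  cat("category thresholds:",
      paste(round(x$thresholds, digits), collapse = ", "), "\n")
  invisible(x)
}

#' Affinely rescale a cardinal scale
#'
#' Maps a 0-100 scale onto a new interval. Ordering and ratios of value
#' differences are preserved (the information content of an interval scale).
#'
#' @param scale A `cardinal_scale` from [derive_scale()].
#' @param new_top,new_bottom Values the current 100 and 0 anchor points map
#'   to; `new_top > new_bottom`.
#' @return A `cardinal_scale` with transformed `values` and `thresholds`.
#' @export
rescale <- function(scale, new_top, new_bottom) {
  stopifnot(inherits(scale, "cardinal_scale"))
  if (!is_scalar_number(new_top) || !is_scalar_number(new_bottom) ||
      new_top <= new_bottom) {
    stop_invalid("new_top must be greater than new_bottom")
  }
  f <- (new_top - new_bottom) / 100
  scale$values <- scale$values * f + new_bottom
  scale$thresholds <- scale$thresholds * f
  scale$range <- c(bottom = new_bottom, top = new_top)
  scale
}
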