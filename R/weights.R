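#' Derive criterion weights by qualitative swing weighting
#'
#' Weights are elicited MACBETH-style over hypothetical alternatives: one
#' "swing" alternative per criterion (that criterion at its upper reference
#' level, all others at their lower levels) plus an all-lower baseline.
#' Pairwise attractiveness-difference judgments over these alternatives are
#' converted to a cardinal scale with the baseline anchored at 0; the
#' weight of criterion j is proportional to the scale value of its swing
#' alternative above the baseline, normalised so the weights sum to 1.
#'
#' @param weighting_matrix A consistent [judgment_matrix()] whose items are
#'   the swing alternatives plus the baseline.
#' @param baseline Item identifier of the all-lower baseline (default
#'   `"baseline"`). It must not be judged more attractive than any swing.
#' @param criteria Optional character vector mapping swing items to
#'   criterion ids, named by swing item; defaults to the swing item names
#'   themselves.
#' @return An object of class `weight_vector`: named numeric weights in
#'   `[0, 1]` summing to 1, with the underlying `cardinal_scale` attached
#'   as attribute `"scale"`.
#' @seealso [derive_scale()], [score_alternative()]
#' @export
#' @examples
#' m <- judgment_matrix(
#'   c("swing_eff", "swing_safety", "baseline"),
#'   data.frame(i = c("swing_eff", "swing_eff", "swing_safety"),
#'              j = c("swing_safety", "baseline", "baseline"),
#'              code = c(3, 5, 3)))
#' derive_weights(m)
derive_weights <- function(weighting_matrix, baseline = "baseline",
                           criteria = NULL) {
  stopifnot(inherits(weighting_matrix, "judgment_matrix"))
  items <- weighting_matrix$items
  if (!baseline %in% items) {
    stop_invalid(sprintf("baseline item '%s' not found", baseline))
  }
  jd <- weighting_matrix$judgments
  if (any(jd$i == baseline & jd$code > 0L)) {
    stop_invalid("baseline is judged more attractive than a swing alternative")
  }
  swings <- setdiff(items, baseline)
  if (length(swings) < 2L) {
    stop_invalid("need at least two swing alternatives")
  }
  # top anchor: a swing never judged strictly less attractive than anything
  dominated <- unique(jd$j[jd$code > 0L])
  top_candidates <- setdiff(swings, dominated)
  if (!length(top_candidates)) {
    stop_invalid("no swing alternative dominates: cannot anchor the scale")
  }
  scale <- derive_scale(weighting_matrix, top = top_candidates[[1L]],
                        bottom = baseline)
  raw <- scale$values[swings]
  if (sum(raw) <= 0) {
    stop_degenerate("all swing alternatives are valued at the baseline")
  }
  w <- raw / sum(raw)
  if (!is.null(criteria)) names(w) <- unname(criteria[swings])
  structure(w, class = c("weight_vector", class(w)), scale = scale)
}

#' @export
print.weight_vector <- function(x, digits = 4, ...) {
  cat("criterion weights (sum 1):\n")
  print(round(stats::setNames(as.numeric(x), names(x)), digits))
  invisible(x)
}
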