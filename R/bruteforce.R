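#' Exhaustive feasibility check on an integer grid
#'
#' Brute-force reference implementation of judgment-matrix consistency for
#' small problems: enumerates every assignment of integer values
#' `0..max_value` to the items and decides, for each assignment, whether
#' strictly increasing integer category thresholds exist that place every
#' judged difference in its category band. Intended as an independent
#' cross-check of [check_consistency()] (which uses linear programming);
#' practical only for `n <= 4` items or so.
#'
#' @param matrix A [judgment_matrix()].
#' @param max_value Largest grid value enumerated (default 24, ample for
#'   four items and categories up to extreme).
#' @return Logical: `TRUE` iff some grid assignment satisfies all judgments.
#' @seealso [check_consistency()]
#' @export
grid_feasible <- function(matrix, max_value = 24L) {
  stopifnot(inherits(matrix, "judgment_matrix"))
  if (length(matrix$items) > 6L) {
    stop_invalid("grid_feasible is exhaustive; use it for small matrices only")
  }
  jd <- indexed_judgments(matrix)
  .grid_feasible_cpp(length(matrix$items),
                     as.integer(jd$ii - 1L), as.integer(jd$jj - 1L),
                     as.integer(jd$code), as.integer(max_value))
}
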