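#' Filter candidate criteria by mean importance score
#'
#' First selection stage: stakeholders score each candidate criterion from
#' 0 (least important) to 5 (most important); candidates whose mean score
#' is less than or equal to the threshold are excluded.
#'
#' @param candidates Data frame with columns `name` and `mean_score`
#'   (means in `[0, 5]`), or with per-rater integer score columns from
#'   which the mean is computed.
#' @param threshold Exclusion boundary; a mean score `<= threshold` drops
#'   the candidate (default 3.5).
#' @return The retained rows, in their original order.
#' @export
#' @examples
#' filter_by_importance(lymphoma_candidate_criteria())
filter_by_importance <- function(candidates, threshold = 3.5) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    stop_invalid("candidates must be a non-empty data frame")
  }
  if (!"mean_score" %in% names(candidates)) {
    score_cols <- setdiff(names(candidates), "name")
    candidates$mean_score <- rowMeans(candidates[, score_cols, drop = FALSE])
  }
  if (any(candidates$mean_score < 0 | candidates$mean_score > 5) ||
      anyNA(candidates$mean_score)) {
    stop_invalid("importance scores must lie in [0, 5]")
  }
  out <- candidates[candidates$mean_score > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Create an exclusion/substitution ledger
#'
#' Second selection stage: criteria that cleared the importance filter may
#' still be excluded (with a reason category) or substituted by an
#' operational measure.
#'
#' @param exclusions Data frame with columns `name` and `reason`; `reason`
#'   must be one of `below-threshold`, `data-unavailable`, `redundant`,
#'   `undefined/unquantifiable`, `confounded`.
#' @param substitutions Data frame with columns `from` and `to`.
#' @return An object of class `selection_ledger`.
#' @export
selection_ledger <- function(exclusions = NULL, substitutions = NULL) {
  reasons <- c("below-threshold", "data-unavailable", "redundant",
               "undefined/unquantifiable", "confounded")
  if (is.null(exclusions)) {
    exclusions <- data.frame(name = character(), reason = character())
  }
  if (is.null(substitutions)) {
    substitutions <- data.frame(from = character(), to = character())
  }
  bad <- setdiff(exclusions$reason, reasons)
  if (length(bad)) {
    stop_invalid(sprintf("unknown exclusion reason: %s",
                         paste(bad, collapse = ", ")))
  }
  both <- intersect(exclusions$name, substitutions$from)
  if (length(both)) {
    stop_invalid(sprintf("criterion both excluded and substituted: %s",
                         paste(both, collapse = ", ")))
  }
  structure(list(exclusions = exclusions, substitutions = substitutions),
            class = "selection_ledger")
}

#' @export
print.selection_ledger <- function(x, ...) {
  cat(sprintf("selection ledger: %d exclusions, %d substitutions\n",
              nrow(x$exclusions), nrow(x$substitutions)))
  if (nrow(x$exclusions)) {
    cat(sprintf("  - exclude %s (%s)\n", x$exclusions$name,
                x$exclusions$reason), sep = "")
  }
  if (nrow(x$substitutions)) {
    cat(sprintf("  - %s -> %s\n", x$substitutions$from, x$substitutions$to),
        sep = "")
  }
  invisible(x)
}

#' Apply a selection ledger to the retained criteria
#'
#' Removes the excluded criteria, renames the substituted ones, and emits
#' an audit trail recording the fate of every retained criterion.
#'
#' @param retained Character vector of criterion names (or a data frame
#'   with a `name` column) that cleared [filter_by_importance()].
#' @param ledger A [selection_ledger()]. Every name it references must
#'   resolve against `retained`.
#' @return List with `final` (character vector of final criterion names,
#'   order preserved) and `audit` (data frame `name`, `action`, `detail`).
#' @export
#' @examples
#' retained <- filter_by_importance(lymphoma_candidate_criteria())
#' sel <- apply_ledger(retained, lymphoma_selection_ledger())
#' sel$final
apply_ledger <- function(retained, ledger) {
  stopifnot(inherits(ledger, "selection_ledger"))
  if (is.data.frame(retained)) retained <- retained$name
  retained <- as.character(retained)
  unresolved <- setdiff(c(ledger$exclusions$name, ledger$substitutions$from),
                        retained)
  if (length(unresolved)) {
    stop_invalid(sprintf("ledger names not in the retained list: %s",
                         paste(unresolved, collapse = ", ")))
  }
  action <- rep("kept", length(retained))
  detail <- rep("", length(retained))
  final <- retained
  ex <- match(ledger$exclusions$name, retained)
  action[ex] <- "excluded"
  detail[ex] <- ledger$exclusions$reason
  su <- match(ledger$substitutions$from, retained)
  action[su] <- "substituted"
  detail[su] <- ledger$substitutions$to
  final[su] <- ledger$substitutions$to
  list(final = final[action != "excluded"],
       audit = data.frame(name = retained, action = action, detail = detail))
}

#' Read an importance-score survey from CSV
#'
#' Expects one row per rater and one column per criterion (first column
#' `rater`), with integer scores 0..5.
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `name` and `mean_score`, in column
#'   order of the survey.
#' @export
read_importance_survey <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  scores <- raw[, setdiff(names(raw), "rater"), drop = FALSE]
  if (!all(vapply(scores, is.numeric, TRUE))) {
    stop_invalid("survey scores must be numeric")
  }
  if (any(scores < 0 | scores > 5, na.rm = FALSE) || anyNA(scores)) {
    stop_invalid("survey scores must be integers in [0, 5] with no gaps")
  }
  data.frame(name = names(scores), mean_score = unname(colMeans(scores)))
}
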