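#' Semantic judgment categories
#'
#' The seven MACBETH attractiveness-difference categories, ordered from
#' "no difference" (code 0) to "extreme" (code 6).
#'
#' @return Character vector of length 7; `macbeth_categories()[code + 1]`
#'   is the label for a given code.
#' @export
#' @examples
#' macbeth_categories()
macbeth_categories <- function() {
  c("no", "very weak", "weak", "moderate", "strong", "very strong", "extreme")
}

# Map a vector of labels/codes (character or numeric) to integer codes 0..6.
parse_category <- function(x) {
  labs <- macbeth_categories()
  out <- rep(NA_integer_, length(x))
  xc <- tolower(trimws(as.character(x)))
  xc[xc %in% c("", "na")] <- NA_character_
  # accept "no difference"/"none" as synonyms for "no"
  xc[xc %in% c("no difference", "none")] <- "no"
  is_num <- grepl("^[0-9]+$", xc)
  out[is_num] <- as.integer(xc[is_num])
  out[!is_num & !is.na(xc)] <- match(xc[!is_num & !is.na(xc)], labs) - 1L
  bad <- !is.na(xc) & (is.na(out) | out < 0L | out > 6L)
  if (any(bad)) {
    stop_invalid(sprintf(
      "unrecognised judgment category: %s",
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  out
}

#' Create a qualitative pairwise judgment matrix
#'
#' A judgment matrix records, for pairs of items (performance reference
#' levels or hypothetical alternatives), the qualitative MACBETH category of
#' the attractiveness difference. Each judgment `(i, j, code)` states that
#' item `i` is at least as attractive as item `j`, with a difference of the
#' given category (0 = no difference ... 6 = extreme). Judgments are a
#' partial map: missing pairs are simply unconstrained.
#'
#' @param items Character vector of unique item identifiers (length >= 2).
#' @param judgments Data frame with columns `i`, `j` (item identifiers, `i`
#'   the non-less-attractive item) and `code` (integer 0..6 or a category
#'   label). At most one judgment per unordered pair.
#' @return An object of class `judgment_matrix`: a list with elements
#'   `items` and `judgments` (data frame `i`, `j`, `code`).
#' @seealso [check_consistency()], [derive_scale()], [read_judgment_matrix()]
#' @export
#' @examples
#' m <- judgment_matrix(
#'   c("A", "B", "C"),
#'   data.frame(i = c("A", "B", "A"), j = c("B", "C", "C"),
#'              code = c(2, 2, 4))
#' )
#' m
judgment_matrix <- function(items, judgments) {
  items <- as.character(items)
  if (length(items) < 2L) {
    stop_invalid("a judgment matrix needs at least 2 items")
  }
  if (anyDuplicated(items)) {
    stop_invalid("item identifiers must be unique")
  }
  if (is.null(judgments) || nrow(judgments) == 0L) {
    judgments <- data.frame(i = character(), j = character(),
                            code = integer(), stringsAsFactors = FALSE)
  } else {
    judgments <- data.frame(
      i = as.character(judgments$i),
      j = as.character(judgments$j),
      code = parse_category(judgments$code),
      stringsAsFactors = FALSE
    )
    if (anyNA(judgments$code)) {
      stop_invalid("judgment categories must not be missing")
    }
    unknown <- setdiff(c(judgments$i, judgments$j), items)
    if (length(unknown)) {
      stop_invalid(sprintf("judgments refer to unknown items: %s",
                           paste(unique(unknown), collapse = ", ")))
    }
    if (any(judgments$i == judgments$j)) {
      stop_invalid("self-judgments (i == j) are not allowed")
    }
    key <- paste(pmin(judgments$i, judgments$j),
                 pmax(judgments$i, judgments$j))
    if (anyDuplicated(key)) {
      stop_invalid("at most one judgment per unordered pair of items")
    }
  }
  structure(list(items = items, judgments = judgments),
            class = "judgment_matrix")
}

#' @export
print.judgment_matrix <- function(x, ...) {
  cat(sprintf("MACBETH judgment matrix: %d items, %d judgments\n",
              length(x$items), nrow(x$judgments)))
  cat("items:", paste(x$items, collapse = ", "), "\n")
  if (nrow(x$judgments)) {
    labs <- macbeth_categories()
    cat(sprintf("  %s over %s: %s\n", x$judgments$i, x$judgments$j,
                labs[x$judgments$code + 1L]), sep = "")
  }
  invisible(x)
}

#' @export
as.matrix.judgment_matrix <- function(x, labels = FALSE, ...) {
  n <- length(x$items)
  m <- matrix(NA_integer_, n, n, dimnames = list(x$items, x$items))
  if (nrow(x$judgments)) {
    m[cbind(x$judgments$i, x$judgments$j)] <- x$judgments$code
  }
  if (labels) {
    ml <- matrix(macbeth_categories()[m + 1L], n, n,
                 dimnames = dimnames(m))
    return(ml)
  }
  m
}

#' Read a judgment matrix from CSV
#'
#' The file is a square table: the header row names the items, and the cell
#' in row r, column c (strictly above the diagonal) holds the category --
#' either the integer code 0..6 or a label (`no`, `very weak`, `weak`,
#' `moderate`, `strong`, `very strong`, `extreme`; case-insensitive) -- of
#' the judgment that the row item is at least as attractive as the column
#' item. Blank cells are missing judgments; cells on or below the diagonal
#' are ignored.
#'
#' @param path Path to a CSV file.
#' @return A [judgment_matrix()].
#' @export
read_judgment_matrix <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, row.names = 1,
                         colClasses = "character")
  items <- colnames(raw)
  if (!identical(rownames(raw), items)) {
    stop_invalid("judgment CSV must have identical row and column item ids")
  }
  n <- length(items)
  recs <- list()
  for (r in seq_len(n)) {
    for (cc in seq_len(n)) {
      if (cc <= r) next  # lower triangle and diagonal ignored
      cell <- raw[r, cc]
      if (is.na(cell) || !nzchar(trimws(cell))) next
      recs[[length(recs) + 1L]] <-
        data.frame(i = items[r], j = items[cc],
                   code = parse_category(cell), stringsAsFactors = FALSE)
    }
  }
  judgments <- if (length(recs)) do.call(rbind, recs) else NULL
  judgment_matrix(items, judgments)
}

#' Write a judgment matrix to CSV
#'
#' Inverse of [read_judgment_matrix()]: emits the square table with category
#' labels in the upper triangle. Judgments whose preferred item appears
#' later in the item order are written with labels in the corresponding
#' upper-triangle cell only when the ordering permits; items are therefore
#' reordered so that every stored judgment lies above the diagonal
#' (possible whenever the strict part of the preference relation is
#' acyclic).
#'
#' @param x A [judgment_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_judgment_matrix <- function(x, path) {
  stopifnot(inherits(x, "judgment_matrix"))
  ord <- preference_order(x)
  m <- as.matrix(x, labels = TRUE)[ord, ord, drop = FALSE]
  lower <- lower.tri(m, diag = TRUE)
  if (any(!is.na(m[lower]))) {
    stop_invalid(paste0("cannot serialise: strict preferences are cyclic, ",
                        "no item order puts all judgments above the diagonal"))
  }
  m[is.na(m)] <- ""
  utils::write.csv(m, path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

# Topological-ish order: items sorted so judged-more-attractive items come
# first. Uses the strict judgments (code > 0) as edges; falls back to the
# stored item order among unconstrained items. Cycles leave the order
# partially unsorted (caught later by the triangle check).
preference_order <- function(x) {
  n <- length(x$items)
  idx <- stats::setNames(seq_len(n), x$items)
  edges <- x$judgments
  adj <- vector("list", n)
  indeg <- integer(n)
  for (r in seq_len(nrow(edges))) {
    a <- idx[[edges$i[r]]]; b <- idx[[edges$j[r]]]
    adj[[a]] <- c(adj[[a]], b)
    indeg[b] <- indeg[b] + 1L
  }
  out <- integer(0)
  avail <- which(indeg == 0L)
  while (length(avail)) {
    v <- avail[1L]  # smallest stored index: deterministic
    avail <- avail[-1L]
    out <- c(out, v)
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- sort(c(avail, w))
    }
  }
  c(out, setdiff(seq_len(n), out))
}
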