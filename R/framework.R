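#' Assemble an additive value framework
#'
#' A framework model is the scoreable artifact: criteria, one value
#' function per criterion, and normalised weights. Scores of an
#' alternative are the weighted sum of its per-criterion value scores
#' (multi-attribute value theory, additive form).
#'
#' @param criteria Named list of [criterion_spec()], indexed by id.
#' @param value_functions Named list of value functions, same ids.
#' @param weights Named numeric weights, same ids; normalised to sum to 1.
#' @return An object of class `framework_model`.
#' @seealso [score_alternative()], [packaged_lymphoma_model()]
#' @export
framework_model <- function(criteria, value_functions, weights) {
  ids <- names(criteria)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop_invalid("criteria must be a uniquely named list")
  }
  if (!setequal(names(value_functions), ids) || !setequal(names(weights), ids)) {
    stop_invalid("criteria, value functions and weights must share the same ids")
  }
  weights <- unlist(weights)[ids]
  if (any(weights < 0) || !all(is.finite(weights)) || sum(weights) <= 0) {
    stop_invalid("weights must be non-negative and not all zero")
  }
  weights <- weights / sum(weights)
  structure(list(criteria = criteria,
                 value_functions = value_functions[ids],
                 weights = weights),
            class = "framework_model")
}

#' @export
print.framework_model <- function(x, ...) {
  cat(sprintf("additive value framework: %d criteria\n", length(x$criteria)))
  prov <- vapply(x$value_functions, function(f) f$provenance, "")
  df <- data.frame(
    id = names(x$criteria),
    name = vapply(x$criteria, function(cr) cr$name, ""),
    direction = vapply(x$criteria, function(cr) cr$direction, ""),
    weight_pct = round(100 * as.numeric(x$weights), 2),
    value_function = unname(prov))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Score an alternative with an additive value framework
#'
#' @param model A [framework_model()].
#' @param performance Named list or vector supplying the performance of the
#'   alternative on every criterion of the model (numeric performance for
#'   numeric criteria, category label for categorical ones).
#' @return An object of class `score_breakdown`: data frame with one row
#'   per criterion (`criterion_id`, `performance`, `value`, `weight`,
#'   `contribution`) and the overall 0-100 score as attribute `"overall"`.
#' @export
#' @examples
#' model <- packaged_lymphoma_model()
#' perf <- list(qalys = 2.1, mpfs = 25.7, orr = 70, sae34 = 20, aetdr = 6,
#'              admc = 150, dosage_admin = "oral fixed-dose",
#'              n_alternatives = "2", mortality = 30)
#' score_alternative(model, perf)
score_alternative <- function(model, performance) {
  stopifnot(inherits(model, "framework_model"))
  ids <- names(model$criteria)
  missing_ids <- setdiff(ids, names(performance))
  if (length(missing_ids)) {
    stop_invalid(sprintf("missing performance for criteria: %s",
                         paste(missing_ids, collapse = ", ")))
  }
  vals <- vapply(ids, function(cid) {
    evaluate_value(model$value_functions[[cid]], performance[[cid]])
  }, numeric(1))
  w <- as.numeric(model$weights[ids])
  out <- data.frame(
    criterion_id = ids,
    performance = vapply(performance[ids], function(p) as.character(p)[1], ""),
    value = unname(vals),
    weight = w,
    contribution = w * unname(vals),
    row.names = NULL)
  structure(out, overall = sum(out$contribution),
            class = c("score_breakdown", "data.frame"))
}

#' @export
print.score_breakdown <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$value <- round(df$value, digits)
  df$weight <- round(df$weight, 4)
  df$contribution <- round(df$contribution, digits)
  print(df, row.names = FALSE)
  cat(sprintf("overall value score: %.*f\n", digits, attr(x, "overall")))
  invisible(x)
}

#' Score many drugs from a performance table
#'
#' @param model A [framework_model()].
#' @param performance Data frame `drug_id`, `criterion_id`, `value` (as in
#'   the standard performance CSV; `value` may be character for
#'   categorical criteria).
#' @return Data frame of per-criterion breakdown rows for every drug, with
#'   an `overall` data frame (`drug_id`, `score`) attached as attribute
#'   `"overall"`.
#' @export
score_table <- function(model, performance) {
  need <- c("drug_id", "criterion_id", "value")
  if (!all(need %in% names(performance))) {
    stop_invalid("performance table needs columns drug_id, criterion_id, value")
  }
  drugs <- unique(performance$drug_id)
  res <- lapply(drugs, function(d) {
    rows <- performance[performance$drug_id == d, ]
    perf <- stats::setNames(as.list(rows$value), rows$criterion_id)
    numeric_ids <- names(model$criteria)[
      vapply(model$criteria, function(cr) cr$kind == "numeric", TRUE)]
    perf[names(perf) %in% numeric_ids] <-
      lapply(perf[names(perf) %in% numeric_ids], as.numeric)
    br <- score_alternative(model, perf)
    cbind(drug_id = d, as.data.frame(br),
          overall = attr(br, "overall"))
  })
  out <- do.call(rbind, res)
  overall <- unique(out[, c("drug_id", "overall")])
  names(overall) <- c("drug_id", "score")
  rownames(overall) <- NULL
  structure(out[, setdiff(names(out), "overall")],
            overall = overall, class = c("data.frame"))
}

# ---- model configuration (JSON) --------------------------------------------

#' Write a framework model to a JSON configuration file
#'
#' The configuration round-trips losslessly through
#' [read_framework_model()]: criteria (id, name, direction, kind, units),
#' five-level breakpoints or category maps with provenance, and weights as
#' fractions.
#'
#' @param model A [framework_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_framework_model <- function(model, path) {
  stopifnot(inherits(model, "framework_model"))
  crit <- lapply(names(model$criteria), function(cid) {
    cr <- model$criteria[[cid]]
    fn <- model$value_functions[[cid]]
    entry <- list(id = cr$id, name = cr$name, direction = cr$direction,
                  kind = cr$kind, units = cr$units,
                  provenance = fn$provenance)
    if (!is.null(fn$breakpoints)) {
      entry$levels <- fn$breakpoints$performance
      entry$values <- fn$breakpoints$value
    } else {
      entry$category_map <- as.list(fn$categories)
    }
    entry
  })
  jsonlite::write_json(list(criteria = crit, weights = as.list(model$weights)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a framework model from a JSON configuration file
#'
#' @param path Path written by [write_framework_model()].
#' @return A [framework_model()].
#' @export
read_framework_model <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  criteria <- list(); vfs <- list()
  for (entry in cfg$criteria) {
    cr <- criterion_spec(entry$id, entry$name, entry$direction,
                         entry$kind, entry$units %||% "")
    criteria[[cr$id]] <- cr
    if (cr$kind == "numeric") {
      rl <- reference_levels(cr, unlist(entry$levels))
      sc <- structure(list(
        values = stats::setNames(unlist(entry$values), paste0("L", 1:5)),
        anchors = c(top = "L1", bottom = "L5"),
        thresholds = numeric(6)), class = "cardinal_scale")
      vfs[[cr$id]] <- build_value_function(rl, sc,
                                           provenance = entry$provenance %||% "configured")
    } else {
      vfs[[cr$id]] <- categorical_value_function(
        cr, unlist(entry$category_map),
        provenance = entry$provenance %||% "configured")
    }
  }
  framework_model(criteria, vfs, unlist(cfg$weights))
}
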