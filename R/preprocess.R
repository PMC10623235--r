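#' Validate a raw response table
#'
#' Checks that the table has the nine item columns and that every observed
#' cell lies in the 0-3 Likert range. Out-of-range values are a hard error
#' naming the offending respondents, never a silent coercion.
#'
#' @param raw Data frame with columns `id` and `item1` ... `item9`; missing
#'   responses as `NA`.
#' @return The table, invisibly, if valid.
#' @export
validate_responses <- function(raw) {
  cols <- item_cols()
  if (!all(cols %in% names(raw)))
    stop("response table must contain columns ", paste(cols, collapse = ", "))
  items <- as.matrix(raw[cols])
  bad <- !is.na(items) & !(items %in% 0:3)
  if (any(bad)) {
    rows <- which(apply(bad, 1, any))
    ids <- if ("id" %in% names(raw)) raw$id[rows] else rows
    vals <- apply(items[rows, , drop = FALSE], 1,
                  function(r) paste(r[!is.na(r) & !(r %in% 0:3)], collapse = ","))
    stop("out-of-range item responses (must be 0-3 or missing) for respondent(s): ",
         paste(sprintf("%s (value %s)", ids, vals), collapse = "; "))
  }
  invisible(raw)
}

#' Drop respondents with more than two missing item responses
#'
#' The standard exclusion rule for nine-item questionnaires: a row is retained
#' only if at most 2 of its 9 item responses are missing. Row order is
#' preserved; the number of excluded rows is attached as attribute
#' `n_excluded`.
#'
#' @param raw Validated response table.
#' @param max_missing Maximum number of missing items a retained row may have
#'   (default 2).
#' @return Filtered table with attributes `n_excluded` and `n_input`.
#' @export
filter_missing_responses <- function(raw, max_missing = 2L) {
  validate_responses(raw)
  n_miss <- rowSums(is.na(as.matrix(raw[item_cols()])))
  keep <- n_miss <= max_missing
  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_input") <- nrow(raw)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

# Most frequent observed value of an integer vector; ties broken toward the
# lower response (the less symptomatic reading) for determinism.
column_mode <- function(x) {
  obs <- x[!is.na(x)]
  if (!length(obs)) stop("cannot impute: an item column has no observed values")
  counts <- tabulate(obs + 1L, nbins = 4L)
  (which.max(counts) - 1L)  # which.max returns the first (lowest) maximum
}

#' Impute remaining missing responses with the item mode
#'
#' Each missing cell is replaced by the most frequent observed value of its
#' item column in this table (modes are never borrowed from another data
#' set). Ties between equally frequent values resolve to the lower score.
#'
#' @param filtered Response table in which every row has at most 2 missing
#'   items (see [filter_missing_responses()]).
#' @return Complete response table; attribute `n_imputed` gives the per-item
#'   count of imputed cells.
#' @export
impute_item_mode <- function(filtered) {
  cols <- item_cols()
  items <- as.matrix(filtered[cols])
  if (any(rowSums(is.na(items)) > 2L))
    stop("impute_item_mode expects rows with at most 2 missing items; filter first")
  n_imputed <- integer(9L)
  for (j in seq_along(cols)) {
    miss <- is.na(items[, j])
    n_imputed[j] <- sum(miss)
    if (any(miss)) items[miss, j] <- column_mode(items[, j])
  }
  filtered[cols] <- items
  attr(filtered, "n_imputed") <- stats::setNames(n_imputed, cols)
  filtered
}

#' Score complete responses and attach the screen-positive label
#'
#' Adds the questionnaire total (0-27) and the binary screening label,
#' positive iff total >= 10, the conventional reference standard for
#' depressive symptomatology on this questionnaire.
#'
#' @param complete Response table with no missing values.
#' @param cutoff Total-score labelling cutoff (default 10).
#' @return Labelled data frame with added columns `total` and `label`.
#' @export
score_and_label <- function(complete, cutoff = 10L) {
  items <- as.matrix(complete[item_cols()])
  if (anyNA(items))
    stop("score_and_label requires complete responses; impute or filter first")
  validate_responses(complete)
  complete$total <- as.integer(rowSums(items))
  complete$label <- complete$total >= cutoff
  complete
}

#' Full preprocessing pipeline: validate, filter, impute, score, label
#'
#' Applies the exclusion rule (drop rows with >2 missing items), mode
#' imputation of remaining missing cells, scoring, and labelling, and
#' returns the labelled data together with a machine-readable report.
#'
#' @param raw Raw response table.
#' @param cutoff Labelling cutoff on the total score (default 10).
#' @return Labelled data frame; attribute `report` holds a list with
#'   `n_read`, `n_excluded`, `n_imputed` (per item), `n_rows`, `prevalence`.
#' @export
preprocess_responses <- function(raw, cutoff = 10L) {
  filtered <- filter_missing_responses(raw)
  complete <- impute_item_mode(filtered)
  labelled <- score_and_label(complete, cutoff = cutoff)
  report <- list(n_read = attr(filtered, "n_input"),
                 n_excluded = attr(filtered, "n_excluded"),
                 n_imputed = as.list(attr(complete, "n_imputed")),
                 n_rows = nrow(labelled),
                 prevalence = mean(labelled$label))
  attr(labelled, "report") <- report
  labelled
}

#' @rdname preprocess_responses
#' @param labelled Output of [preprocess_responses()].
#' @param path File path for the JSON report.
#' @export
write_preprocess_report <- function(labelled, path) {
  report <- attr(labelled, "report")
  if (is.null(report)) stop("no preprocessing report attached to this dataset")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
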