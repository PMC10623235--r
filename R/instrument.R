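#' Frozen screening instruments
#'
#' An instrument is a deployable decision rule whose predictions depend only
#' on the response pattern: either a fitted two-item logistic model plus one
#' chosen probability threshold, or an item subset plus an integer sum-score
#' cutoff (the psychometric convention, e.g. PHQ-2 with cutoff 2 or 3).
#'
#' @param model A [pair_logit()] fit.
#' @param threshold Probability threshold; classification is positive iff
#'   the pattern probability is >= `threshold`.
#' @param label Human-readable instrument name.
#' @param provenance Optional list (seeds, config) recorded with the
#'   instrument.
#' @return Object of class `phq_instrument`.
#' @name phq_instrument
#' @export
model_instrument <- function(model, threshold, label = NULL,
                             provenance = NULL) {
  stopifnot(inherits(model, "pair_logit"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("a model instrument's threshold must be a probability in (0, 1)")
  structure(
    list(kind = "model",
         items = model$items,
         model = model,
         threshold = threshold,
         label = label %||% sprintf("phq%d&%d>=%.3f", model$items[1],
                                    model$items[2], threshold),
         provenance = provenance),
    class = "phq_instrument")
}

#' @rdname phq_instrument
#' @param items Integer vector of item indices in 1..9.
#' @param cutoff Integer cutoff on the item subscore; positive iff
#'   subscore >= cutoff.
#' @export
sum_score_instrument <- function(items, cutoff, label = NULL,
                                 provenance = NULL) {
  items <- as.integer(items)
  if (!length(items) || any(items < 1L | items > 9L) || anyDuplicated(items))
    stop("items must be a nonempty set of distinct indices in 1..9")
  cutoff <- as.integer(cutoff)
  if (cutoff < 0L || cutoff > 3L * length(items))
    stop("cutoff must lie in 0..", 3L * length(items))
  structure(
    list(kind = "sumscore",
         items = items,
         cutoff = cutoff,
         label = label %||% sprintf("sum(%s)>=%d",
                                    paste(items, collapse = ","), cutoff),
         provenance = provenance),
    class = "phq_instrument")
}

#' @export
print.phq_instrument <- function(x, ...) {
  cat("Frozen screening instrument:", x$label, "\n")
  if (x$kind == "model") {
    cat(sprintf("  logistic model on items %d & %d; probability threshold >= %.6g\n",
                x$items[1], x$items[2], x$threshold))
  } else {
    cat(sprintf("  sum score of items {%s}; cutoff >= %d\n",
                paste(x$items, collapse = ","), x$cutoff))
  }
  invisible(x)
}

#' Scores and classifications of an instrument on a dataset
#'
#' @param object A `phq_instrument`.
#' @param newdata Labelled (or at least complete) response data frame.
#' @param type `"score"` for the instrument's ranking score (pattern
#'   probability, or integer subscore), `"class"` for the frozen
#'   classification.
#' @param ... Unused.
#' @export
predict.phq_instrument <- function(object, newdata,
                                   type = c("score", "class"), ...) {
  type <- match.arg(type)
  cols <- paste0("item", object$items)
  if (!all(cols %in% names(newdata)))
    stop("dataset lacks item column(s) required by this instrument: ",
         paste(setdiff(cols, names(newdata)), collapse = ", "))
  if (object$kind == "model") {
    scores <- predict(object$model, newdata, type = "response")
    if (type == "score") scores else scores >= object$threshold
  } else {
    scores <- rowSums(newdata[, cols, drop = FALSE])
    if (type == "score") scores else scores >= object$cutoff
  }
}

# Content fingerprint of an instrument's frozen parameters, used to assert
# that evaluation never mutates an instrument.
instrument_fingerprint <- function(instrument) {
  rec <- instrument_record(instrument)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(rec, tmp, auto_unbox = TRUE, digits = I(17))
  unname(tools::md5sum(tmp))
}

instrument_record <- function(x) {
  if (x$kind == "model") {
    cf <- x$model$coefficients
    list(kind = "model", label = x$label, pair = x$items,
         w1 = unname(cf["w1"]), w2 = unname(cf["w2"]), b = unname(cf["bias"]),
         reg_strength = x$model$C, threshold = x$threshold,
         pattern_table = pattern_probabilities(x$model),
         provenance = x$provenance)
  } else {
    list(kind = "sumscore", label = x$label, items = x$items,
         cutoff = x$cutoff, provenance = x$provenance)
  }
}

#' Serialize and restore frozen instruments (JSON)
#'
#' @param instrument A `phq_instrument`.
#' @param path File path.
#' @export
write_instrument <- function(instrument, path) {
  jsonlite::write_json(instrument_record(instrument), path,
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_instrument
#' @export
read_instrument <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(rec$kind, "model")) {
    model <- structure(
      list(items = as.integer(rec$pair),
           coefficients = stats::setNames(c(rec$w1, rec$w2, rec$b),
                                          c("w1", "w2", "bias")),
           C = rec$reg_strength, objective = NA_real_,
           iterations = NA_integer_, n = NA_integer_, counts = NULL),
      class = "pair_logit")
    model_instrument(model, rec$threshold, label = rec$label,
                     provenance = rec$provenance)
  } else {
    sum_score_instrument(as.integer(rec$items), rec$cutoff,
                         label = rec$label, provenance = rec$provenance)
  }
}
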