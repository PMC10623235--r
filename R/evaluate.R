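#' Evaluate a frozen instrument on a labelled dataset
#'
#' Computes the tie-corrected AUC of the instrument's scores and the full
#' operating point (confusion counts, sensitivity, specificity, Youden,
#' PPV, NPV) at the instrument's frozen threshold. The instrument is never
#' retrained or adjusted; its parameter fingerprint is checked before and
#' after evaluation.
#'
#' @param instrument A `phq_instrument` (model or sum-score).
#' @param data Labelled dataset containing the instrument's item columns.
#' @param dataset_label Name recorded in the report.
#' @return Object of class `phq_evaluation`: list with `dataset`,
#'   `instrument`, `kind`, `n`, `prevalence`, `auc`, `degenerate_scores`
#'   (TRUE when all scores coincide, in which case the rank AUC is the
#'   uninformative 0.5), and `point` (one-row [operating_points()] frame).
#' @export
evaluate_instrument <- function(instrument, data, dataset_label = "data") {
  stopifnot(inherits(instrument, "phq_instrument"))
  check_labeled(data)
  check_two_classes(data$label)
  fp_before <- instrument_fingerprint(instrument)
  scores <- predict(instrument, data, type = "score")
  threshold <- if (instrument$kind == "model") instrument$threshold else instrument$cutoff
  point <- operating_points(scores, data$label, thresholds = threshold)
  out <- structure(
    list(dataset = dataset_label,
         instrument = instrument$label,
         kind = instrument$kind,
         n = nrow(data),
         prevalence = mean(data$label),
         auc = auc_rank(scores, data$label),
         degenerate_scores = length(unique(scores)) == 1L,
         point = point),
    class = "phq_evaluation")
  fp_after <- instrument_fingerprint(instrument)
  if (!identical(fp_before, fp_after))
    stop("internal error: instrument parameters changed during evaluation")
  out
}

#' @rdname evaluate_instrument
#' @param items,cutoff Item subset and integer cutoff of a sum-score rule,
#'   evaluated without constructing the instrument explicitly.
#' @export
evaluate_sum_score <- function(items, cutoff, data, dataset_label = "data") {
  evaluate_instrument(sum_score_instrument(items, cutoff), data,
                      dataset_label = dataset_label)
}

#' @export
print.phq_evaluation <- function(x, ...) {
  cat(sprintf("%s on %s (n = %d, prevalence %.3f)\n",
              x$instrument, x$dataset, x$n, x$prevalence))
  cat(sprintf("  AUC %.3f%s | youden %.3f sens %.3f spec %.3f ppv %.3f npv %.3f\n",
              x$auc, if (x$degenerate_scores) " (degenerate: single score value)" else "",
              x$point$youden, x$point$sensitivity, x$point$specificity,
              x$point$ppv, x$point$npv))
  invisible(x)
}

#' Side-by-side comparison of instrument evaluations
#'
#' Collects evaluation reports into one table, one row per instrument per
#' data set, and flags per data set which instrument attains the maximum
#' AUC and which the maximum Youden index (ties flag every tied row).
#'
#' @param reports List of [evaluate_instrument()] reports.
#' @return Data frame of class `instrument_comparison` with columns
#'   `dataset`, `instrument`, `auc`, `threshold`, `youden`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `tp`, `fp`, `tn`, `fn`, `auc_best`,
#'   `youden_best`.
#' @export
compare_instruments <- function(reports) {
  if (length(reports) < 2L)
    stop("need at least two evaluation reports to compare")
  if (!all(vapply(reports, inherits, logical(1), "phq_evaluation")))
    stop("all reports must be phq_evaluation objects")
  rows <- lapply(reports, function(r) {
    cbind(data.frame(dataset = r$dataset, instrument = r$instrument,
                     auc = r$auc),
          r$point[c("threshold", "youden", "sensitivity", "specificity",
                    "ppv", "npv", "tp", "fp", "tn", "fn")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$auc_best <- FALSE
  out$youden_best <- FALSE
  for (d in unique(out$dataset)) {
    sel <- out$dataset == d
    out$auc_best[sel] <- out$auc[sel] >= max(out$auc[sel])
    out$youden_best[sel] <- out$youden[sel] >= max(out$youden[sel])
  }
  class(out) <- c("instrument_comparison", "data.frame")
  out
}

#' Write a metrics table as TSV
#'
#' Columns follow the conventional validation-table order: instrument,
#' threshold, youden, sensitivity, specificity, ppv, npv, then the raw
#' confusion counts. A `dataset` column, if present, is kept first. Values
#' are written at full precision; round for display, not on disk.
#'
#' @param table Data frame (e.g. from [compare_instruments()] or
#'   [operating_points()]).
#' @param path Output path.
#' @export
write_metrics_tsv <- function(table, path) {
  order_cols <- c("dataset", "instrument", "threshold", "youden",
                  "sensitivity", "specificity", "ppv", "npv",
                  "tp", "fp", "tn", "fn")
  keep <- intersect(order_cols, names(table))
  rest <- setdiff(names(table), keep)
  utils::write.table(table[c(keep, rest)], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full two-item instrument study on one dataset
#'
#' Convenience wrapper for the end-to-end procedure: stratified train/test
#' split, stratified k-fold CV plan, ranking of all 36 pairings by tuned
#' mean CV AUC, freezing of the top pairings with CV-Youden thresholds, and
#' held-out evaluation of the frozen instruments next to the PHQ-2 sum-score
#' cutoffs (>= 2 and >= 3).
#'
#' @param data Labelled dataset (see [preprocess_responses()]).
#' @param train_fraction,k,seed Split and CV parameters.
#' @param budget,reg_range Tuning parameters (see [tune_regularization()]).
#' @param n_final Number of top-ranked pairings to freeze (default 2).
#' @return List of class `pair_study` with `split`, `plan`, `ranking`,
#'   `instruments`, `evaluations` (test-split reports), and `comparison`.
#' @export
pair_screen_study <- function(data, train_fraction = 0.7, k = 5L, seed = 1L,
                              budget = 10L, reg_range = c(1e-3, 1e3),
                              n_final = 2L) {
  split <- split_dataset(data, train_fraction, seed = derive_seed(seed, 1L))
  plan <- make_cv_folds(split$train, k = k, seed = derive_seed(seed, 2L))
  ranking <- rank_pairings(split$train, plan, reg_range = reg_range,
                           budget = budget, seed = derive_seed(seed, 3L))
  top <- utils::head(ranking, n_final)
  instruments <- lapply(seq_len(nrow(top)), function(r) {
    finalize_instrument(split$train, plan, c(top$i[r], top$j[r]),
                        C = top$tuned_C[r])
  })
  baselines <- list(sum_score_instrument(c(1, 2), 2, label = "PHQ-2>=2"),
                    sum_score_instrument(c(1, 2), 3, label = "PHQ-2>=3"))
  all_inst <- c(instruments, baselines)
  evaluations <- lapply(all_inst, evaluate_instrument, data = split$test,
                        dataset_label = "test")
  structure(list(split = split, plan = plan, ranking = ranking,
                 instruments = all_inst, evaluations = evaluations,
                 comparison = compare_instruments(evaluations),
                 seed = as.integer(seed)),
            class = "pair_study")
}

#' @export
print.pair_study <- function(x, ...) {
  print(x$split)
  print(x$ranking, n = 5L)
  cat("\nHeld-out test evaluation:\n")
  cmp <- as.data.frame(x$comparison)
  cmp[c("auc", "youden", "sensitivity", "specificity", "ppv", "npv")] <-
    round(cmp[c("auc", "youden", "sensitivity", "specificity", "ppv", "npv")], 3)
  print(cmp[c("instrument", "auc", "threshold", "youden", "sensitivity",
              "specificity", "ppv", "npv")])
  invisible(x)
}
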