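#' Stratified train/test split
#'
#' Splits a labelled dataset into disjoint, exhaustive train and test sets,
#' stratified by the screening label so both sets keep the sample prevalence.
#' The training size is `round(train_fraction * n)`, apportioned across the
#' two label strata by largest remainder, so e.g. a 4025-row table at
#' fraction 0.6999 always yields 2817 training and 1208 test rows.
#' Deterministic under `seed`.
#'
#' @param data Labelled dataset.
#' @param train_fraction Fraction of rows assigned to training, in (0, 1).
#' @param seed Integer seed.
#' @return Object of class `phq_split`: list with `train`, `test`,
#'   `train_fraction`, `seed`, and an `audit` log of data accesses.
#' @export
split_dataset <- function(data, train_fraction = 0.7, seed = 1L) {
  check_labeled(data)
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must lie strictly between 0 and 1")
  n <- nrow(data)
  strata <- split(seq_len(n), data$label)
  if (any(lengths(strata) < 2L))
    stop("each label stratum must contain at least 2 rows to be split")
  n_train <- round(train_fraction * n)
  exact <- train_fraction * lengths(strata)
  quota <- floor(exact)
  short <- n_train - sum(quota)
  if (short > 0) {
    o <- order(-(exact - quota), -lengths(strata))
    quota[o[seq_len(short)]] <- quota[o[seq_len(short)]] + 1L
  } else if (short < 0) {
    o <- order(exact - quota, lengths(strata))
    quota[o[seq_len(-short)]] <- quota[o[seq_len(-short)]] - 1L
  }
  idx_train <- with_seed(seed, {
    sort(unlist(mapply(function(ix, q) ix[sample.int(length(ix))[seq_len(q)]],
                       strata, quota, SIMPLIFY = FALSE), use.names = FALSE))
  })
  train <- data[idx_train, , drop = FALSE]
  test <- data[-idx_train, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  structure(list(train = train, test = test,
                 train_fraction = train_fraction, seed = as.integer(seed),
                 audit = data.frame(stage = "split", role = c("train", "test"),
                                    n = c(nrow(train), nrow(test)))),
            class = "phq_split")
}

#' @export
print.phq_split <- function(x, ...) {
  cat(sprintf("Stratified split: %d train / %d test (fraction %.4f, seed %d)\n",
              nrow(x$train), nrow(x$test), x$train_fraction, x$seed))
  invisible(x)
}

#' Stratified k-fold cross-validation plan
#'
#' Partitions the training rows into `k` folds, stratified by label; within
#' each stratum fold sizes differ by at most one, and the within-stratum
#' remainders are placed greedily on the currently smallest folds so the
#' overall fold sizes also stay balanced (2817 rows at k = 5 give folds of
#' 563-564). When a class has fewer than `k` members (e.g. leave-one-out on
#' a toy set) stratification is impossible; the partition falls back to
#' plain balanced folds with a warning.
#'
#' @param train Labelled training dataset.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Object of class `cv_plan`: list with `k`, `fold` (fold id per
#'   training row), `seed`, `stratified`.
#' @export
make_cv_folds <- function(train, k = 5L, seed = 1L) {
  check_labeled(train)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  n <- nrow(train)
  if (k > n) stop("k cannot exceed the number of rows")
  stratified <- all(table(factor(train$label, levels = c(FALSE, TRUE))) >= k)
  if (!stratified)
    warning("a class has fewer members than folds; using balanced unstratified folds")
  strata <- if (stratified) split(seq_len(n), train$label) else list(seq_len(n))
  fold <- integer(n)
  totals <- numeric(k)
  with_seed(seed, {
    for (ix in strata) {
      ix <- ix[sample.int(length(ix))]
      m <- length(ix) %/% k
      r <- length(ix) %% k
      sizes <- rep(m, k)
      if (r > 0) {
        extra <- order(totals, seq_len(k))[seq_len(r)]
        sizes[extra] <- m + 1L
      }
      fold[ix] <- rep(seq_len(k), times = sizes)
      totals <- totals + sizes
    }
  })
  structure(list(k = k, fold = fold, seed = as.integer(seed),
                 stratified = stratified),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("Stratified %d-fold CV plan over %d rows (seed %d); fold sizes: %s\n",
              x$k, length(x$fold), x$seed,
              paste(tabulate(x$fold, x$k), collapse = ", ")))
  invisible(x)
}

# Per-fold pattern-class counts for one item pair: a 32 x k matrix whose
# column f holds the 16 negative-class then 16 positive-class pattern counts
# of fold f.
fold_pattern_counts <- function(train, plan, items) {
  a <- train[[paste0("item", items[1])]]
  b <- train[[paste0("item", items[2])]]
  y <- as.integer(train$label)
  idx <- 4L * a + b + 1L + 16L * y + 32L * (plan$fold - 1L)
  matrix(tabulate(idx, nbins = 32L * plan$k), 32L, plan$k)
}

as_count_matrix <- function(v) matrix(v, 16L, 2L, dimnames = list(NULL, c("neg", "pos")))

# Mean out-of-fold AUC of the pair model at one penalty setting. Each fold's
# model is fitted on the other k-1 folds; its linear scores (a monotone
# transform of the probabilities, so AUC-equivalent) rank the held-out fold.
cv_pair_auc <- function(fold_counts, C) {
  total <- rowSums(fold_counts)
  k <- ncol(fold_counts)
  g <- pattern_grid()
  vapply(seq_len(k), function(f) {
    fit <- fit_logit_counts(as_count_matrix(total - fold_counts[, f]), C)
    z <- fit$beta[1] * g$a + fit$beta[2] * g$b
    val <- as_count_matrix(fold_counts[, f])
    auc_grouped(z, val[, "pos"], val[, "neg"])
  }, numeric(1))
}

#' Tune the regularization strength of one pairing by cross-validated AUC
#'
#' Evaluates at most `budget` candidate values of the inverse penalty `C` and
#' returns the evaluated candidate with the highest mean out-of-fold AUC.
#' The search is a deterministic log-spaced ladder over `reg_range`, refined
#' once with the remaining budget between the incumbent's neighbours; the
#' contract is the argmax over the evaluated set, not global optimality.
#'
#' @param train Labelled training dataset.
#' @param plan A [make_cv_folds()] plan for `train`.
#' @param items Two item indices.
#' @param reg_range Positive bounds of the search interval for `C`
#'   (log scale). Default spans six orders of magnitude.
#' @param budget Maximum number of candidates evaluated (>= 1).
#' @param seed Kept for interface stability; the default search is
#'   deterministic and does not consume randomness.
#' @return List with `C` (selected), `per_fold_auc` at the selection,
#'   `mean_cv_auc`, and `evaluated` (data frame of all candidates).
#' @export
tune_regularization <- function(train, plan, items,
                                reg_range = c(1e-3, 1e3), budget = 10L,
                                seed = 1L) {
  if (budget < 1L) stop("budget must be at least 1")
  if (any(reg_range <= 0)) stop("reg_range bounds must be positive")
  fold_counts <- fold_pattern_counts(train, plan, items)
  evaluated_C <- numeric(0)
  fold_aucs <- list()
  eval_cand <- function(Cs) {
    for (C in Cs) {
      fa <- cv_pair_auc(fold_counts, C)
      evaluated_C[length(evaluated_C) + 1L] <<- C
      fold_aucs[[length(fold_aucs) + 1L]] <<- fa
    }
  }
  m1 <- max(1L, ceiling(budget * 0.6))
  ladder <- exp(seq(log(reg_range[1]), log(reg_range[2]), length.out = m1))
  eval_cand(ladder)
  m2 <- budget - m1
  if (m2 > 0L) {
    means <- vapply(fold_aucs, mean, numeric(1))
    best <- which.max(means)
    lo <- if (best > 1L) ladder[best - 1L] else ladder[best]
    hi <- if (best < m1) ladder[best + 1L] else ladder[best]
    if (hi > lo) {
      refine <- exp(seq(log(lo), log(hi), length.out = m2 + 2L))[-c(1L, m2 + 2L)]
      eval_cand(refine)
    }
  }
  # AUC only sees the score ordering, so candidates often tie exactly; ties
  # resolve to the weakest penalty (closest to the unpenalized MLE), keeping
  # coefficients on an interpretable scale
  means <- vapply(fold_aucs, mean, numeric(1))
  o <- order(-means, -evaluated_C)
  sel <- o[1]
  list(C = evaluated_C[sel],
       per_fold_auc = fold_aucs[[sel]],
       mean_cv_auc = means[sel],
       evaluated = data.frame(C = evaluated_C, mean_cv_auc = means))
}

#' Rank all 36 item pairings by mean cross-validated AUC
#'
#' Runs [tune_regularization()] for every unordered pairing of the nine
#' items and ranks pairings by the tuned mean out-of-fold AUC, descending;
#' exact ties break by lexicographic pair order for determinism.
#'
#' @inheritParams tune_regularization
#' @return Object of class `pair_ranking`: a data frame with one row per
#'   pairing (`i`, `j`, `tuned_C`, `mean_cv_auc`, `auc_fold1..k`), sorted.
#' @export
rank_pairings <- function(train, plan, reg_range = c(1e-3, 1e3),
                          budget = 10L, seed = 1L) {
  pairs <- all_item_pairs()
  res <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    tuned <- tune_regularization(train, plan, pairs[p, ],
                                 reg_range = reg_range, budget = budget,
                                 seed = derive_seed(seed, p))
    row <- data.frame(i = pairs[p, 1], j = pairs[p, 2],
                      tuned_C = tuned$C, mean_cv_auc = tuned$mean_cv_auc)
    row[paste0("auc_fold", seq_along(tuned$per_fold_auc))] <-
      as.list(tuned$per_fold_auc)
    res[[p]] <- row
  }
  out <- do.call(rbind, res)
  out <- out[order(-out$mean_cv_auc, out$i, out$j), ]
  rownames(out) <- NULL
  class(out) <- c("pair_ranking", "data.frame")
  attr(out, "audit") <- data.frame(stage = "rank_pairings", role = "train",
                                   n = nrow(train))
  out
}

#' @export
print.pair_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("Pairing ranking by mean CV AUC (%d pairings; top %d shown):\n",
              nrow(x), min(n, nrow(x))))
  top <- utils::head(as.data.frame(x)[c("i", "j", "tuned_C", "mean_cv_auc")], n)
  top$mean_cv_auc <- round(top$mean_cv_auc, 4)
  top$tuned_C <- signif(top$tuned_C, 3)
  print(top)
  invisible(x)
}

#' Freeze an instrument: final fit plus CV-Youden-selected threshold
#'
#' Fits the final pair model on the full training split at the tuned penalty,
#' enumerates the decision rules induced by its candidate pattern
#' probabilities, scores every rule's sensitivity and specificity on each CV
#' validation fold (rules partition the 16 response patterns, so they are
#' evaluable out-of-fold without reference to fold-model probability
#' scales), and freezes the rule with the highest mean CV Youden index.
#' Ties break toward higher mean sensitivity, then the lower threshold.
#'
#' @inheritParams tune_regularization
#' @param C Inverse penalty strength from the tuning stage.
#' @param label Optional instrument name.
#' @return A frozen `phq_instrument` whose provenance records the seed,
#'   penalty and the per-threshold CV table (attribute `cv_table`).
#' @export
finalize_instrument <- function(train, plan, items, C, label = NULL) {
  model <- pair_logit(train, items, C = C)
  probs <- pattern_probabilities(model)$probability
  thresholds <- candidate_thresholds(model)
  fold_counts <- fold_pattern_counts(train, plan, items)
  k <- plan$k
  stats_for <- function(t) {
    positive <- probs >= t
    per_fold <- vapply(seq_len(k), function(f) {
      cnt <- as_count_matrix(fold_counts[, f])
      tp <- sum(cnt[positive, "pos"]); fn <- sum(cnt[!positive, "pos"])
      tn <- sum(cnt[!positive, "neg"]); fp <- sum(cnt[positive, "neg"])
      c(sens = tp / (tp + fn), spec = tn / (tn + fp))
    }, numeric(2))
    rowMeans(per_fold)
  }
  cv <- t(vapply(thresholds, stats_for, numeric(2)))
  cv_table <- data.frame(threshold = thresholds,
                         mean_cv_sensitivity = cv[, "sens"],
                         mean_cv_specificity = cv[, "spec"],
                         mean_cv_youden = cv[, "sens"] + cv[, "spec"] - 1)
  o <- order(-cv_table$mean_cv_youden, -cv_table$mean_cv_sensitivity,
             cv_table$threshold)
  chosen <- cv_table$threshold[o[1]]
  inst <- model_instrument(
    model, chosen, label = label,
    provenance = list(cv_seed = plan$seed, k = plan$k, C = C,
                      mean_cv_youden = cv_table$mean_cv_youden[o[1]]))
  attr(inst, "cv_table") <- cv_table
  inst
}
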