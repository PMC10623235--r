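test_that("frozen evaluation matches a by-hand confusion count on toy data", {
  # 20 rows, scores hand-computable: sum-score instrument on items 1,2
  a <- c(0, 0, 1, 1, 2, 2, 3, 3, 0, 1, 2, 3, 0, 1, 2, 3, 1, 2, 0, 3)
  b <- c(0, 1, 0, 1, 0, 1, 0, 1, 2, 2, 2, 2, 3, 3, 3, 3, 1, 0, 0, 3)
  label <- c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE,
             TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
  dat <- toy_pair_data(a, b, label)
  ev <- evaluate_sum_score(c(1, 2), 3, dat, "toy")
  oc <- oracle_confusion(a + b, label, 3)
  expect_equal(unlist(ev$point[c("tp", "fp", "tn", "fn")]), oc)
  expect_equal(ev$point$sensitivity, oc["tp"] / (oc["tp"] + oc["fn"]),
               ignore_attr = TRUE)
  expect_equal(ev$auc, oracle_auc_pairs(a + b, label), tolerance = 1e-12)
  expect_equal(ev$prevalence, mean(label))
})

test_that("evaluation is pure: the instrument fingerprint never changes", {
  dat <- sim_labeled(600, seed = 71)
  plan <- make_cv_folds(dat, 5, seed = 1)
  inst <- finalize_instrument(dat, plan, c(2, 4), C = 1)
  fp0 <- phqpairs:::instrument_fingerprint(inst)
  ev1 <- evaluate_instrument(inst, dat, "train")
  fp1 <- phqpairs:::instrument_fingerprint(inst)
  ev2 <- evaluate_instrument(inst, dat, "train")
  expect_identical(fp0, fp1)
  expect_equal(ev1$auc, ev2$auc)
  expect_equal(ev1$point, ev2$point)
})

test_that("evaluating on the training split reproduces directly computed metrics", {
  dat <- sim_labeled(900, seed = 72)
  plan <- make_cv_folds(dat, 5, seed = 2)
  inst <- finalize_instrument(dat, plan, c(2, 8), C = 5)
  ev <- evaluate_instrument(inst, dat, "train")
  scores <- predict(inst$model, dat, type = "response")
  direct <- operating_points(scores, dat$label, thresholds = inst$threshold)
  expect_equal(ev$point, direct)
  expect_equal(ev$auc, auc_rank(scores, dat$label))
})

test_that("degenerate single-valued scores are flagged and give AUC 0.5", {
  dat <- toy_pair_data(rep(0L, 30), rep(0L, 30),
                       rep(c(TRUE, FALSE), 15))
  ev <- evaluate_sum_score(c(1, 2), 0, dat, "flat")
  expect_true(ev$degenerate_scores)
  expect_equal(ev$auc, 0.5)
  expect_equal(ev$point$sensitivity, 1)  # cutoff 0 classifies everyone positive
  expect_equal(ev$point$specificity, 0)
})

test_that("a dataset missing a required item column is a validation error", {
  dat <- sim_labeled(50, seed = 73)
  inst <- sum_score_instrument(c(1, 2), 2)
  dat$item2 <- NULL
  expect_error(predict(inst, dat), "item2")
})

test_that("sum-score toy enumeration matches the exhaustive oracle at every cutoff", {
  # subscores 0..6, one per label pattern
  a <- c(0, 1, 2, 3, 3, 3, 3)
  b <- c(0, 0, 0, 0, 1, 2, 3)
  label <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)
  dat <- toy_pair_data(a, b, label)
  pts <- sum_score_points(dat, c(1, 2))
  for (r in seq_len(nrow(pts))) {
    oc <- oracle_confusion(a + b, label, pts$threshold[r])
    expect_equal(unlist(pts[r, c("tp", "fp", "tn", "fn")]), oc)
  }
})

test_that("comparison flags the per-dataset argmax and ties", {
  dat <- sim_labeled(700, seed = 74)
  sp <- split_dataset(dat, 0.7, seed = 3)
  i22 <- sum_score_instrument(c(1, 2), 2, label = "PHQ-2>=2")
  i23 <- sum_score_instrument(c(1, 2), 3, label = "PHQ-2>=3")
  dup <- sum_score_instrument(c(1, 2), 2, label = "PHQ-2>=2 copy")

  tie_reports <- list(evaluate_instrument(i22, sp$test, "test"),
                      evaluate_instrument(dup, sp$test, "test"))
  cmp <- compare_instruments(tie_reports)
  expect_equal(cmp$auc[1], cmp$auc[2])
  expect_true(all(cmp$auc_best))  # tie flagged on both rows

  # three synthetic datasets; flags must equal an external recomputation
  sets <- list(A = sim_labeled(400, seed = 75), B = sim_labeled(400, seed = 76),
               C = sim_labeled(400, seed = 77))
  reports <- unlist(lapply(names(sets), function(nm) {
    lapply(list(i22, i23), evaluate_instrument, data = sets[[nm]],
           dataset_label = nm)
  }), recursive = FALSE)
  cmp <- compare_instruments(reports)
  for (nm in names(sets)) {
    sub <- cmp[cmp$dataset == nm, ]
    expect_equal(sub$auc_best, sub$auc == max(sub$auc))
    expect_equal(sub$youden_best, sub$youden == max(sub$youden))
  }
  expect_error(compare_instruments(reports[1]), "at least two")
})

test_that("every emitted row satisfies the Youden and predictive-value identities", {
  dat <- sim_labeled(800, seed = 78)
  sp <- split_dataset(dat, 0.7, seed = 4)
  plan <- make_cv_folds(sp$train, 5, seed = 5)
  inst <- finalize_instrument(sp$train, plan, c(2, 4), C = 1)
  reports <- list(evaluate_instrument(inst, sp$test, "test"),
                  evaluate_sum_score(c(1, 2), 2, sp$test, "test"),
                  evaluate_sum_score(c(1, 2), 3, sp$test, "test"))
  cmp <- compare_instruments(reports)
  expect_true(all(abs(cmp$youden - (cmp$sensitivity + cmp$specificity - 1)) < 1e-12))
  expect_equal(cmp$ppv, cmp$tp / (cmp$tp + cmp$fp), tolerance = 1e-15)
  expect_equal(cmp$npv, cmp$tn / (cmp$tn + cmp$fn), tolerance = 1e-15)
})

test_that("the reported AUC does not depend on the frozen threshold", {
  dat <- sim_labeled(500, seed = 79)
  fit <- pair_logit(dat, c(2, 4), C = 1)
  thr <- candidate_thresholds(fit)
  ev_lo <- evaluate_instrument(model_instrument(fit, thr[10]), dat, "d")
  ev_hi <- evaluate_instrument(model_instrument(fit, thr[4]), dat, "d")
  expect_equal(ev_lo$auc, ev_hi$auc)
  expect_false(isTRUE(all.equal(ev_lo$point$sensitivity, ev_hi$point$sensitivity)))
})

test_that("metrics tables and instruments round-trip through disk", {
  dat <- sim_labeled(400, seed = 80)
  reports <- list(evaluate_sum_score(c(1, 2), 2, dat, "d"),
                  evaluate_sum_score(c(1, 2), 3, dat, "d"))
  cmp <- compare_instruments(reports)
  tsv <- tempfile(fileext = ".tsv")
  write_metrics_tsv(cmp, tsv)
  head <- strsplit(readLines(tsv, n = 1), "\t")[[1]]
  expect_equal(head[1:12],
               c("dataset", "instrument", "threshold", "youden", "sensitivity",
                 "specificity", "ppv", "npv", "tp", "fp", "tn", "fn"))

  plan <- make_cv_folds(dat, 5, seed = 6)
  inst <- finalize_instrument(dat, plan, c(2, 4), C = 2)
  path <- tempfile(fileext = ".json")
  write_instrument(inst, path)
  back <- read_instrument(path)
  expect_identical(back$threshold, inst$threshold)
  expect_identical(back$model$coefficients, inst$model$coefficients)
  ev1 <- evaluate_instrument(inst, dat, "d")
  ev2 <- evaluate_instrument(back, dat, "d")
  expect_equal(ev1$point, ev2$point)
  ssi <- sum_score_instrument(c(1, 2), 3)
  write_instrument(ssi, path)
  expect_equal(read_instrument(path)$cutoff, 3L)
})
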