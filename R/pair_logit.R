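#' All 36 unordered pairings of the nine items
#'
#' @return 36 x 2 integer matrix with columns `i`, `j` (`i < j`), in
#'   lexicographic order.
#' @export
all_item_pairs <- function() {
  pairs <- t(utils::combn(9L, 2L))
  colnames(pairs) <- c("i", "j")
  pairs
}

# Aggregate a labelled dataset restricted to two items into per-pattern,
# per-class counts: a 16 x 2 matrix (columns: negatives, positives), row k
# corresponding to pattern (a, b) with k = 4*a + b + 1.
pattern_counts <- function(data, items) {
  a <- data[[paste0("item", items[1])]]
  b <- data[[paste0("item", items[2])]]
  y <- as.integer(data$label)
  idx <- 4L * a + b + 1L + 16L * y
  counts <- tabulate(idx, nbins = 32L)
  matrix(counts, 16L, 2L, dimnames = list(NULL, c("neg", "pos")))
}

# The 16 lattice patterns in row order matching pattern_counts().
pattern_grid <- function() {
  g <- expand.grid(b = 0:3, a = 0:3)[, c("a", "b")]
  rownames(g) <- NULL
  g
}

# Penalized logistic fit on aggregated pattern counts by Newton-Raphson with
# step halving. Objective: mean negative log-likelihood over respondents plus
# ||w||^2 / (2C); the bias is unpenalized. Strictly convex for C < Inf, so the
# optimum is unique; convergence is declared at gradient norm < grad_tol.
fit_logit_counts <- function(counts, C, grad_tol = 1e-8, max_iter = 200L) {
  n <- sum(counts)
  if (sum(counts[, "pos"]) == 0L || sum(counts[, "neg"]) == 0L)
    stop("cannot fit a classifier: all training labels belong to one class")
  g <- pattern_grid()
  X <- cbind(a = g$a, b = g$b, bias = 1)
  w_tot <- counts[, "neg"] + counts[, "pos"]
  y_pos <- counts[, "pos"]
  pen <- c(1 / C, 1 / C, 0)
  objective <- function(beta) {
    z <- drop(X %*% beta)
    # -sum over patterns of [pos*log(p) + neg*log(1-p)] / n, in stable form
    nll <- sum(w_tot * log1p(exp(-abs(z))) + w_tot * pmax(z, 0) - y_pos * z) / n
    nll + sum(pen * beta^2) / 2
  }
  gradient <- function(beta) {
    p <- sigmoid(drop(X %*% beta))
    drop(crossprod(X, w_tot * p - y_pos)) / n + pen * beta
  }
  beta <- c(0, 0, stats::qlogis(max(min(sum(y_pos) / n, 1 - 1e-12), 1e-12)))
  f <- objective(beta)
  for (iter in seq_len(max_iter)) {
    gr <- gradient(beta)
    if (sqrt(sum(gr^2)) < grad_tol)
      return(list(beta = beta, objective = f, iterations = iter - 1L,
                  converged = TRUE))
    p <- sigmoid(drop(X %*% beta))
    W <- w_tot * p * (1 - p)
    H <- crossprod(X, X * W) / n + diag(pen)
    step <- solve(H, gr)
    # step halving guards the few iterations before the quadratic regime
    t <- 1
    repeat {
      beta_new <- beta - t * step
      f_new <- objective(beta_new)
      if (f_new <= f + 1e-12 || t < 1e-8) break
      t <- t / 2
    }
    beta <- beta_new
    f <- f_new
  }
  stop(sprintf("logistic fit did not converge in %d Newton iterations (gradient norm %.3g)",
               max_iter, sqrt(sum(gradient(beta)^2))))
}

#' Fit a two-item regularized logistic screening model
#'
#' Fits the logistic model `P(screen positive) = sigmoid(w1*a + w2*b + bias)`
#' to the responses of two questionnaire items `a`, `b` in \{0,1,2,3\}, by
#' minimizing the mean negative log-likelihood plus an L2 penalty
#' `(w1^2 + w2^2) / (2C)` on the weights only (the bias stays free to absorb
#' prevalence). Larger `C` means a weaker penalty. The objective is strictly
#' convex; the unique optimum is found by Newton-Raphson on the 16 aggregated
#' response patterns and convergence is declared when the gradient norm drops
#' below 1e-8 (non-convergence is an error, never a silent partial result).
#'
#' @param data Labelled dataset (see [preprocess_responses()]): complete
#'   `item1..item9` columns plus logical `label`.
#' @param items Integer vector of two item indices; the first maps to `w1`.
#' @param C Inverse penalty strength, > 0.
#' @return Object of class `pair_logit` with components `items`,
#'   `coefficients` (`w1`, `w2`, `bias`), `C`, `objective`, `iterations`,
#'   `n`, `counts`.
#' @examples
#' cfg <- sim_config(500, seed = 7)
#' dat <- score_and_label(simulate_responses(cfg))
#' fit <- pair_logit(dat, items = c(2, 4), C = 1)
#' coef(fit)
#' predict(fit, data.frame(a = 2, b = 1))
#' @export
pair_logit <- function(data, items, C = 1) {
  items <- as.integer(items)
  if (length(items) != 2L || anyDuplicated(items) || any(items < 1L | items > 9L))
    stop("items must be two distinct item indices in 1..9")
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0)
    stop("C (inverse penalty strength) must be a positive finite number")
  check_labeled(data)
  counts <- pattern_counts(data, items)
  fit <- fit_logit_counts(counts, C)
  structure(
    list(items = items,
         coefficients = stats::setNames(fit$beta, c("w1", "w2", "bias")),
         C = C,
         objective = fit$objective,
         iterations = fit$iterations,
         n = sum(counts),
         counts = counts),
    class = "pair_logit")
}

#' @export
print.pair_logit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-item logistic screening model (items %d and %d)\n",
              x$items[1], x$items[2]))
  cat(sprintf("  n = %d, C = %g (inverse L2 penalty), %d Newton iterations\n",
              x$n, x$C, x$iterations))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.pair_logit <- function(object, ...) object$coefficients

#' Pattern probabilities of a fitted two-item model
#'
#' The probability the model assigns to each of the 16 response patterns
#' (a, b) in \{0..3\}^2, recomputed from the coefficients on every call (the
#' table is derived, never cached, so serialized models cannot
#' desynchronize).
#'
#' @param model A [pair_logit()] fit.
#' @return Data frame with columns `a`, `b`, `probability` (16 rows).
#' @export
pattern_probabilities <- function(model) {
  stopifnot(inherits(model, "pair_logit"))
  g <- pattern_grid()
  cf <- model$coefficients
  g$probability <- sigmoid(cf["w1"] * g$a + cf["w2"] * g$b + cf["bias"])
  g
}

#' Candidate probability thresholds of a two-item model
#'
#' The distinct values among the model's 16 pattern probabilities, in
#' descending order. Each defines one achievable decision rule on the 4 x 4
#' pattern lattice; with all probabilities distinct there are 16 candidate
#' thresholds (against the 7 cutoff rules of an unweighted two-item sum
#' score).
#'
#' @param model A [pair_logit()] fit.
#' @param tol Probabilities closer than `tol` are merged as duplicates.
#' @return Numeric vector of thresholds, descending, length <= 16.
#' @export
candidate_thresholds <- function(model, tol = 1e-12) {
  p <- sort(pattern_probabilities(model)$probability, decreasing = TRUE)
  keep <- c(TRUE, diff(p) < -tol)
  p[keep]
}

#' @export
summary.pair_logit <- function(object, ...) {
  out <- list(model = object,
              pattern_table = pattern_probabilities(object),
              thresholds = candidate_thresholds(object))
  class(out) <- "summary.pair_logit"
  out
}

#' @export
print.summary.pair_logit <- function(x, digits = 4, ...) {
  print(x$model, digits = digits)
  tab <- matrix(x$pattern_table$probability, 4, 4, byrow = TRUE,
                dimnames = list(paste0("a=", 0:3), paste0("b=", 0:3)))
  cat("\nPattern probabilities (rows: first item, cols: second item):\n")
  print(round(tab, digits))
  cat(sprintf("\n%d candidate threshold(s):\n", length(x$thresholds)))
  print(round(x$thresholds, digits))
  invisible(x)
}

#' Predict screening probabilities from a fitted two-item model
#'
#' @param object A [pair_logit()] fit.
#' @param newdata Data frame with either columns `a` and `b` (pattern form)
#'   or the full `item1..item9` columns, from which the model's two items are
#'   taken. Default: the 16-pattern grid.
#' @param type `"response"` for probabilities, `"link"` for the linear score,
#'   `"class"` for a logical classification at `threshold`.
#' @param threshold Probability threshold for `type = "class"`.
#' @param ... Unused.
#' @return Numeric (or logical) vector, one value per row of `newdata`.
#' @export
predict.pair_logit <- function(object, newdata = pattern_grid(),
                               type = c("response", "link", "class"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  if (all(c("a", "b") %in% names(newdata))) {
    a <- newdata$a; b <- newdata$b
  } else {
    cols <- paste0("item", object$items)
    if (!all(cols %in% names(newdata)))
      stop("newdata must contain columns a,b or ", paste(cols, collapse = ","))
    a <- newdata[[cols[1]]]; b <- newdata[[cols[2]]]
  }
  if (anyNA(a) || anyNA(b) || !all(c(a, b) %in% 0:3))
    stop("item responses must lie in {0,1,2,3} with no missing values")
  cf <- object$coefficients
  z <- cf["w1"] * a + cf["w2"] * b + cf["bias"]
  switch(type,
         link = unname(z),
         response = unname(sigmoid(z)),
         class = unname(sigmoid(z) >= threshold))
}

#' Heatmap of the 4 x 4 pattern-probability lattice
#'
#' Draws the model's pattern probabilities as a shaded lattice, optionally
#' overlaying the decision boundary induced by a probability threshold.
#'
#' @param x A [pair_logit()] fit.
#' @param threshold Optional probability threshold whose decision boundary
#'   (positive iff probability >= threshold) is drawn.
#' @param ... Passed to [graphics::image()].
#' @export
plot.pair_logit <- function(x, threshold = NULL, ...) {
  tab <- matrix(pattern_probabilities(x)$probability, 4, 4, byrow = TRUE)
  graphics::image(0:3, 0:3, tab, zlim = c(0, 1),
                  col = grDevices::hcl.colors(64, "Blue-Red", rev = FALSE),
                  xlab = sprintf("item %d response", x$items[1]),
                  ylab = sprintf("item %d response", x$items[2]),
                  main = sprintf("Pattern probabilities, items %d & %d",
                                 x$items[1], x$items[2]), ...)
  for (a in 0:3) for (b in 0:3) {
    pos <- !is.null(threshold) && tab[a + 1, b + 1] >= threshold
    graphics::text(a, b, sprintf("%.3f%s", tab[a + 1, b + 1],
                                 if (pos) "+" else ""), cex = 0.8)
  }
  invisible(x)
}

#' Serialize and restore fitted two-item models
#'
#' Models are written as JSON with the pair, coefficients at full precision,
#' the penalty setting, and (for human inspection only) the derived 16-entry
#' pattern table; on reading, probabilities are always recomputed from the
#' coefficients.
#'
#' @param model A [pair_logit()] fit.
#' @param path File path.
#' @name pair_logit_io
#' @export
write_pair_model <- function(model, path) {
  rec <- list(pair = model$items,
              w1 = unname(model$coefficients["w1"]),
              w2 = unname(model$coefficients["w2"]),
              b = unname(model$coefficients["bias"]),
              reg_strength = model$C,
              n = model$n,
              pattern_table = pattern_probabilities(model))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname pair_logit_io
#' @export
read_pair_model <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(items = as.integer(rec$pair),
         coefficients = stats::setNames(c(rec$w1, rec$w2, rec$b),
                                        c("w1", "w2", "bias")),
         C = rec$reg_strength,
         objective = NA_real_,
         iterations = NA_integer_,
         n = rec$n %||% NA_integer_,
         counts = NULL),
    class = "pair_logit")
}
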