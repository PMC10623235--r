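# Fixtures built in code.

# Labelled dataset with the two active items placed in given columns and all
# other items zero; labels supplied directly (they need not equal total>=10
# for model-level tests).
toy_pair_data <- function(a, b, label, items = c(1L, 2L)) {
  n <- length(a)
  df <- as.data.frame(matrix(0L, n, 9, dimnames = list(NULL, paste0("item", 1:9))))
  df[[paste0("item", items[1])]] <- as.integer(a)
  df[[paste0("item", items[2])]] <- as.integer(b)
  df <- cbind(id = seq_len(n), df)
  df$total <- as.integer(rowSums(df[paste0("item", 1:9)]))
  df$label <- as.logical(label)
  df
}

# Random small labelled dataset (both classes guaranteed).
random_pair_data <- function(n, seed, items = c(1L, 2L)) {
  set.seed(seed)
  repeat {
    a <- sample(0:3, n, replace = TRUE)
    b <- sample(0:3, n, replace = TRUE)
    p <- plogis(-1 + 0.6 * a + 0.4 * b)
    label <- runif(n) < p
    if (any(label) && !all(label)) break
  }
  toy_pair_data(a, b, label, items)
}

# Random scores/labels instance for ROC tests, with heavy ties.
random_roc_instance <- function(n, seed) {
  set.seed(seed)
  repeat {
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    labels <- runif(n) < plogis(3 * scores - 1.5)
    if (any(labels) && !all(labels)) break
  }
  list(scores = scores, labels = labels)
}

# A pair_logit object with prescribed coefficients (for closed-form pattern
# arithmetic checks that need no fitting).
manual_pair_model <- function(w1, w2, bias, items = c(1L, 2L), C = 1) {
  structure(list(items = as.integer(items),
                 coefficients = c(w1 = w1, w2 = w2, bias = bias),
                 C = C, objective = NA_real_, iterations = 0L,
                 n = NA_integer_, counts = NULL),
            class = "pair_logit")
}

# Default simulated labelled dataset reused by pipeline tests.
sim_labeled <- function(n, seed, config = sim_config(n, seed = seed)) {
  config$n_respondents <- as.integer(n)
  config$seed <- as.integer(seed)
  score_and_label(simulate_responses(config))
}

# Base configuration for planted-pair recovery experiments: uniform moderate
# loadings leave headroom for a 1.5x loading boost.
recovery_config <- function(n, seed) {
  sim_config(n, latent_correlation = onefactor_correlation(rep(0.55, 9)),
             seed = seed)
}
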