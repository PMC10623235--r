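# Independent oracles the implementation is checked against. These stay
# deliberately naive: double loops, exhaustive enumeration, quadrature, grid
# search -- never calls into the code paths they verify.

# AUC as the literal proportion of (positive, negative) pairs won, ties 1/2.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Confusion counts by classifying every row one at a time.
oracle_confusion <- function(scores, labels, threshold) {
  tp <- fp <- tn <- fn <- 0L
  for (r in seq_along(scores)) {
    pred <- scores[r] >= threshold
    if (pred && labels[r]) tp <- tp + 1L
    else if (pred && !labels[r]) fp <- fp + 1L
    else if (!pred && labels[r]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Penalized logistic objective (mean NLL + ||w||^2/(2C)) for a grid of
# candidate (w1, w2, b), evaluated on pattern counts.
grid_objective <- function(counts, C, W) {
  g <- expand.grid(b = 0:3, a = 0:3)[, c("a", "b")]
  X <- cbind(g$a, g$b, 1)
  Z <- W %*% t(X)                       # n_grid x 16
  w_tot <- counts[, "neg"] + counts[, "pos"]
  y_pos <- counts[, "pos"]
  n <- sum(counts)
  nll <- (log1p(exp(-abs(Z))) %*% w_tot + pmax(Z, 0) %*% w_tot - Z %*% y_pos) / n
  drop(nll) + (W[, 1]^2 + W[, 2]^2) / (2 * C)
}

# Staged grid search for the minimum of the convex penalized objective over
# (w1, w2, b) in [-5, 5]^3: coarse grid, then repeated refinement in a window
# of +-2 previous steps around the incumbent (the slack window guards against
# diagonal valleys; valid for a strictly convex objective, final step ~3e-4).
oracle_grid_logistic <- function(data, items, C, bounds = c(-5, 5)) {
  a <- data[[paste0("item", items[1])]]
  b <- data[[paste0("item", items[2])]]
  y <- as.integer(data$label)
  idx <- 4L * a + b + 1L + 16L * y
  counts <- matrix(tabulate(idx, nbins = 32L), 16L, 2L,
                   dimnames = list(NULL, c("neg", "pos")))
  centre <- c(0, 0, 0)
  half <- diff(bounds) / 2
  step <- half / 25
  best <- NULL
  for (stage in 1:5) {
    ax <- lapply(centre, function(m) seq(m - half, m + half, by = step))
    W <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
    W <- W[apply(W >= bounds[1] & W <= bounds[2], 1, all), , drop = FALSE]
    f <- grid_objective(counts, C, W)
    best <- min(f)
    centre <- W[which.min(f), ]
    half <- 2 * step
    step <- step / 5
  }
  list(objective = best, par = centre)
}

# P(a1 < X <= b1, a2 < Y <= b2) for standard bivariate normal with
# correlation rho, by adaptive quadrature over the conditional distribution.
oracle_bvn_rect <- function(a1, b1, a2, b2, rho) {
  s <- sqrt(1 - rho^2)
  f <- function(x) {
    stats::dnorm(x) * (stats::pnorm((b2 - rho * x) / s) -
                         stats::pnorm((a2 - rho * x) / s))
  }
  stats::integrate(f, lower = max(a1, -40), upper = min(b1, 40),
                   rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# 4 x 4 joint pmf of two 0-3 ordinal items under the Gaussian copula with
# marginals p1, p2 and latent correlation rho.
oracle_joint_pmf <- function(p1, p2, rho) {
  c1 <- c(-Inf, stats::qnorm(cumsum(p1)[1:3]), Inf)
  c2 <- c(-Inf, stats::qnorm(cumsum(p2)[1:3]), Inf)
  pmf <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    pmf[i, j] <- oracle_bvn_rect(c1[i], c1[i + 1], c2[j], c2[j + 1], rho)
  }
  pmf
}

# Population Spearman correlation (midrank/grade form, the large-sample limit
# of cor(..., method = "spearman") with ties) for a discrete joint pmf.
oracle_spearman <- function(pmf) {
  px <- rowSums(pmf); py <- colSums(pmf)
  gx <- cumsum(px) - px / 2    # grades: F(x-) + p/2
  gy <- cumsum(py) - py / 2
  mx <- sum(gx * px); my <- sum(gy * py)
  vx <- sum((gx - mx)^2 * px); vy <- sum((gy - my)^2 * py)
  cv <- sum(outer(gx - mx, gy - my) * pmf)
  cv / sqrt(vx * vy)
}
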