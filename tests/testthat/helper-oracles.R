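# Independent oracles used to cross-check the implementation.

# Soft-margin SVM via the dual box-constrained QP, solved with kernlab's
# generic interior-point solver (independent of libsvm's SMO).
svmOracleQP <- function(X, y, C) {
  X <- as.matrix(X)
  n <- nrow(X)
  K <- tcrossprod(X)
  H <- (y %o% y) * K + diag(1e-10, n)
  sol <- kernlab::ipop(c = rep(-1, n), H = H,
                       A = matrix(as.numeric(y), 1L), b = 0,
                       l = rep(0, n), u = rep(C, n), r = 0,
                       sigf = 10, maxiter = 200)
  alpha <- kernlab::primal(sol)
  w <- unname(drop(crossprod(X, alpha * y)))
  free <- which(alpha > 1e-6 * C & alpha < C * (1 - 1e-6))
  b <- if (length(free)) mean(y[free] - drop(X[free, , drop = FALSE] %*% w))
       else NA_real_
  list(weights = w, intercept = b)
}

# Platt objective (negative log-likelihood with smoothed targets),
# written independently of the package's internals.
plattOracleObjective <- function(par, fvals, yvals) {
  n_pos <- sum(yvals > 0)
  n_neg <- sum(yvals < 0)
  t <- ifelse(yvals > 0, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  fApB <- par[1L] * fvals + par[2L]
  sum(ifelse(fApB >= 0, t * fApB + log1p(exp(-fApB)),
             (t - 1) * fApB + log1p(exp(fApB))))
}

# Grid search plus Nelder-Mead refinement of the Platt objective.
plattOracle <- function(fvals, yvals) {
  grid_a <- seq(-25, 5, by = 0.25)
  grid_b <- seq(-5, 5, by = 0.1)
  best <- c(0, 0)
  best_val <- Inf
  for (a in grid_a) {
    vals <- vapply(grid_b, function(b)
      plattOracleObjective(c(a, b), fvals, yvals), numeric(1))
    k <- which.min(vals)
    if (vals[k] < best_val) {
      best_val <- vals[k]
      best <- c(a, grid_b[k])
    }
  }
  opt <- stats::optim(best, plattOracleObjective, fvals = fvals,
                      yvals = yvals, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 20000))
  list(platt_a = opt$par[1L], platt_b = opt$par[2L])
}

# AUC as the pairwise concordance count, ties counted one half.
aucConcordance <- function(p, is_pos) {
  pos <- p[is_pos]
  neg <- p[!is_pos]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# Exhaustive threshold search over candidate probabilities.
thresholdOracle <- function(p, is_pos, objective, target = NULL) {
  cands <- sort(unique(p))
  tpr <- vapply(cands, function(t) mean(p[is_pos] >= t), numeric(1))
  fpr <- vapply(cands, function(t) mean(p[!is_pos] >= t), numeric(1))
  if (objective == "youden") {
    j <- tpr - fpr
    cands[which(j == max(j))][1L]
  } else {
    ok <- cands[tpr >= target]
    if (!length(ok)) NA_real_ else max(ok)
  }
}
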