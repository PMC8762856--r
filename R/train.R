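## Training of one-vs-rest, probability-calibrated linear classifiers.

#' Training configuration
#'
#' @param kernel only `"linear"` is supported; the field is kept for
#'   future kernels.
#' @param cost_c soft-margin cost C (> 0); the penalty weight on margin
#'   violations (regularization strength 1/C). Used when `tune_cost` is
#'   `FALSE`, and as the fallback when tuning is not possible.
#' @param balance `"downsample"` (seeded downsampling of the majority
#'   class to the minority size; the default, because one-vs-rest labels
#'   are typically very imbalanced) or `"none"`.
#' @param seed integer seed driving the balancing draw and the
#'   cross-validation folds.
#' @param min_cells_per_class minimum training cells required per class
#'   (>= 2).
#' @param tune_cost select the cost by stratified 5-fold cross-validated
#'   accuracy on the balanced training set (default `TRUE`, echoing the
#'   resampling-based tuning of the caret-style training stacks this
#'   workflow descends from); ties resolve to the smallest cost, i.e.
#'   the strongest regularization.
#' @param cost_grid candidate costs for `tune_cost`.
#' @return A `TrainingConfig` list.
#' @export
trainingConfig <- function(kernel = "linear", cost_c = 1.0,
                           balance = c("downsample", "none"), seed = 1L,
                           min_cells_per_class = 10L, tune_cost = TRUE,
                           cost_grid = c(0.01, 0.1, 1, 10)) {
  balance <- match.arg(balance)
  if (!identical(kernel, "linear"))
    ctStop("validity_error", "only the linear kernel is supported")
  assertScalarNumber(cost_c, "cost_c")
  if (cost_c <= 0) ctStop("validity_error", "cost_c must be positive")
  if (min_cells_per_class < 2L)
    ctStop("validity_error", "min_cells_per_class must be at least 2")
  if (!is.numeric(cost_grid) || !length(cost_grid) || any(cost_grid <= 0))
    ctStop("validity_error", "cost_grid must be positive numbers")
  structure(list(kernel = kernel, cost_c = cost_c, balance = balance,
                 seed = as.integer(seed),
                 min_cells_per_class = as.integer(min_cells_per_class),
                 tune_cost = isTRUE(tune_cost),
                 cost_grid = sort(as.numeric(cost_grid))),
            class = "TrainingConfig")
}

## Stratified k-fold CV accuracy over the cost grid; ties -> smallest
## cost. Returns cfg$cost_c when folds cannot be formed.
selectCost <- function(Z, y, cfg, k = 5L) {
  pos <- which(y > 0)
  neg <- which(y < 0)
  if (length(pos) < k || length(neg) < k) return(cfg$cost_c)
  folds <- integer(length(y))
  withr::with_seed(cfg$seed, {
    folds[pos] <- sample(rep_len(seq_len(k), length(pos)))
    folds[neg] <- sample(rep_len(seq_len(k), length(neg)))
  })
  acc <- vapply(cfg$cost_grid, function(C) {
    hits <- unlist(lapply(seq_len(k), function(fold) {
      tr <- folds != fold
      fit <- tryCatch(fitLinearSVM(Z[tr, , drop = FALSE], y[tr], C),
                      scTypeTree_error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      f <- drop(Z[!tr, , drop = FALSE] %*% fit$weights) + fit$intercept
      (f >= 0) == (y[!tr] > 0)
    }))
    if (is.null(hits)) NA_real_ else mean(hits)
  }, numeric(1))
  if (all(is.na(acc))) return(cfg$cost_c)
  cfg$cost_grid[which.max(acc)]
}

#' One-vs-rest binary labels
#'
#' @param labels per-cell character labels.
#' @param positive_type the cell type to mark `+1`.
#' @param aliases optional extra label spellings (or descendant labels)
#'   also counted as positive.
#' @return Integer vector in `{+1, -1}`, one per cell.
#' @export
makeBinaryLabels <- function(labels, positive_type, aliases = NULL) {
  pos <- labels %in% c(positive_type, aliases)
  if (!any(pos) || all(pos))
    ctStop("degenerate_labels_error",
           "labels for '%s' yield a single class (%d positive of %d)",
           positive_type, sum(pos), length(labels))
  ifelse(pos, 1L, -1L)
}

#' Balance classes by downsampling the majority
#'
#' Keeps every minority-class cell and a seeded random subset of the
#' majority class of equal size.
#'
#' @param y integer labels in `{+1, -1}`.
#' @param seed integer seed.
#' @return Sorted integer indices of the retained cells.
#' @export
balanceDownsample <- function(y, seed = 1L) {
  pos <- which(y > 0)
  neg <- which(y < 0)
  if (!length(pos) || !length(neg))
    ctStop("degenerate_labels_error", "both classes must be present")
  n <- min(length(pos), length(neg))
  keep <- withr::with_seed(as.integer(seed), {
    c(if (length(pos) > n) sample(pos, n) else pos,
      if (length(neg) > n) sample(neg, n) else neg)
  })
  sort(keep)
}

#' Fit a soft-margin linear SVM
#'
#' Standard C-SVM (hinge loss, L2 penalty, regularization strength
#' `1/cost_c`) on already-standardized features; delegates the
#' optimization to libsvm. The returned decision function
#' \eqn{f(x) = w \cdot x + b} is positive toward the `+1` class.
#'
#' @param X numeric matrix (cells x features), standardized, no constant
#'   columns.
#' @param y integer labels in `{+1, -1}`.
#' @param cost_c soft-margin cost C.
#' @return `list(weights, intercept)` with `weights` named by column.
#' @export
fitLinearSVM <- function(X, y, cost_c = 1.0) {
  X <- as.matrix(X)
  if (length(unique(y)) != 2L)
    ctStop("degenerate_labels_error", "both classes must be present")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    ctStop("degenerate_features_error",
           "constant feature column(s): %s",
           paste(colnames(X)[sds == 0], collapse = ", "))
  fit <- tryCatch(
    e1071::svm(x = X, y = factor(y, levels = c(-1L, 1L)),
               type = "C-classification", kernel = "linear",
               cost = cost_c, scale = FALSE, tolerance = 1e-8),
    error = function(e)
      ctStop("optimization_error", "SVM fit failed: %s",
             conditionMessage(e)))
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  ## libsvm orients the decision function toward the first class it saw;
  ## fix the sign so f is positive toward +1.
  f <- drop(X %*% w) + b
  if (mean(f[y > 0]) < mean(f[y < 0])) {
    w <- -w
    b <- -b
  }
  names(w) <- colnames(X)
  list(weights = w, intercept = b)
}

## Platt negative log-likelihood with smoothed targets; stable in fApB.
plattObjective <- function(par, f, t) {
  fApB <- par[1L] * f + par[2L]
  sum(ifelse(fApB >= 0, t * fApB + log1p(exp(-fApB)),
             (t - 1) * fApB + log1p(exp(fApB))))
}

#' Platt sigmoid calibration
#'
#' Fits the probability map \eqn{p(f) = 1/(1 + \exp(A f + B))} to
#' decision values by minimizing the negative log-likelihood with
#' Platt's smoothed targets \eqn{t_+ = (N_+ + 1)/(N_+ + 2)},
#' \eqn{t_- = 1/(N_- + 2)} (a Bayesian correction that keeps fitted
#' probabilities off 0 and 1). Newton's method with backtracking line
#' search on the convex objective. `A` comes out negative whenever
#' decision values are positively associated with the `+1` class.
#'
#' @param decision_values numeric decision values \eqn{f}.
#' @param y integer labels in `{+1, -1}`.
#' @param max_iter,min_step,sigma,grad_tol Newton iteration cap,
#'   smallest admissible line-search step, Hessian ridge, and gradient
#'   stopping tolerance.
#' @return `list(platt_a, platt_b)`.
#' @export
calibratePlatt <- function(decision_values, y, max_iter = 200L,
                           min_step = 1e-10, sigma = 1e-12,
                           grad_tol = 1e-6) {
  f <- as.numeric(decision_values)
  n_pos <- sum(y > 0)
  n_neg <- sum(y < 0)
  if (!n_pos || !n_neg)
    ctStop("degenerate_labels_error", "both classes must be present")
  hi <- (n_pos + 1) / (n_pos + 2)
  lo <- 1 / (n_neg + 2)
  t <- ifelse(y > 0, hi, lo)
  A <- 0
  B <- log((n_neg + 1) / (n_pos + 1))
  fval <- plattObjective(c(A, B), f, t)
  for (it in seq_len(max_iter)) {
    fApB <- A * f + B
    p <- invLogitNeg(fApB)           # 1/(1+exp(fApB))
    q <- 1 - p
    d1 <- t - p                      # gradient pieces: dF/dA = sum f*d1
    pq <- p * q
    h11 <- sum(f * f * pq) + sigma
    h22 <- sum(pq) + sigma
    h21 <- sum(f * pq)
    g1 <- sum(f * d1)
    g2 <- sum(d1)
    if (abs(g1) < grad_tol && abs(g2) < grad_tol) break
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      newA <- A + step * dA
      newB <- B + step * dB
      newf <- plattObjective(c(newA, newB), f, t)
      if (newf < fval + 1e-4 * step * gd) {
        A <- newA; B <- newB; fval <- newf
        break
      }
      step <- step / 2
      if (step < min_step) {
        ## no representable step improves the objective: either we are
        ## at numerical precision (tiny gradient) or genuinely stuck
        if (max(abs(g1), abs(g2)) < 1e-3) break
        ctStop("optimization_error",
               "Platt calibration line search failed at iteration %d", it)
      }
    }
    if (step < min_step) break
  }
  if (it >= max_iter && (abs(g1) > 1e-3 || abs(g2) > 1e-3))
    ctStop("optimization_error",
           "Platt calibration did not converge in %d iterations", max_iter)
  list(platt_a = A, platt_b = B)
}

## Lineage of `parent` within `db`, plus the trainee itself.
parentLineage <- function(db, parent, cell_type)
  unique(c(parent, descendantsOf(db, parent), cell_type))

#' Train a cell-type classifier
#'
#' One-vs-rest training pipeline: optionally restrict to cells of the
#' parent lineage (by their labels), normalize raw counts, extract the
#' feature panel, drop constant features (with a warning), standardize
#' (storing the constants), balance classes, fit the linear SVM, and
#' calibrate probabilities on the training decision values.
#'
#' @param m an [ExpressionMatrix-class] (raw counts are normalized
#'   internally).
#' @param labels per-cell character labels, aligned with `m`'s cells.
#' @param cell_type the type this classifier detects.
#' @param features candidate gene symbols (e.g. markers).
#' @param cfg a [trainingConfig()].
#' @param parent_db database containing the parent (required when
#'   `parent` is given).
#' @param parent optional parent cell-type name; training is then
#'   restricted to cells labeled with the parent lineage and the
#'   negative class becomes "other cells of the parent type".
#' @param aliases optional labels also counted as `cell_type` (e.g.
#'   alternative spellings, or descendant types when training a parent).
#' @param threshold acceptance threshold stored in the classifier.
#' @return A [CellClassifier-class].
#' @export
trainClassifier <- function(m, labels, cell_type, features, cfg = trainingConfig(),
                            parent_db = NULL, parent = NA_character_,
                            aliases = NULL, threshold = 0.5) {
  stopifnot(is(m, "ExpressionMatrix"))
  labels <- as.character(labels)
  if (length(labels) != nrow(m@values))
    ctStop("alignment_error", "%d labels for %d cells", length(labels),
           nrow(m@values))
  if (!is.na(parent)) {
    if (is.null(parent_db) || !parent %in% cellTypes(parent_db))
      ctStop("unresolved_parent_error",
             "parent '%s' is not present in the supplied database", parent)
    lineage <- parentLineage(parent_db, parent, cell_type)
    keep <- labels %in% c(lineage, aliases)
    m <- m[keep]
    labels <- labels[keep]
  }
  y <- makeBinaryLabels(labels, cell_type, aliases = aliases)
  if (sum(y > 0) < cfg$min_cells_per_class ||
      sum(y < 0) < cfg$min_cells_per_class)
    ctStop("sample_size_error",
           "need at least %d cells per class for '%s' (have %d positive, %d negative)",
           cfg$min_cells_per_class, cell_type, sum(y > 0), sum(y < 0))
  if (!isNormalized(m)) m <- normalizeCounts(m)
  fm <- extractFeatures(m, features)
  X <- fm@values
  sds <- apply(X, 2L, stats::sd)
  keep_feat <- sds > 0
  if (!any(keep_feat))
    ctStop("degenerate_features_error",
           "all %d features are constant on the training cells", ncol(X))
  if (any(!keep_feat))
    ctWarn("constant_features_warning",
           "dropping %d constant feature(s): %s", sum(!keep_feat),
           paste(colnames(X)[!keep_feat], collapse = ", "))
  X <- X[, keep_feat, drop = FALSE]
  means <- colMeans(X)
  sds <- sds[keep_feat]
  Z <- sweep(sweep(X, 2L, means, "-"), 2L, sds, "/")
  idx <- if (cfg$balance == "downsample") balanceDownsample(y, cfg$seed)
         else seq_along(y)
  cost <- if (cfg$tune_cost) selectCost(Z[idx, , drop = FALSE], y[idx], cfg)
          else cfg$cost_c
  svm_fit <- fitLinearSVM(Z[idx, , drop = FALSE], y[idx], cost)
  f_train <- drop(Z[idx, , drop = FALSE] %*% svm_fit$weights) +
    svm_fit$intercept
  cal <- calibratePlatt(f_train, y[idx])
  model <- linearBinaryModel(
    feature_names = colnames(X), weights = svm_fit$weights,
    intercept = svm_fit$intercept, platt_a = cal$platt_a,
    platt_b = cal$platt_b, feature_means = means, feature_sds = sds)
  cellClassifier(cell_type, model, threshold = threshold, parent = parent)
}

#' Train a whole classifier database
#'
#' Trains one classifier per row of `hierarchy` in parent-before-child
#' order. When a type has descendants in the hierarchy, those descendant
#' labels are automatically counted as positives for it (a plasma cell
#' *is* a B cell), and child classifiers are trained only on their
#' parent-lineage cells.
#'
#' @param m an [ExpressionMatrix-class].
#' @param labels per-cell character labels.
#' @param hierarchy data.frame with columns `cell_type` and `parent`
#'   (`NA` for roots).
#' @param feature_sets named list: `cell_type` -> character vector of
#'   candidate genes.
#' @param cfg a [trainingConfig()].
#' @param threshold acceptance threshold for every classifier.
#' @param inherit_features give each classifier the union of its own and
#'   its descendants' feature sets (default `TRUE`): a parent classifier
#'   must accept all its subtypes, so it needs their markers too.
#' @return A [ClassifierDatabase-class].
#' @export
trainDatabase <- function(m, labels, hierarchy, feature_sets,
                          cfg = trainingConfig(), threshold = 0.5,
                          inherit_features = TRUE) {
  stopifnot(all(c("cell_type", "parent") %in% names(hierarchy)))
  parent_of <- stats::setNames(as.character(hierarchy$parent),
                               hierarchy$cell_type)
  desc <- function(ct) {
    kids <- names(parent_of)[!is.na(parent_of) & parent_of == ct]
    unlist(c(kids, lapply(kids, desc)), use.names = FALSE)
  }
  ## parents before children
  depth <- vapply(hierarchy$cell_type, function(ct) {
    d <- 0L
    while (!is.na(parent_of[[ct]])) {
      d <- d + 1L
      ct <- parent_of[[ct]]
      if (d > nrow(hierarchy)) break
    }
    d
  }, integer(1))
  db <- classifierDatabase()
  for (ct in hierarchy$cell_type[order(depth)]) {
    feats <- feature_sets[[ct]]
    if (inherit_features)
      feats <- unique(c(feats, unlist(feature_sets[desc(ct)],
                                      use.names = FALSE)))
    db <- addClassifier(db, trainClassifier(
      m, labels, cell_type = ct, features = feats, cfg = cfg,
      parent_db = db, parent = parent_of[[ct]], aliases = desc(ct),
      threshold = threshold))
  }
  db
}
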