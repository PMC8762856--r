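## Hierarchical application of a classifier database.

#' @describeIn predictProbability calibrated probability of one cell type
#'   for every cell: \eqn{p = 1/(1 + \exp(A f + B))} with
#'   \eqn{f = w \cdot z + b} computed on the standardized feature panel.
#'   Only the classifier's feature columns are densified.
#' @param auto_normalize normalize raw counts on the fly (default `TRUE`).
#' @export
setMethod("predictProbability", signature("CellClassifier", "ExpressionMatrix"),
  function(classifier, m, auto_normalize = TRUE, ...) {
    if (!isNormalized(m)) {
      if (!auto_normalize)
        ctStop("validity_error",
               "matrix is raw counts; normalize it or set auto_normalize = TRUE")
      m <- normalizeCounts(m)
    }
    mod <- classifier@model
    fm <- extractFeatures(m, mod@feature_names)
    z <- standardizeFeatures(fm, mod@feature_means, mod@feature_sds)
    f <- drop(z@values %*% mod@weights) + mod@intercept
    p <- invLogitNeg(mod@platt_a * f + mod@platt_b)
    ## keep probabilities strictly inside (0, 1)
    eps <- .Machine$double.eps
    p <- pmin(pmax(p, eps), 1 - eps)
    stats::setNames(p, rownames(fm@values))
  })

resolveThresholds <- function(db, threshold_overrides = NULL) {
  thr <- vapply(db@entries, probThreshold, numeric(1))
  if (length(threshold_overrides)) {
    bad <- setdiff(names(threshold_overrides), names(thr))
    if (length(bad))
      ctStop("not_found_error", "threshold override(s) for unknown type(s): %s",
             paste(bad, collapse = ", "))
    ov <- unlist(threshold_overrides)
    if (any(ov <= 0 | ov >= 1))
      ctStop("validity_error", "threshold overrides must lie in (0, 1)")
    thr[names(ov)] <- ov
  }
  thr
}

#' Classify cells with a classifier database
#'
#' Root classifiers are evaluated on every cell; a child classifier is
#' evaluated only on cells whose parent probability meets the parent's
#' threshold (comparison is `>=`). Per cell, the candidate set consists
#' of the *deepest* passing type on each passing branch — a passing
#' child replaces its passing ancestor. The assignment is `"unknown"`
#' when no classifier passes, the single name when one candidate
#' remains, and the slash-joined lexicographically sorted names when
#' several branches pass. `best_guess` is the candidate with the highest
#' probability (ties broken lexicographically).
#'
#' @param db a valid [ClassifierDatabase-class].
#' @param m a non-empty [ExpressionMatrix-class].
#' @param threshold_overrides optional named numeric, per-type threshold
#'   replacements for this run (the stored database is untouched).
#' @param auto_normalize normalize raw counts on the fly.
#' @return A [PredictionTable-class].
#' @export
classifyCells <- function(db, m, threshold_overrides = NULL,
                          auto_normalize = TRUE) {
  stopifnot(is(db, "ClassifierDatabase"), is(m, "ExpressionMatrix"))
  viol <- validateDatabase(db)
  if (length(viol))
    ctStop("validation_error", "invalid classifier database: %s",
           paste(viol, collapse = "; "))
  if (nrow(m@values) == 0L)
    ctStop("validity_error", "the expression matrix contains no cells")
  if (!isNormalized(m)) {
    if (!auto_normalize)
      ctStop("validity_error",
             "matrix is raw counts; normalize it or set auto_normalize = TRUE")
    m <- normalizeCounts(m)
  }
  cells <- rownames(m@values)
  types <- names(db@entries)            # database insertion order
  thr <- resolveThresholds(db, threshold_overrides)
  probs <- matrix(NA_real_, nrow = length(cells), ncol = length(types),
                  dimnames = list(cells, types))
  for (ct in topoOrder(db)) {
    clf <- db@entries[[ct]]
    p_parent <- parentType(clf)
    eligible <- if (is.na(p_parent)) seq_along(cells)
                else which(!is.na(probs[, p_parent]) &
                           probs[, p_parent] >= thr[p_parent])
    if (!length(eligible)) next
    probs[eligible, ct] <- predictProbability(clf, m[eligible])
  }
  pass <- !is.na(probs) & probs >= matrix(thr, nrow = length(cells),
                                          ncol = length(types), byrow = TRUE)
  kids <- childrenMap(db)
  assignment <- character(length(cells))
  best <- character(length(cells))
  for (i in seq_along(cells)) {
    passing <- types[pass[i, ]]
    ## deepest passing node per branch: drop any passing type with a
    ## passing child (a child can only pass if its parent passed)
    cand <- passing[vapply(passing, function(ct)
      !any(kids[[ct]] %in% passing), logical(1))]
    if (!length(cand)) {
      assignment[i] <- "unknown"
      best[i] <- "unknown"
    } else {
      cand <- sort(cand)
      assignment[i] <- paste(cand, collapse = "/")
      best[i] <- cand[order(-probs[i, cand], cand)][1L]
    }
  }
  new("PredictionTable", probs = probs, thresholds = thr,
      best_guess = best, assignment = assignment)
}

#' Change a classifier's acceptance threshold
#'
#' Thresholds are adjustable without retraining: only the stored
#' threshold changes, the model is untouched.
#'
#' @param db a [ClassifierDatabase-class].
#' @param cell_type classifier to adjust.
#' @param new_threshold probability in (0, 1).
#' @return The updated database.
#' @export
setThreshold <- function(db, cell_type, new_threshold) {
  stopifnot(is(db, "ClassifierDatabase"))
  if (!cell_type %in% names(db@entries))
    ctStop("not_found_error", "no classifier named '%s' in the database",
           cell_type)
  assertScalarNumber(new_threshold, "new_threshold")
  if (new_threshold <= 0 || new_threshold >= 1)
    ctStop("validity_error", "threshold must lie strictly between 0 and 1")
  db@entries[[cell_type]]@threshold <- as.numeric(new_threshold)
  db
}

#' Write predictions to CSV
#'
#' Columns: `cell_id`, `assignment`, `best_guess`, then `p_<cell type>`
#' in database insertion order; not-evaluated probabilities are written
#' as `NA`.
#'
#' @param pt a [PredictionTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(pt, path) {
  stopifnot(is(pt, "PredictionTable"))
  utils::write.csv(as.data.frame(pt), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
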