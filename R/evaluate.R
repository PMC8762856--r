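## Benchmark metrics: dataset accuracy, per-type sensitivity/specificity,
## unknown population detection, ROC and threshold tuning.

## assignment string -> character set of asserted types ("unknown" -> none)
assignmentSet <- function(a) {
  if (identical(a, "unknown") || !nzchar(a)) character(0)
  else strsplit(a, "/", fixed = TRUE)[[1L]]
}

## is `anc` a strict ancestor of `type` under the named parent map?
isAncestor <- function(anc, type, parent_map) {
  p <- parent_map[[type]]
  steps <- 0L
  while (!is.null(p) && !is.na(p)) {
    if (identical(p, anc)) return(TRUE)
    p <- parent_map[[p]]
    steps <- steps + 1L
    if (steps > length(parent_map)) break
  }
  FALSE
}

extractAssignments <- function(preds, truth) {
  if (is(preds, "PredictionTable")) {
    a <- assignments(preds)
  } else if (is.character(preds)) {
    a <- preds
  } else {
    ctStop("validity_error",
           "preds must be a PredictionTable or a character vector")
  }
  if (!is.null(names(a)) && !is.null(names(truth))) {
    if (!setequal(names(a), names(truth)))
      ctStop("alignment_error",
             "truth and predictions cover different cells")
    a <- a[names(truth)]
  } else if (length(a) != length(truth)) {
    ctStop("alignment_error", "%d predictions for %d truth labels",
           length(a), length(truth))
  }
  a
}

#' Score predictions against truth labels
#'
#' Two scoring variants, mirroring a dual benchmark convention for tools
#' that can emit ambiguous or intermediate labels:
#' * `strict`: a cell with an in-reference truth is correct only when
#'   the assignment is exactly that single type (ambiguous sets count as
#'   incorrect even when they contain the truth).
#' * `intermediate_accepted`: additionally correct when the truth is a
#'   member of the assignment set, or the assignment is a single
#'   ancestor of the truth in the hierarchy.
#'
#' A cell whose truth is absent from `reference_types` is correct iff it
#' was assigned `"unknown"`. Sensitivity for type `t` is the fraction of
#' truth-`t` cells scored correct; specificity for `t` is the fraction
#' of truth-not-`t` cells whose assignment set does not assert `t`.
#' Mean sensitivity/specificity are unweighted across reference types
#' present in the truth.
#'
#' @param truth per-cell character labels (optionally named by cell id).
#' @param preds a [PredictionTable-class] or character assignments.
#' @param reference_types types the classifier database knows.
#' @param hierarchy optional named character: type -> parent (`NA` for
#'   roots), used by the intermediate-accepted variant; a
#'   [ClassifierDatabase-class] is also accepted.
#' @param variant `"strict"` or `"intermediate_accepted"`.
#' @param include_unknown_truth include out-of-reference cells in the
#'   dataset-level accuracy denominator (default `TRUE`).
#' @return A [MetricsReport-class].
#' @export
scorePredictions <- function(truth, preds, reference_types,
                             hierarchy = NULL,
                             variant = c("strict", "intermediate_accepted"),
                             include_unknown_truth = TRUE) {
  variant <- match.arg(variant)
  truth <- stats::setNames(as.character(truth), names(truth))
  a <- extractAssignments(preds, truth)
  if (is(hierarchy, "ClassifierDatabase"))
    hierarchy <- stats::setNames(
      vapply(hierarchy@entries, parentType, character(1)),
      cellTypes(hierarchy))
  parent_map <- as.list(hierarchy %||% stats::setNames(character(0),
                                                       character(0)))
  sets <- lapply(a, assignmentSet)
  in_ref <- truth %in% reference_types
  correct <- logical(length(truth))
  for (i in seq_along(truth)) {
    s <- sets[[i]]
    if (in_ref[i]) {
      hit <- length(s) == 1L && identical(s, truth[[i]])
      if (!hit && variant == "intermediate_accepted")
        hit <- truth[[i]] %in% s ||
          (length(s) == 1L && isAncestor(s, truth[[i]], parent_map))
      correct[i] <- hit
    } else {
      correct[i] <- length(s) == 0L
    }
  }
  denom <- if (include_unknown_truth) rep(TRUE, length(truth)) else in_ref
  accuracy <- if (any(denom)) mean(correct[denom]) else undefinedRate()
  types <- sort(intersect(reference_types, unique(truth)))
  per_type <- data.frame(cell_type = types,
                         sensitivity = NA_real_, specificity = NA_real_,
                         stringsAsFactors = FALSE)
  for (k in seq_along(types)) {
    t <- types[k]
    is_t <- truth == t
    per_type$sensitivity[k] <- mean(correct[is_t])
    asserts_t <- vapply(sets, function(s) t %in% s, logical(1))
    per_type$specificity[k] <- if (any(!is_t)) mean(!asserts_t[!is_t])
                               else undefinedRate()
  }
  new("MetricsReport",
      accuracy = accuracy, per_type = per_type,
      mean_sensitivity = if (nrow(per_type)) mean(per_type$sensitivity)
                         else undefinedRate(),
      mean_specificity = if (nrow(per_type))
                           mean(per_type$specificity, na.rm = TRUE)
                         else undefinedRate(),
      unknown_detection_rate = unknownDetectionRate(truth, a,
                                                    reference_types),
      variant = variant)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unknown population detection rate
#'
#' Among cells whose true type is absent from the reference: the
#' fraction assigned `"unknown"`. `NA` when no such cells exist.
#'
#' @param truth per-cell character labels.
#' @param preds a [PredictionTable-class] or character assignments.
#' @param reference_types types present in the reference.
#' @return A fraction in \[0, 1\], or `NA`.
#' @export
unknownDetectionRate <- function(truth, preds, reference_types) {
  truth <- stats::setNames(as.character(truth), names(truth))
  a <- extractAssignments(preds, truth)
  out <- !(truth %in% reference_types)
  if (!any(out)) return(undefinedRate())
  mean(a[out] == "unknown")
}

#' ROC points and area under the curve for one classifier
#'
#' Evaluates the classifier's probabilities on `m` and sweeps the
#' acceptance threshold over the sorted unique probabilities
#' (acceptance is `>=`). The area is computed by the trapezoid rule.
#'
#' @param classifier a [CellClassifier-class].
#' @param m an [ExpressionMatrix-class].
#' @param truth per-cell labels; positives are cells labeled
#'   `cellType(classifier)` (or an alias).
#' @param aliases labels also counted as positive.
#' @return `list(points, auc)`: `points` is a data.frame with columns
#'   `threshold`, `tpr`, `fpr`.
#' @export
rocPoints <- function(classifier, m, truth, aliases = NULL) {
  p <- predictProbability(classifier, m)
  y <- truth %in% c(cellType(classifier), aliases)
  if (!any(y) || all(y))
    ctStop("degenerate_truth_error",
           "both classes must be present to compute a ROC curve")
  thr <- sort(unique(p))
  tpr <- vapply(thr, function(t) mean(p[y] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(p[!y] >= t), numeric(1))
  pts <- data.frame(threshold = thr, tpr = tpr, fpr = fpr)
  ## trapezoid over the full curve, anchored at (0,0) and (1,1)
  ox <- c(0, rev(fpr), 1)
  oy <- c(0, rev(tpr), 1)
  auc <- sum(diff(ox) * (utils::head(oy, -1L) + utils::tail(oy, -1L)) / 2)
  list(points = pts, auc = auc)
}

#' Tune a classifier's threshold from labeled data
#'
#' Candidate thresholds are the observed unique probabilities.
#' `"youden"` maximizes `tpr - fpr` (ties resolved to the lowest
#' threshold); `"target_sensitivity"` returns the largest threshold
#' still achieving `tpr >= target`.
#'
#' @param classifier a [CellClassifier-class].
#' @param m an [ExpressionMatrix-class].
#' @param truth per-cell labels.
#' @param objective `"youden"` or `"target_sensitivity"`.
#' @param target required sensitivity for `"target_sensitivity"`.
#' @param aliases labels also counted as positive.
#' @return The selected threshold (numeric).
#' @export
tuneThreshold <- function(classifier, m, truth,
                          objective = c("youden", "target_sensitivity"),
                          target = NULL, aliases = NULL) {
  objective <- match.arg(objective)
  p <- predictProbability(classifier, m)
  y <- truth %in% c(cellType(classifier), aliases)
  if (!any(y) || all(y))
    ctStop("degenerate_truth_error", "both classes must be present")
  thr <- sort(unique(p))
  tpr <- vapply(thr, function(t) mean(p[y] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(p[!y] >= t), numeric(1))
  if (objective == "youden") {
    thr[which.max(tpr - fpr)]
  } else {
    assertScalarNumber(target, "target")
    ok <- which(tpr >= target)
    if (!length(ok))
      ctStop("infeasible_error",
             "no threshold reaches sensitivity %g (maximum attainable: %g)",
             target, max(tpr))
    max(thr[ok])
  }
}

#' Write a metrics report pair to CSV
#'
#' `summary.csv` holds one row per variant (accuracy, mean
#' sensitivity/specificity, unknown detection rate);
#' `per_type.csv` holds the per-type sensitivities/specificities.
#'
#' @param reports list of [MetricsReport-class] objects.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeMetrics <- function(reports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- do.call(rbind, lapply(reports, function(r)
    data.frame(variant = r@variant, accuracy = r@accuracy,
               mean_sensitivity = r@mean_sensitivity,
               mean_specificity = r@mean_specificity,
               unknown_detection_rate = r@unknown_detection_rate)))
  utils::write.csv(summary, file.path(dir, "summary.csv"), row.names = FALSE)
  per_type <- do.call(rbind, lapply(reports, function(r)
    cbind(variant = r@variant, r@per_type)))
  utils::write.csv(per_type, file.path(dir, "per_type.csv"),
                   row.names = FALSE)
  invisible(dir)
}
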