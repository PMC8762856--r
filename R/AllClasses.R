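#' Linear binary decision model with Platt calibration
#'
#' Holds everything needed to score cells for one cell type: the linear
#' decision function \eqn{f(x) = w \cdot z + b} on standardized feature
#' values \eqn{z = (x - \mu)/\sigma}, and the sigmoid calibration pair
#' \eqn{(A, B)} mapping decision values to probabilities
#' \eqn{p(f) = 1/(1 + \exp(A f + B))}.
#'
#' @slot feature_names character, ordered gene symbols the model uses.
#' @slot weights numeric, one weight per feature.
#' @slot intercept numeric(1), the decision-function intercept \eqn{b}.
#' @slot platt_a numeric(1), sigmoid slope \eqn{A} (negative when decision
#'   values increase with the positive class).
#' @slot platt_b numeric(1), sigmoid offset \eqn{B}.
#' @slot feature_means numeric, training-set centering constants.
#' @slot feature_sds numeric, training-set scaling constants (all > 0;
#'   constant features are dropped before fitting).
#'
#' @seealso [cellClassifier()], [fitLinearSVM()], [calibratePlatt()]
#' @export
setClass("LinearBinaryModel",
  representation(feature_names = "character",
                 weights       = "numeric",
                 intercept     = "numeric",
                 platt_a       = "numeric",
                 platt_b       = "numeric",
                 feature_means = "numeric",
                 feature_sds   = "numeric"))

setValidity("LinearBinaryModel", function(object) {
  n <- length(object@feature_names)
  msgs <- character(0)
  if (length(object@weights) != n || length(object@feature_means) != n ||
      length(object@feature_sds) != n)
    msgs <- c(msgs, "weights, feature_means and feature_sds must match feature_names in length")
  if (anyDuplicated(object@feature_names))
    msgs <- c(msgs, "feature_names must be unique")
  if (any(!is.finite(object@feature_sds)) || any(object@feature_sds <= 0))
    msgs <- c(msgs, "all feature_sds must be positive")
  for (s in c("intercept", "platt_a", "platt_b"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msgs <- c(msgs, paste(s, "must be a single finite number"))
  if (length(msgs)) msgs else TRUE
})

#' Construct a LinearBinaryModel
#'
#' @param feature_names character vector of gene symbols.
#' @param weights numeric weights, one per feature.
#' @param intercept decision-function intercept.
#' @param platt_a,platt_b sigmoid calibration pair.
#' @param feature_means,feature_sds training-set standardization constants.
#' @return A [LinearBinaryModel-class] object.
#' @export
linearBinaryModel <- function(feature_names, weights, intercept,
                              platt_a, platt_b, feature_means, feature_sds) {
  new("LinearBinaryModel",
      feature_names = as.character(feature_names),
      weights = as.numeric(weights),
      intercept = as.numeric(intercept),
      platt_a = as.numeric(platt_a),
      platt_b = as.numeric(platt_b),
      feature_means = as.numeric(feature_means),
      feature_sds = as.numeric(feature_sds))
}

#' Cell-type classifier
#'
#' The unit of the classifier database: a cell-type name, a trained
#' [LinearBinaryModel-class], the feature set the model was trained on,
#' a probability threshold for acceptance, and optionally the name of a
#' parent cell type. When a parent is set, the classifier is only applied
#' to cells accepted by the parent classifier.
#'
#' @slot cell_type character(1), non-empty, must not contain "/" (the
#'   ambiguous-assignment separator).
#' @slot model a [LinearBinaryModel-class].
#' @slot features character, identical to the model's feature names.
#' @slot threshold numeric(1) in (0, 1); probabilities at or above it
#'   accept the cell. Default 0.5. Adjustable without retraining.
#' @slot parent character(1), parent cell-type name, or `NA` for a root.
#' @export
setClass("CellClassifier",
  representation(cell_type = "character",
                 model     = "LinearBinaryModel",
                 features  = "character",
                 threshold = "numeric",
                 parent    = "character"))

setValidity("CellClassifier", function(object) {
  msgs <- character(0)
  if (length(object@cell_type) != 1L || !nzchar(object@cell_type))
    msgs <- c(msgs, "cell_type must be a single non-empty string")
  if (length(object@threshold) != 1L || !is.finite(object@threshold) ||
      object@threshold <= 0 || object@threshold >= 1)
    msgs <- c(msgs, "threshold must lie strictly between 0 and 1")
  if (!identical(object@features, object@model@feature_names))
    msgs <- c(msgs, "features must equal the model's feature_names")
  if (length(object@parent) != 1L)
    msgs <- c(msgs, "parent must be a single string or NA")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CellClassifier
#'
#' @param cell_type cell-type name (no "/").
#' @param model a [LinearBinaryModel-class].
#' @param threshold acceptance probability threshold in (0, 1).
#' @param parent parent cell-type name, or `NA` for a root classifier.
#' @return A [CellClassifier-class] object.
#' @export
cellClassifier <- function(cell_type, model, threshold = 0.5,
                           parent = NA_character_) {
  new("CellClassifier",
      cell_type = as.character(cell_type),
      model = model,
      features = model@feature_names,
      threshold = as.numeric(threshold),
      parent = as.character(parent))
}

#' Classifier database
#'
#' A named collection of [CellClassifier-class] objects whose parent
#' links form a forest. The database is the unit of persistence and
#' sharing (see [saveDatabase()] / [loadDatabase()]). Semantic
#' invariants (resolvable parents, acyclicity) are checked by
#' [validateDatabase()] and enforced on mutation by [addClassifier()].
#'
#' @slot entries named list of [CellClassifier-class]; names equal the
#'   entries' cell types and follow insertion order.
#' @slot format_version character(1), archive format version.
#' @export
setClass("ClassifierDatabase",
  representation(entries = "list", format_version = "character"))

setValidity("ClassifierDatabase", function(object) {
  msgs <- character(0)
  if (!all(vapply(object@entries, is, logical(1), class2 = "CellClassifier")))
    msgs <- c(msgs, "all entries must be CellClassifier objects")
  if (length(object@format_version) != 1L)
    msgs <- c(msgs, "format_version must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Construct an empty classifier database
#'
#' @param format_version archive format version string.
#' @return An empty [ClassifierDatabase-class].
#' @export
classifierDatabase <- function(format_version = CTDB_FORMAT_VERSION) {
  new("ClassifierDatabase", entries = structure(list(), names = character(0)),
      format_version = format_version)
}

#' Sparse expression matrix with cell/gene identifiers
#'
#' Cells-by-genes sparse non-negative matrix. Kept sparse through
#' normalization; only per-classifier feature panels are ever densified.
#'
#' @slot values a `dgCMatrix`, rows = cells, columns = genes, with unique
#'   dimnames.
#' @slot is_normalized logical(1); `TRUE` once library-size scaled and
#'   log1p-transformed (or when the input was declared pre-normalized).
#' @export
setClass("ExpressionMatrix",
  representation(values = "dgCMatrix", is_normalized = "logical"))

setValidity("ExpressionMatrix", function(object) {
  msgs <- character(0)
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "cell and gene identifiers are required as dimnames")
  else {
    if (anyDuplicated(rownames(v))) msgs <- c(msgs, "cell_ids must be unique")
    if (anyDuplicated(colnames(v))) msgs <- c(msgs, "gene_ids must be unique")
  }
  if (length(v@x) && min(v@x) < 0)
    msgs <- c(msgs, "expression values must be non-negative")
  if (length(object@is_normalized) != 1L || is.na(object@is_normalized))
    msgs <- c(msgs, "is_normalized must be TRUE or FALSE")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values a matrix-like object, rows = cells, columns = genes; will
#'   be stored as a `dgCMatrix`.
#' @param cell_ids,gene_ids identifiers; taken from `dimnames(values)`
#'   when omitted.
#' @param is_normalized whether the values are already normalized.
#' @return An [ExpressionMatrix-class].
#' @export
expressionMatrix <- function(values, cell_ids = rownames(values),
                             gene_ids = colnames(values),
                             is_normalized = FALSE) {
  m <- Matrix::Matrix(values, sparse = TRUE, doDiag = FALSE)
  m <- as(as(m * 1.0, "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(as.character(cell_ids), as.character(gene_ids))
  new("ExpressionMatrix", values = m, is_normalized = is_normalized)
}

#' Dense feature submatrix for one classifier
#'
#' @slot values dense cells-by-features matrix in the classifier's
#'   feature order; features absent from the source are zero-filled.
#' @slot missing_features gene symbols absent from the source matrix.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", missing_features = "character"))

#' Per-cell classification results
#'
#' One row per cell. `probs` holds a probability per evaluated cell type;
#' `NA` marks a type that was *not evaluated* for that cell because its
#' parent did not pass (distinct from a low probability). `assignment` is
#' `"unknown"`, a single cell-type name, or a slash-joined lexicographic
#' set of names from different branches; `best_guess` is the candidate
#' with maximal probability.
#'
#' @slot probs numeric matrix, cells x cell types (database order);
#'   `NA` = not evaluated.
#' @slot thresholds named numeric, the acceptance threshold used per type.
#' @slot best_guess character per cell.
#' @slot assignment character per cell.
#' @export
setClass("PredictionTable",
  representation(probs = "matrix", thresholds = "numeric",
                 best_guess = "character", assignment = "character"))

setValidity("PredictionTable", function(object) {
  n <- nrow(object@probs)
  if (length(object@best_guess) != n || length(object@assignment) != n)
    return("best_guess and assignment must have one element per cell")
  if (ncol(object@probs) != length(object@thresholds))
    return("one threshold per evaluated cell type is required")
  TRUE
})

#' Classification performance report
#'
#' @slot accuracy dataset-level fraction of correct cells.
#' @slot per_type data.frame with columns `cell_type`, `sensitivity`,
#'   `specificity` (reference types present in the truth).
#' @slot mean_sensitivity,mean_specificity unweighted means across types.
#' @slot unknown_detection_rate fraction of out-of-reference cells left
#'   unassigned; `NA` when no such cells exist.
#' @slot variant `"strict"` or `"intermediate_accepted"`.
#' @export
setClass("MetricsReport",
  representation(accuracy = "numeric", per_type = "data.frame",
                 mean_sensitivity = "numeric", mean_specificity = "numeric",
                 unknown_detection_rate = "numeric", variant = "character"))
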