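#' Accessors for scTypeTree objects
#'
#' Small read-only accessors; prefer these to direct slot access.
#'
#' @param object a package object (classifier, database, matrix, table).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("cellType", "CellClassifier", function(object) object@cell_type)

#' @rdname accessors
#' @export
setMethod("parentType", "CellClassifier", function(object) object@parent)

#' @rdname accessors
#' @export
setMethod("classifierFeatures", "CellClassifier",
          function(object) object@features)

#' @rdname accessors
#' @export
setMethod("probThreshold", "CellClassifier", function(object) object@threshold)

#' @rdname accessors
#' @export
setMethod("classifierModel", "CellClassifier", function(object) object@model)

#' @rdname accessors
#' @export
setMethod("cellTypes", "ClassifierDatabase",
          function(object) names(object@entries))

#' @rdname accessors
#' @export
setMethod("cellIds", "ExpressionMatrix",
          function(object) rownames(object@values))

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionMatrix",
          function(object) colnames(object@values))

#' @rdname accessors
#' @export
setMethod("isNormalized", "ExpressionMatrix",
          function(object) object@is_normalized)

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("cellIds", "PredictionTable",
          function(object) rownames(object@probs))

#' @rdname accessors
#' @export
setMethod("cellTypes", "PredictionTable",
          function(object) colnames(object@probs))

#' @rdname accessors
#' @export
setMethod("assignments", "PredictionTable", function(object) {
  structure(object@assignment, names = rownames(object@probs))
})

#' @rdname accessors
#' @export
setMethod("bestGuess", "PredictionTable", function(object) {
  structure(object@best_guess, names = rownames(object@probs))
})

#' @rdname accessors
#' @export
setMethod("probabilities", "PredictionTable", function(object) object@probs)

#' Look up one classifier by cell type
#'
#' @param db a [ClassifierDatabase-class].
#' @param cell_type cell-type name.
#' @return The matching [CellClassifier-class].
#' @export
getClassifier <- function(db, cell_type) {
  if (!cell_type %in% names(db@entries))
    ctStop("not_found_error", "no classifier named '%s' in the database",
           cell_type)
  db@entries[[cell_type]]
}

#' Number of classifiers in a database
#' @param x a [ClassifierDatabase-class].
#' @export
setMethod("length", "ClassifierDatabase", function(x) length(x@entries))

#' Matrix dimensions of an ExpressionMatrix
#' @param x an [ExpressionMatrix-class].
#' @export
setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

#' Subset cells of an ExpressionMatrix
#'
#' Rows (cells) only; the result stays sparse.
#' @param x an [ExpressionMatrix-class].
#' @param i cell index (integer, logical, or cell ids).
#' @param j unused.
#' @param drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "ExpressionMatrix", function(x, i, j, ..., drop = FALSE) {
  if (!missing(j))
    ctStop("validity_error", "gene subsetting is not supported; use extractFeatures()")
  new("ExpressionMatrix", values = x@values[i, , drop = FALSE],
      is_normalized = x@is_normalized)
})

#' @describeIn accessors compact display of a classifier
#' @export
setMethod("show", "CellClassifier", function(object) {
  cat(sprintf("CellClassifier '%s'\n", object@cell_type))
  cat(sprintf("  features : %d genes (%s%s)\n", length(object@features),
              paste(utils::head(object@features, 3L), collapse = ", "),
              if (length(object@features) > 3L) ", ..." else ""))
  cat(sprintf("  threshold: %g\n", object@threshold))
  cat(sprintf("  parent   : %s\n",
              if (is.na(object@parent)) "<root>" else object@parent))
})

#' @describeIn accessors compact display of a database
#' @export
setMethod("show", "ClassifierDatabase", function(object) {
  cat(sprintf("ClassifierDatabase (format %s) with %d classifier(s)\n",
              object@format_version, length(object@entries)))
  for (nm in names(object@entries)) {
    p <- object@entries[[nm]]@parent
    cat(sprintf("  %s%s\n", nm, if (is.na(p)) "" else paste0(" <- ", p)))
  }
})

#' @describeIn accessors compact display of an expression matrix
#' @export
setMethod("show", "ExpressionMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("ExpressionMatrix: %d cells x %d genes (%s; %.1f%% nonzero)\n",
              d[1L], d[2L],
              if (object@is_normalized) "normalized" else "raw counts",
              100 * length(object@values@x) / prod(pmax(d, 1L))))
})

#' @describeIn accessors compact display of predictions
#' @export
setMethod("show", "PredictionTable", function(object) {
  cat(sprintf("PredictionTable: %d cells x %d cell types\n",
              nrow(object@probs), ncol(object@probs)))
  tab <- sort(table(object@assignment), decreasing = TRUE)
  cat("  assignments:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

#' @describeIn accessors compact display of a metrics report
#' @export
setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (%s)\n", object@variant))
  cat(sprintf("  accuracy              : %.4f\n", object@accuracy))
  cat(sprintf("  mean sensitivity      : %.4f\n", object@mean_sensitivity))
  cat(sprintf("  mean specificity      : %.4f\n", object@mean_specificity))
  cat(sprintf("  unknown detection rate: %s\n",
              if (is.na(object@unknown_detection_rate)) "undefined"
              else sprintf("%.4f", object@unknown_detection_rate)))
})

#' Convert predictions to a data.frame
#'
#' One row per cell: `cell_id`, `assignment`, `best_guess`, then one
#' probability column `p_<cell type>` per database entry (`NA` where the
#' type was not evaluated for that cell).
#'
#' @param x a [PredictionTable-class].
#' @param ... ignored.
#' @return A `data.frame`.
#' @export
setMethod("as.data.frame", "PredictionTable", function(x, ...) {
  p <- x@probs
  out <- data.frame(cell_id = rownames(p), assignment = x@assignment,
                    best_guess = x@best_guess, stringsAsFactors = FALSE)
  probs <- as.data.frame(p)
  names(probs) <- paste0("p_", colnames(p))
  cbind(out, probs, row.names = NULL)
})
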