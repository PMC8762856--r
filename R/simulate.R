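## Seeded generator of hierarchically structured scRNA-seq counts with
## planted marker signal; the offline stand-in for a labeled reference.

#' Simulation specification
#'
#' Describes a hierarchically structured cell population with planted
#' marker signal. Counts follow a negative binomial with mean
#' \eqn{s_c \cdot \mu_0 \cdot F} and variance \eqn{\mu + \mu^2/\phi},
#' where \eqn{s_c} is a per-cell log-normal library factor,
#' \eqn{\mu_0} the baseline mean, and \eqn{F} the fold change applied
#' to a gene that is a marker of the cell's type or of one of its
#' ancestors (so a subtype carries its lineage's markers too).
#'
#' The default spec is the reference scenario used throughout the
#' package's own validation: three root immune types plus one subtype
#' ("Plasma cells" under "B cells"), 30 markers each, fold change 4,
#' 500 cells per type, 1000 genes, with "NK cells" held out of training
#' to probe unknown-population rejection.
#'
#' @param types data.frame with columns `name`, `parent` (`NA` for
#'   roots), `n_cells`, `fold_change`; or `NULL` for the default.
#' @param n_genes total number of genes.
#' @param n_markers_per_type markers planted per type (used only when
#'   `marker_sets` is `NULL`; markers are assigned disjointly in gene
#'   order).
#' @param marker_sets optional named list: type -> character vector of
#'   marker gene ids (disjoint across sibling types).
#' @param baseline_mean baseline NB mean per gene (default 0.5).
#' @param nb_dispersion NB dispersion \eqn{\phi} (default 2; smaller =
#'   more overdispersed).
#' @param libsize_sigma sdlog of the log-normal per-cell library factor
#'   (default 0.3; 0 disables depth variation).
#' @param unknown_types type names to hold out of training (still
#'   simulated), used to measure unknown-population detection.
#' @param seed integer seed; generation is fully determined by it.
#' @return A `SimulationSpec` list.
#' @export
simulationSpec <- function(types = NULL, n_genes = 1000L,
                           n_markers_per_type = 30L, marker_sets = NULL,
                           baseline_mean = 0.5, nb_dispersion = 2.0,
                           libsize_sigma = 0.3,
                           unknown_types = "NK cells", seed = 42L) {
  if (is.null(types))
    types <- data.frame(
      name = c("B cells", "Plasma cells", "T cells", "NK cells"),
      parent = c(NA, "B cells", NA, NA),
      n_cells = 500L, fold_change = 4,
      stringsAsFactors = FALSE)
  stopifnot(all(c("name", "parent", "n_cells", "fold_change") %in%
                names(types)))
  if (any(types$n_cells < 1L))
    ctStop("spec_error", "every type needs at least one cell")
  if (any(types$fold_change < 1))
    ctStop("spec_error", "fold_change must be >= 1")
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  if (is.null(marker_sets)) {
    need <- nrow(types) * n_markers_per_type
    if (need > n_genes)
      ctStop("spec_error", "%d markers requested but only %d genes",
             need, n_genes)
    marker_sets <- lapply(seq_len(nrow(types)), function(i)
      gene_ids[((i - 1L) * n_markers_per_type + 1L):(i * n_markers_per_type)])
    names(marker_sets) <- types$name
  }
  spec <- structure(
    list(types = types, n_genes = as.integer(n_genes),
         marker_sets = marker_sets, baseline_mean = baseline_mean,
         nb_dispersion = nb_dispersion, libsize_sigma = libsize_sigma,
         unknown_types = unknown_types, seed = as.integer(seed),
         gene_ids = gene_ids),
    class = "SimulationSpec")
  validateSimulationSpec(spec)
  spec
}

validateSimulationSpec <- function(spec) {
  types <- spec$types
  missing_markers <- setdiff(types$name, names(spec$marker_sets))
  if (length(missing_markers))
    ctStop("spec_error", "no marker set for type(s): %s",
           paste(missing_markers, collapse = ", "))
  unknown_genes <- setdiff(unlist(spec$marker_sets), spec$gene_ids)
  if (length(unknown_genes))
    ctStop("spec_error", "marker gene(s) outside the gene universe: %s",
           paste(utils::head(unknown_genes, 5L), collapse = ", "))
  ## sibling marker sets must be disjoint
  key <- ifelse(is.na(types$parent), "<root>", types$parent)
  for (p in unique(key)) {
    sibs <- types$name[key == p]
    if (length(sibs) < 2L) next
    all_m <- unlist(spec$marker_sets[sibs])
    if (anyDuplicated(all_m))
      ctStop("spec_error",
             "marker sets overlap among siblings of '%s' (e.g. '%s')",
             p, all_m[duplicated(all_m)][1L])
  }
  invisible(spec)
}

specAncestors <- function(spec, name) {
  parent_of <- stats::setNames(as.character(spec$types$parent),
                               spec$types$name)
  out <- character(0)
  p <- parent_of[[name]]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- parent_of[[p]]
    if (length(out) > nrow(spec$types)) break
  }
  out
}

#' Simulate a hierarchically structured count dataset
#'
#' Draws negative-binomial counts per the spec (see
#' [simulationSpec()]): a gene that is a marker of the cell's type or
#' of one of its ancestors has its mean multiplied by the marker-owning
#' type's fold change. Fully deterministic given the spec's seed.
#'
#' @param spec a [simulationSpec()].
#' @return `list(matrix, labels)`: an [ExpressionMatrix-class] of raw
#'   counts and a named character vector of true labels.
#' @export
simulateDataset <- function(spec) {
  validateSimulationSpec(spec)
  types <- spec$types
  withr::with_seed(spec$seed, {
    blocks <- vector("list", nrow(types))
    labels <- character(0)
    for (i in seq_len(nrow(types))) {
      tname <- types$name[i]
      n <- types$n_cells[i]
      fold <- stats::setNames(rep(1, spec$n_genes), spec$gene_ids)
      for (owner in c(tname, specAncestors(spec, tname)))
        fold[spec$marker_sets[[owner]]] <-
          types$fold_change[types$name == owner]
      s_c <- if (spec$libsize_sigma > 0)
        stats::rlnorm(n, meanlog = 0, sdlog = spec$libsize_sigma)
      else rep(1, n)
      mu <- outer(s_c, spec$baseline_mean * fold)
      blocks[[i]] <- matrix(
        stats::rnbinom(n * spec$n_genes, size = spec$nb_dispersion, mu = mu),
        nrow = n, ncol = spec$n_genes)
      labels <- c(labels, rep(tname, n))
    }
    counts <- do.call(rbind, blocks)
  })
  cell_ids <- sprintf("cell_%05d", seq_len(nrow(counts)))
  m <- expressionMatrix(counts, cell_ids = cell_ids,
                        gene_ids = spec$gene_ids, is_normalized = FALSE)
  list(matrix = m, labels = stats::setNames(labels, cell_ids))
}

#' Stratified train/test split
#'
#' Splits cells into disjoint, exhaustive train and test sets,
#' stratified by label, with a seeded draw.
#'
#' @param m an [ExpressionMatrix-class].
#' @param labels named per-cell labels aligned with `m`.
#' @param test_fraction fraction of each class assigned to the test set
#'   (strictly between 0 and 1).
#' @param seed integer seed.
#' @return `list(train = list(matrix, labels), test = list(matrix, labels))`.
#' @export
splitTrainTest <- function(m, labels, test_fraction = 0.5, seed = 1L) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (test_fraction <= 0 || test_fraction >= 1)
    ctStop("validity_error", "test_fraction must lie strictly in (0, 1)")
  labels <- as.character(labels)
  if (length(labels) != nrow(m@values))
    ctStop("alignment_error", "%d labels for %d cells", length(labels),
           nrow(m@values))
  counts <- table(labels)
  if (any(counts < 2L))
    ctStop("stratification_error",
           "class(es) with fewer than 2 cells: %s",
           paste(names(counts)[counts < 2L], collapse = ", "))
  test_idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(split(seq_along(labels), labels), function(idx) {
      k <- max(1L, min(length(idx) - 1L, round(length(idx) * test_fraction)))
      sample(idx, k)
    }), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(labels), test_idx)
  cells <- rownames(m@values)
  list(train = list(matrix = m[train_idx],
                    labels = stats::setNames(labels[train_idx],
                                             cells[train_idx])),
       test = list(matrix = m[test_idx],
                   labels = stats::setNames(labels[test_idx],
                                            cells[test_idx])))
}

#' Write a simulated dataset as an MTX directory
#'
#' Writes `matrix.mtx` (genes x cells, 10x orientation), `features.tsv`,
#' `barcodes.tsv`, `labels.csv` (`cell_id,label`) and the spec as a JSON
#' sidecar `simulation_spec.json`.
#'
#' @param sim result of [simulateDataset()].
#' @param spec the [simulationSpec()] that produced it.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(sim, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- sim$matrix
  Matrix::writeMM(Matrix::t(exprValues(m)), file.path(dir, "matrix.mtx"))
  write(geneIds(m), file.path(dir, "features.tsv"), ncolumns = 1L)
  write(cellIds(m), file.path(dir, "barcodes.tsv"), ncolumns = 1L)
  utils::write.csv(data.frame(cell_id = names(sim$labels),
                              label = unname(sim$labels)),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  side <- spec[c("types", "n_genes", "marker_sets", "baseline_mean",
                 "nb_dispersion", "libsize_sigma", "unknown_types", "seed")]
  jsonlite::write_json(side, file.path(dir, "simulation_spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

#' Read back a labels CSV
#'
#' @param path CSV with columns `cell_id`, `label`.
#' @return Named character vector of labels.
#' @export
readLabels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "label") %in% names(df)))
    ctStop("format_error", "labels file '%s' needs columns cell_id,label",
           path)
  stats::setNames(as.character(df$label), df$cell_id)
}
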