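# Fixture builders shared across test files. All fixtures are generated
# in code; nothing is read from disk.

# A "probe" classifier whose probability for a cell is
# plogis(value of `gene` - 5) on an already-normalized matrix: single
# feature, unit weight, centering constant 5 (so matrix values stay
# non-negative), sigmoid A = -1, B = 0. Lets tests dial in exact
# probabilities per cell via the expression value qlogis(p) + 5.
probeClassifier <- function(cell_type, gene, threshold = 0.5,
                            parent = NA_character_) {
  model <- linearBinaryModel(
    feature_names = gene, weights = 1, intercept = 0,
    platt_a = -1, platt_b = 0, feature_means = 5, feature_sds = 1)
  cellClassifier(cell_type, model, threshold = threshold, parent = parent)
}

# Normalized matrix with exact values; `probs` is cells x genes giving
# the desired probe probability per (cell, classifier gene). Requires
# probabilities in [plogis(-5), 1).
probeMatrix <- function(probs, cell_ids = NULL, gene_ids = colnames(probs)) {
  stopifnot(all(probs >= stats::plogis(-5)))
  vals <- stats::qlogis(probs) + 5
  if (is.null(cell_ids)) cell_ids <- sprintf("c%02d", seq_len(nrow(probs)))
  expressionMatrix(vals, cell_ids = cell_ids, gene_ids = gene_ids,
                   is_normalized = TRUE)
}

# Arbitrary toy linear model over `k` features.
toyModel <- function(k = 2L, seed = 1L) {
  withr::with_seed(seed, {
    linearBinaryModel(
      feature_names = sprintf("g%02d", seq_len(k)),
      weights = stats::rnorm(k), intercept = stats::rnorm(1),
      platt_a = -stats::runif(1, 0.5, 3), platt_b = stats::rnorm(1, 0, 0.2),
      feature_means = stats::rnorm(k), feature_sds = stats::runif(k, 0.5, 2))
  })
}

toyClassifier <- function(cell_type, parent = NA_character_,
                          threshold = 0.5, k = 2L, seed = 1L) {
  cellClassifier(cell_type, toyModel(k, seed), threshold = threshold,
                 parent = parent)
}

# Random forest-shaped database over a shared gene universe. Each
# classifier uses a random subset of genes with identity-free scaling,
# so random normalized matrices produce dispersed probabilities.
randomDatabase <- function(n_types = 5L, n_genes = 30L, seed = 1L) {
  withr::with_seed(seed, {
    genes <- sprintf("g%02d", seq_len(n_genes))
    db <- classifierDatabase()
    nms <- paste0("type", seq_len(n_types))
    for (i in seq_len(n_types)) {
      parent <- if (i > 1L && stats::runif(1) < 0.5)
        nms[sample.int(i - 1L, 1L)] else NA_character_
      k <- sample(2:4, 1L)
      feats <- sample(genes, k)
      model <- linearBinaryModel(
        feature_names = feats, weights = stats::rnorm(k), intercept = stats::rnorm(1),
        platt_a = -stats::runif(1, 0.5, 2), platt_b = stats::rnorm(1, 0, 0.5),
        feature_means = stats::runif(k, 0, 2), feature_sds = stats::runif(k, 0.5, 2))
      db <- addClassifier(db, cellClassifier(
        nms[i], model, threshold = stats::runif(1, 0.2, 0.8), parent = parent))
    }
    db
  })
}

# Random normalized expression matrix over the same gene universe.
randomNormalizedMatrix <- function(n_cells = 40L, n_genes = 30L, seed = 1L) {
  withr::with_seed(seed, {
    vals <- matrix(stats::runif(n_cells * n_genes, 0, 4),
                   nrow = n_cells)
    vals[stats::runif(length(vals)) < 0.5] <- 0
    expressionMatrix(vals,
                     cell_ids = sprintf("cell%03d", seq_len(n_cells)),
                     gene_ids = sprintf("g%02d", seq_len(n_genes)),
                     is_normalized = TRUE)
  })
}

# The reference end-to-end run (default simulation conditions), computed
# once per test session and reused by several tests.
.pipeline_cache <- new.env(parent = emptyenv())
defaultPipelineRun <- function() {
  if (!is.null(.pipeline_cache$run)) return(.pipeline_cache$run)
  spec <- simulationSpec()
  sim <- simulateDataset(spec)
  sp <- splitTrainTest(sim$matrix, sim$labels, test_fraction = 0.5,
                       seed = spec$seed + 1L)
  keep <- !(sp$train$labels %in% spec$unknown_types)
  hier <- data.frame(
    cell_type = setdiff(spec$types$name, spec$unknown_types),
    stringsAsFactors = FALSE)
  hier$parent <- spec$types$parent[match(hier$cell_type, spec$types$name)]
  db <- suppressWarnings(trainDatabase(
    sp$train$matrix[keep], sp$train$labels[keep], hier,
    spec$marker_sets[hier$cell_type],
    cfg = trainingConfig(seed = spec$seed)))
  pt <- classifyCells(db, sp$test$matrix)
  .pipeline_cache$run <- list(spec = spec, split = sp, db = db, pt = pt)
  .pipeline_cache$run
}

# Small simulation spec for quick pipeline tests.
smallSpec <- function(seed = 11L, fold_change = 4) {
  simulationSpec(
    types = data.frame(
      name = c("B cells", "Plasma cells", "T cells", "NK cells"),
      parent = c(NA, "B cells", NA, NA),
      n_cells = 120L, fold_change = fold_change,
      stringsAsFactors = FALSE),
    n_genes = 400L, n_markers_per_type = 20L, seed = seed)
}
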