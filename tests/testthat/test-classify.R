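# Hierarchical classification: probabilities, gating, assignment.

test_that("predictProbability evaluates the calibrated linear model", {
  # null model: w = 0, b = 0, B = 0 -> p = 0.5 everywhere
  null_model <- linearBinaryModel("g1", weights = 0, intercept = 0,
                                  platt_a = -2, platt_b = 0,
                                  feature_means = 0, feature_sds = 1)
  m <- expressionMatrix(matrix(c(0, 1, 7), ncol = 1L,
                               dimnames = list(c("c1", "c2", "c3"), "g1")),
                        is_normalized = TRUE)
  p <- predictProbability(cellClassifier("X", null_model), m)
  expect_equal(unname(p), rep(0.5, 3L))

  # worked example: w = (1, -1), b = 0.5, z = (2, 1), A = -2, B = 0
  model <- linearBinaryModel(c("g1", "g2"), weights = c(1, -1),
                             intercept = 0.5, platt_a = -2, platt_b = 0,
                             feature_means = c(0, 0), feature_sds = c(1, 1))
  m2 <- expressionMatrix(matrix(c(2, 1), nrow = 1L,
                                dimnames = list("c1", c("g1", "g2"))),
                         is_normalized = TRUE)
  p2 <- predictProbability(cellClassifier("X", model), m2)
  expect_equal(unname(p2), 1 / (1 + exp(-3)), tolerance = 1e-10)

  # monotone in the decision value when A < 0
  m3 <- expressionMatrix(matrix(seq(0, 5, length.out = 20L), ncol = 1L,
                                dimnames = list(sprintf("c%02d", 1:20), "g1")),
                         is_normalized = TRUE)
  clf <- probeClassifier("X", "g1")
  expect_true(all(diff(predictProbability(clf, m3)) > 0))
})

test_that("assignment combines roots, refines along branches, rejects", {
  db <- classifierDatabase()
  db <- addClassifier(db, probeClassifier("A", "gA"))
  db <- addClassifier(db, probeClassifier("B", "gB"))
  m <- probeMatrix(rbind(c(0.9, 0.2), c(0.9, 0.8), c(0.1, 0.2)),
                   gene_ids = c("gA", "gB"))
  pt <- classifyCells(db, m)
  expect_identical(unname(assignments(pt)), c("A", "A/B", "unknown"))
  expect_identical(unname(bestGuess(pt)), c("A", "A", "unknown"))

  # empty database rejects everything
  pt0 <- classifyCells(classifierDatabase(), m)
  expect_true(all(assignments(pt0) == "unknown"))

  # child gated by parent; a passing child replaces its ancestor
  db2 <- classifierDatabase()
  db2 <- addClassifier(db2, probeClassifier("B cells", "gB"))
  db2 <- addClassifier(db2, probeClassifier("Plasma cells", "gP",
                                            parent = "B cells"))
  m2 <- probeMatrix(rbind(c(0.4, 0.9), c(0.9, 0.8), c(0.9, 0.2)),
                    gene_ids = c("gB", "gP"))
  pt2 <- classifyCells(db2, m2)
  p <- probabilities(pt2)
  expect_true(is.na(p["c01", "Plasma cells"]))   # parent failed -> not evaluated
  expect_identical(unname(assignments(pt2)),
                   c("unknown", "Plasma cells", "B cells"))
})

test_that("probability exactly at threshold passes", {
  db <- addClassifier(classifierDatabase(),
                      probeClassifier("A", "gA", threshold = 0.75))
  m <- probeMatrix(matrix(0.75, 1, 1), gene_ids = "gA")
  pt <- classifyCells(db, m)
  expect_identical(unname(assignments(pt)), "A")
})

test_that("classification is equivariant under cell permutation", {
  db <- randomDatabase(n_types = 4L, seed = 31L)
  m <- randomNormalizedMatrix(n_cells = 25L, seed = 31L)
  pt <- classifyCells(db, m)
  perm <- withr::with_seed(31L, sample(nrow(probabilities(pt))))
  ptp <- classifyCells(db, m[perm])
  # probabilities agree up to BLAS accumulation order
  expect_equal(probabilities(ptp), probabilities(pt)[perm, , drop = FALSE],
               tolerance = 1e-12)
  expect_identical(unname(assignments(ptp)), unname(assignments(pt)[perm]))
})

test_that("prediction table invariants hold on random databases", {
  for (seed in 1:8) {
    db <- randomDatabase(n_types = sample(3:6, 1L), seed = seed)
    m <- randomNormalizedMatrix(n_cells = 30L, seed = seed + 100L)
    pt <- classifyCells(db, m)
    p <- probabilities(pt)
    thr <- pt@thresholds
    for (ct in cellTypes(db)) {
      par <- parentType(getClassifier(db, ct))
      if (is.na(par)) {
        expect_false(anyNA(p[, ct]))
      } else {
        gated <- is.na(p[, ct])
        parent_pass <- !is.na(p[, par]) & p[, par] >= thr[par]
        # child evaluated <=> parent passed
        expect_identical(unname(!gated), unname(parent_pass))
      }
    }
    pass_any <- apply(p, 1L, function(row)
      any(!is.na(row) & row >= thr))
    expect_identical(unname(assignments(pt) == "unknown"), unname(!pass_any))
    # every asserted name passes its threshold
    for (i in seq_len(nrow(p))) {
      a <- assignments(pt)[[i]]
      if (a == "unknown") next
      for (nm in strsplit(a, "/", fixed = TRUE)[[1L]])
        expect_gte(p[i, nm], thr[nm])
    }
  }
})

test_that("setThreshold changes only the threshold and respects bounds", {
  db <- randomDatabase(n_types = 3L, seed = 8L)
  ct <- cellTypes(db)[2L]
  db2 <- setThreshold(db, ct, 0.3)
  expect_identical(probThreshold(getClassifier(db2, ct)), 0.3)
  expect_identical(getClassifier(db2, ct)@model, getClassifier(db, ct)@model)
  other <- setdiff(cellTypes(db), ct)
  for (o in other)
    expect_identical(probThreshold(getClassifier(db2, o)),
                     probThreshold(getClassifier(db, o)))
  expect_error(setThreshold(db, ct, 1.2), class = "validity_error")
  expect_error(setThreshold(db, "ghost", 0.4), class = "not_found_error")
})

test_that("lowering thresholds grows accepted sets; raising shrinks them", {
  candSize <- function(pt) {
    a <- assignments(pt)
    ifelse(a == "unknown", 0L,
           lengths(strsplit(a, "/", fixed = TRUE)))
  }
  for (seed in 1:10) {
    db <- randomDatabase(n_types = sample(3:6, 1L), seed = seed + 50L)
    m <- randomNormalizedMatrix(n_cells = 30L, seed = seed + 200L)
    base <- classifyCells(db, m)
    ct <- withr::with_seed(seed, sample(cellTypes(db), 1L))
    thr <- probThreshold(getClassifier(db, ct))

    lower <- classifyCells(setThreshold(db, ct, thr * 0.5), m)
    expect_true(all(candSize(lower) >= candSize(base)))
    # assigned cells never become unknown on lowering
    expect_true(all(!(assignments(base) != "unknown" &
                      assignments(lower) == "unknown")))

    higher <- classifyCells(setThreshold(db, ct, thr + (1 - thr) * 0.5), m)
    expect_true(all(candSize(higher) <= candSize(base)))
    expect_true(all(!(assignments(base) == "unknown" &
                      assignments(higher) != "unknown")))
  }
})

test_that("classifying with an invalid database fails up front", {
  db <- randomDatabase(n_types = 3L, seed = 2L)
  db@entries[[2L]]@parent <- "ghost"
  m <- randomNormalizedMatrix(n_cells = 5L, seed = 2L)
  expect_error(classifyCells(db, m), class = "validation_error")
})

test_that("predictions CSV carries assignments and per-type probabilities", {
  db <- classifierDatabase()
  db <- addClassifier(db, probeClassifier("B cells", "gB"))
  db <- addClassifier(db, probeClassifier("Plasma cells", "gP",
                                          parent = "B cells"))
  m <- probeMatrix(rbind(c(0.9, 0.8), c(0.2, 0.9)),
                   gene_ids = c("gB", "gP"))
  pt <- classifyCells(db, m)
  path <- withr::local_tempfile(fileext = ".csv")
  writePredictions(pt, path)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_identical(names(back),
                   c("cell_id", "assignment", "best_guess",
                     "p_B.cells", "p_Plasma.cells"))
  expect_identical(back$assignment, c("Plasma cells", "unknown"))
  expect_true(is.na(back$p_Plasma.cells[2L]))
})
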