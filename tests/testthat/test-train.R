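# Training: labels, balancing, SVM fit, calibration, full pipeline.

test_that("one-vs-rest labels honor aliases and reject degenerate cases", {
  expect_identical(makeBinaryLabels(c("B", "T", "B", "NK"), "B"),
                   c(1L, -1L, 1L, -1L))
  expect_identical(
    makeBinaryLabels(c("B cell", "B cells", "T"), "B cells",
                     aliases = "B cell"),
    c(1L, 1L, -1L))
  expect_error(makeBinaryLabels(c("B", "B"), "B"),
               class = "degenerate_labels_error")
  expect_error(makeBinaryLabels(c("T", "T"), "B"),
               class = "degenerate_labels_error")
})

test_that("downsampling equalizes classes deterministically", {
  y <- rep(c(1L, -1L), each = 10L)
  expect_identical(balanceDownsample(y, seed = 3L), seq_along(y))

  y <- c(rep(1L, 5L), rep(-1L, 100L))
  idx <- balanceDownsample(y, seed = 3L)
  expect_length(idx, 10L)
  expect_true(all(1:5 %in% idx))
  expect_identical(idx, balanceDownsample(y, seed = 3L))
  expect_false(identical(idx, balanceDownsample(y, seed = 4L)))
})

test_that("linear SVM matches sign symmetry and simple geometry", {
  X <- matrix(c(-1, 1), ncol = 1L, dimnames = list(NULL, "g1"))
  y <- c(-1L, 1L)
  fit <- fitLinearSVM(X, y, cost_c = 1)
  expect_gt(fit$weights[["g1"]], 0)
  f <- drop(X %*% fit$weights) + fit$intercept
  expect_true(all(sign(f) == y))

  # label flip negates the solution
  X2 <- matrix(c(-2, -1, 1, 2, 0.5, -0.5, 1.5, -1.5), ncol = 2L,
               dimnames = list(NULL, c("g1", "g2")))
  y2 <- c(-1L, -1L, 1L, 1L)
  a <- fitLinearSVM(X2, y2, cost_c = 1)
  b <- fitLinearSVM(X2, -y2, cost_c = 1)
  expect_equal(a$weights, -b$weights, tolerance = 1e-6)
  expect_equal(a$intercept, -b$intercept, tolerance = 1e-6)

  expect_error(fitLinearSVM(X, c(1L, 1L), 1), class = "degenerate_labels_error")
  Xc <- cbind(X, g2 = c(1, 1))
  expect_error(fitLinearSVM(Xc, y, 1), class = "degenerate_features_error")
})

test_that("SVM solution matches an interior-point QP oracle on small 2-D sets", {
  skip_if_not_installed("kernlab")
  sets <- list(
    list(X = matrix(c(-1, -1, 1, 1, -1, 1, -1, 1), ncol = 2L),
         y = c(-1L, -1L, 1L, 1L)),
    list(X = matrix(c(-2, -1.5, -1, 1, 1.5, 2,
                      0.3, -0.4, 0.8, -0.2, 0.5, -0.6), ncol = 2L),
         y = c(-1L, -1L, -1L, 1L, 1L, 1L)),
    list(X = withr::with_seed(9L, {
           cbind(c(rnorm(5, -2), rnorm(5, 2)), rnorm(10))
         }),
         y = rep(c(-1L, 1L), each = 5L)))
  for (C in c(1, 10)) {
    for (s in sets) {
      X <- s$X
      colnames(X) <- c("g1", "g2")
      fit <- fitLinearSVM(X, s$y, cost_c = C)
      oracle <- svmOracleQP(X, s$y, C)
      expect_equal(unname(fit$weights) / sqrt(sum(fit$weights^2)),
                   oracle$weights / sqrt(sum(oracle$weights^2)),
                   tolerance = 1e-4)
    }
  }
})

test_that("Platt calibration matches a grid-plus-refinement oracle", {
  f <- c(-2.0, -1.0, -0.5, 0.5, 1.2, 2.5)
  y <- c(-1L, -1L, 1L, -1L, 1L, 1L)
  fit <- calibratePlatt(f, y)
  oracle <- plattOracle(f, y)
  expect_equal(fit$platt_a, oracle$platt_a, tolerance = 1e-4)
  expect_equal(fit$platt_b, oracle$platt_b, tolerance = 1e-4)
  expect_lt(fit$platt_a, 0)
})

test_that("Platt calibration is symmetric and monotone", {
  fit <- calibratePlatt(c(-1, -1, 1, 1), c(-1L, -1L, 1L, 1L))
  expect_lt(abs(fit$platt_b), 1e-6)
  expect_lt(fit$platt_a, 0)

  # p(f) strictly increases with f when A < 0
  f_grid <- seq(-4, 4, length.out = 50L)
  p <- plogis(-(fit$platt_a * f_grid + fit$platt_b))
  expect_true(all(diff(p) > 0))

  expect_error(calibratePlatt(c(1, 2), c(1L, 1L)),
               class = "degenerate_labels_error")
})

test_that("training on strong markers yields an accurate, calibrated classifier", {
  spec <- smallSpec(seed = 21L)
  sim <- simulateDataset(spec)
  cfg <- trainingConfig(seed = 5L)
  clf <- trainClassifier(sim$matrix, sim$labels, "T cells",
                         spec$marker_sets[["T cells"]], cfg = cfg)
  expect_s4_class(clf, "CellClassifier")
  expect_identical(cellType(clf), "T cells")
  expect_identical(probThreshold(clf), 0.5)

  p <- predictProbability(clf, sim$matrix)
  pred_pos <- p >= 0.5
  truth_pos <- sim$labels == "T cells"
  expect_gte(mean(pred_pos == truth_pos), 0.95)

  # calibration sanity: mean probability on the balanced training cells
  # is near the balanced positive fraction (1/2)
  y <- makeBinaryLabels(sim$labels, "T cells")
  idx <- balanceDownsample(y, cfg$seed)
  expect_lt(abs(mean(p[idx]) - 0.5), 0.1)
})

test_that("training is deterministic given the seed", {
  spec <- smallSpec(seed = 22L)
  sim <- simulateDataset(spec)
  cfg <- trainingConfig(seed = 9L)
  a <- trainClassifier(sim$matrix, sim$labels, "B cells",
                       spec$marker_sets[["B cells"]], cfg = cfg,
                       aliases = "Plasma cells")
  b <- trainClassifier(sim$matrix, sim$labels, "B cells",
                       spec$marker_sets[["B cells"]], cfg = cfg,
                       aliases = "Plasma cells")
  expect_identical(a@model@weights, b@model@weights)
  expect_identical(a@model@intercept, b@model@intercept)
  expect_identical(a@model@platt_a, b@model@platt_a)
  expect_identical(a@model@platt_b, b@model@platt_b)
})

test_that("child training sees only the parent lineage", {
  spec <- smallSpec(seed = 23L)
  sim <- simulateDataset(spec)
  cfg <- trainingConfig(seed = 2L)
  parent_db <- addClassifier(
    classifierDatabase(),
    trainClassifier(sim$matrix, sim$labels, "B cells",
                    spec$marker_sets[["B cells"]], cfg = cfg,
                    aliases = "Plasma cells"))

  child_full <- trainClassifier(sim$matrix, sim$labels, "Plasma cells",
                                spec$marker_sets[["Plasma cells"]],
                                cfg = cfg, parent_db = parent_db,
                                parent = "B cells")

  # dropping all out-of-lineage cells changes nothing
  lineage <- sim$labels %in% c("B cells", "Plasma cells")
  child_restricted <- trainClassifier(
    sim$matrix[lineage], sim$labels[lineage], "Plasma cells",
    spec$marker_sets[["Plasma cells"]], cfg = cfg,
    parent_db = parent_db, parent = "B cells")
  expect_identical(child_full@model@weights, child_restricted@model@weights)
  expect_identical(child_full@model@platt_a, child_restricted@model@platt_a)

  expect_error(
    trainClassifier(sim$matrix, sim$labels, "Plasma cells",
                    spec$marker_sets[["Plasma cells"]], cfg = cfg,
                    parent_db = parent_db, parent = "Myeloid"),
    class = "unresolved_parent_error")
})

test_that("training rejects too-small classes and all-constant panels", {
  spec <- smallSpec(seed = 24L)
  sim <- simulateDataset(spec)
  few <- c(which(sim$labels == "T cells")[1:3],
           which(sim$labels == "B cells"))
  expect_error(
    trainClassifier(sim$matrix[few], sim$labels[few], "T cells",
                    spec$marker_sets[["T cells"]]),
    class = "sample_size_error")

  flat <- expressionMatrix(
    matrix(1, nrow = 30L, ncol = 2L,
           dimnames = list(sprintf("c%02d", 1:30), c("g1", "g2"))))
  labs <- rep(c("A", "B"), 15L)
  expect_error(
    suppressWarnings(trainClassifier(flat, labs, "A", c("g1", "g2"))),
    class = "degenerate_features_error")
})
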