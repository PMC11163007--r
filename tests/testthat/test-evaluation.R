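test_that("computeMetrics reproduces the precision/recall/F definitions", {
  # perfect prediction
  m <- computeMetrics(c("a", "b", "a"), c("a", "b", "a"), c("a", "b"))
  expect_equal(unname(m$macro), c(1, 1, 1))
  # P = 0.5, R = 1 -> F = 2/3
  m2 <- computeMetrics(c("a", "b"), c("a", "a"), c("a", "b"))
  a <- m2$perClass[m2$perClass$class == "a", ]
  expect_equal(a$precision, 0.5)
  expect_equal(a$recall, 1)
  expect_equal(a$f_score, 2 / 3)
  # TP=3 FP=1 FN=2 for class x
  truth <- c(rep("x", 5), rep("y", 3))
  pred  <- c("x", "x", "x", "y", "y", "x", "y", "y")
  m3 <- computeMetrics(truth, pred, c("x", "y"))
  xr <- m3$perClass[m3$perClass$class == "x", ]
  expect_equal(c(xr$tp, xr$fp, xr$fn), c(3, 1, 2))
  expect_equal(xr$precision, 0.75)
  expect_equal(xr$recall, 0.6)
  expect_equal(xr$f_score, 2 * 0.75 * 0.6 / 1.35)
  expect_error(computeMetrics(c("a"), c("a", "b"), c("a", "b")), "length")
  expect_error(computeMetrics("c", "a", c("a", "b")), "inventory")
})

test_that("computeMetrics agrees with the counting oracle and caret on 1000
           random label vectors", {
  skip_if_not_installed("caret")
  set.seed(17)
  classes <- c("gel", "solution")
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    m <- computeMetrics(truth, pred, classes)
    o <- oracleMetrics(truth, pred, classes)
    expect_equal(m$macro[["precision"]], o$precision, tolerance = 1e-12)
    expect_equal(m$macro[["recall"]], o$recall, tolerance = 1e-12)
    expect_equal(m$macro[["f_score"]], o$f_score, tolerance = 1e-12)
    # harmonic-mean bounds per class
    pc <- m$perClass
    both <- pc$precision + pc$recall > 0
    expect_true(all(pc$f_score[both] <= pmax(pc$precision, pc$recall)[both] + 1e-12))
    expect_true(all(pc$f_score[both] >= pmin(pc$precision, pc$recall)[both] - 1e-12))
    expect_true(all(pc$f_score >= 0 & pc$f_score <= 1))
  }
  # spot-check per-class values against caret (zero-division mapped to 0)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    truth <- factor(sample(classes, n, replace = TRUE), levels = classes)
    pred <- factor(sample(classes, n, replace = TRUE), levels = classes)
    m <- computeMetrics(as.character(truth), as.character(pred), classes)
    for (cl in classes) {
      cp <- caret::precision(pred, truth, relevant = cl)
      cr <- caret::recall(pred, truth, relevant = cl)
      row <- m$perClass[m$perClass$class == cl, ]
      expect_equal(row$precision, ifelse(is.na(cp), 0, cp), tolerance = 1e-12)
      expect_equal(row$recall, ifelse(is.na(cr), 0, cr), tolerance = 1e-12)
    }
  }
})

test_that("the paired one-sided t statistic matches Student's t", {
  b <- c(0.5, 0.7, 0.6)
  a <- b + c(1, 2, 3)
  r <- pairedOneSidedT(a, b)
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  # survival-function oracle
  expect_equal(r$p, stats::t.test(a, b, paired = TRUE,
                                  alternative = "greater")$p.value,
               tolerance = 1e-9)
  # antisymmetry
  r2 <- pairedOneSidedT(b, a)
  expect_equal(r2$t, -r$t, tolerance = 1e-12)
  expect_equal(r2$p, 1 - r$p, tolerance = 1e-9)
  expect_error(pairedOneSidedT(b + 2, b), "degenerate")
  expect_error(pairedOneSidedT(1, 2), "2 pairs")
})

test_that("runExperiment bookkeeping and determinism", {
  ds <- simulateDataset(SimConfig(length = 32L,
                                  nPerClass = c(solution = 40L, gel = 20L)))
  spec <- ImbalanceSpec("solution", "gel", 20L, 5L)
  protocol <- list(clf = scaledThreePlayerConfig(
    epochs = 5L, clfKernels = c(4L, 4L, 8L, 8L), featureDim = 8L))
  rep1 <- runExperiment(ds, list(spec), "none", nRepetitions = 2L,
                        baseSeed = 3L, protocol = protocol)
  expect_s4_class(rep1, "MetricsReport")
  mac <- rep1@records[rep1@records$class == "MACRO", ]
  expect_equal(nrow(mac), 2L)
  expect_equal(nrow(rep1@summary), 3L)
  expect_true(all(rep1@summary$n_reps == 2L))
  rep2 <- runExperiment(ds, list(spec), "none", nRepetitions = 2L,
                        baseSeed = 3L, protocol = protocol)
  expect_identical(rep1@records, rep2@records)
})

test_that("minority recall degrades as the training ratio shrinks (the
           imbalance effect)", {
  recalls <- vapply(list(c(20L, 20L), c(20L, 2L)), function(nn) {
    mean(vapply(1:5, function(sd) {
      ds <- simulateDataset(SimConfig(length = 32L, seed = sd,
                                      nPerClass = c(solution = 50L,
                                                    gel = 30L)))
      sp <- makeImbalancedSplit(ds, ImbalanceSpec("solution", "gel",
                                                  nn[1], nn[2]), sd)
      fit <- trainClassifier(sp$train, scaledThreePlayerConfig(
        epochs = 8L, seed = sd, clfKernels = c(4L, 4L, 8L, 8L),
        featureDim = 8L))
      pred <- classifySpectra(fit, sp$test)$labels
      m <- computeMetrics(spectraLabels(sp$test), pred, classLevels(ds))
      m$perClass$recall[m$perClass$class == "gel"]
    }, 0))
  }, 0)
  expect_gte(recalls[1], recalls[2])
})

test_that("exportReport writes byte-stable, internally consistent reports", {
  ds <- simulateDataset(SimConfig(length = 32L,
                                  nPerClass = c(solution = 30L, gel = 15L)))
  spec <- ImbalanceSpec("solution", "gel", 15L, 5L)
  protocol <- list(clf = scaledThreePlayerConfig(
    epochs = 3L, clfKernels = c(4L, 4L, 8L, 8L), featureDim = 8L))
  rep1 <- runExperiment(ds, list(spec), "none", 2L, 5L, protocol)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  exportReport(rep1, d1, features = list(
    toy = list(features = matrix(1:6 / 7, 3), labels = c("a", "b", "a"))))
  exportReport(rep1, d2)
  expect_identical(readLines(file.path(d1, "summary.csv")),
                   readLines(file.path(d2, "summary.csv")))
  expect_true(file.exists(file.path(d1, "features_toy.csv")))
  # summary means re-derivable from the per-repetition records
  rec <- jsonlite::fromJSON(file.path(d1, "records.json"))
  mac <- rec[rec$class == "MACRO", ]
  sm <- read.csv(file.path(d1, "summary.csv"))
  for (mt in c("precision", "recall", "f_score")) {
    expect_equal(sm$mean[sm$metric == mt], mean(mac[[mt]]), tolerance = 1e-12)
  }
  expect_error(exportReport(new("MetricsReport",
                                records = data.frame(),
                                summary = data.frame(),
                                nRepetitions = 0L), d1), "empty")
})
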