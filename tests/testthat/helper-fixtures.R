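# shared fixtures; expensive trained bundles are cached per test session

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

randomSpectraSet <- function(n = 10, L = 8, seed = 1,
                             classes = c("gel", "solution")) {
  set.seed(seed)
  SpectraSet(matrix(rnorm(n * L), L, n),
             sample(classes, n, replace = TRUE), classes = classes)
}

# the desk-scale trend experiment of the study design: length-128 spectra,
# 150 majority / 4 minority training split, balanced held-out test
trendSplit <- function(simSeed, similarity = 0) {
  sim <- SimConfig(length = 128L,
                   nPerClass = c(solution = 250L, gel = 104L),
                   similarity = similarity, seed = simSeed)
  ds <- simulateDataset(sim)
  sp <- makeImbalancedSplit(ds, ImbalanceSpec("solution", "gel", 150L, 4L),
                            seed = simSeed)
  sp$classes <- classLevels(ds)
  sp
}

testMacroF <- function(players, sp) {
  pred <- classifySpectra(players, sp$test)$labels
  computeMetrics(spectraLabels(sp$test), pred, sp$classes)$macro[["f_score"]]
}

# 5-seed desk-scale comparison on one similarity regime; cached because the
# acceptance suite and the module tests share it
trendRuns <- function(similarity) {
  cached(paste0("trend", similarity), {
    res <- lapply(1:5, function(sd) {
      sp <- trendSplit(sd, similarity)
      gan <- trainThreePlayer(sp$train, scaledThreePlayerConfig(seed = sd))
      none <- trainClassifier(sp$train, scaledThreePlayerConfig(seed = sd))
      smote <- trainClassifier(
        augmentToBalance(sp$train, "smote", seed = sd, kNeighbors = 3L),
        scaledThreePlayerConfig(seed = sd))
      list(gan = testMacroF(gan$players, sp), none = testMacroF(none, sp),
           smote = testMacroF(smote, sp), log = gan$log)
    })
    res
  })
}

# small trained bundle on an easy, noiseless two-peak problem
easyTrainedPlayers <- function() {
  cached("easyPlayers", {
    sim <- SimConfig(length = 64L, noiseSd = 0, jitterSd = 0.005,
                     nPerClass = c(solution = 40L, gel = 40L), seed = 11L)
    ds <- simulateDataset(sim)
    fit <- trainThreePlayer(ds, scaledThreePlayerConfig(
      epochs = 15L, pretrainEpochs = 60L, seed = 11L))
    list(players = fit$players, log = fit$log, sim = sim, data = ds)
  })
}
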