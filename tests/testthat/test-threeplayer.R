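ns <- asNamespace("spectraGAN")

tinyCfg <- function(...) scaledThreePlayerConfig(
  latentDim = 8L, embedDim = 4L, discKernels = c(3L, 4L, 4L, 5L),
  genKernels = c(6L, 6L, 4L, 1L), clfKernels = c(3L, 3L, 4L, 5L),
  featureDim = 6L, batchSize = 8L, ...)

test_that("buildPlayers honours the architecture contracts", {
  cfg <- tinyCfg(seed = 2L, reshape = c(4L, 8L))
  players <- buildPlayers(cfg, c("solution", "gel"), 32L)
  X <- matrix(runif(5 * 32, -1, 1), 5)
  # classifier output is a probability simplex
  probs <- ns$softmaxProbs(ns$clfForward(players@classifier, X)$logits)
  expect_equal(dim(probs), c(5L, 2L))
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-6)
  expect_true(all(probs >= 0))
  # generator output has spectrum shape and lives in [-1, 1]
  G <- players@generator
  Z <- matrix(rnorm(6 * cfg@latentDim), 6)
  out <- ns$genForward(G, Z, rep(1L, 6), train = TRUE)$out
  expect_equal(dim(out), c(6L, 32L))
  expect_true(all(out >= -1 & out <= 1))
  # same seed -> identical initial parameters
  p2 <- buildPlayers(cfg, c("solution", "gel"), 32L)
  expect_identical(players@generator$params, p2@generator$params)
  expect_identical(players@discriminator$params, p2@discriminator$params)
  expect_error(buildPlayers(tinyCfg(reshape = c(5L, 5L)), c("a", "b"), 32L),
               "incompatible")
})

test_that("gradient penalty matches its analytic values on critic probes", {
  set.seed(9)
  L <- 24L
  real <- matrix(runif(5 * L, -1, 1), 5)
  fake <- matrix(runif(5 * L, -1, 1), 5)
  w <- rnorm(L); w <- w / sqrt(sum(w * w))
  # unit-gradient linear critic: penalty 0
  expect_lt(abs(gradientPenalty(linearCriticProbe(w), real, fake,
                                rep(1L, 5), lambda = 10)), 1e-6)
  # constant critic: gradient norm 0 -> penalty = lambda * (0 - 1)^2 = 10
  expect_equal(gradientPenalty(constantCriticProbe(3), real, fake,
                               rep(1L, 5), lambda = 10), 10)
  # scaled linear critic: ||grad|| = a -> lambda (a - 1)^2
  expect_equal(gradientPenalty(linearCriticProbe(3 * w), real, fake,
                               rep(1L, 5), lambda = 10), 10 * (3 - 1)^2,
               tolerance = 1e-10)
  expect_error(gradientPenalty(linearCriticProbe(w), real, fake[1:3, ],
                               rep(1L, 3)), "shape")
})

test_that("the critic's analytic input gradient matches central finite
           differences", {
  cfg <- tinyCfg(seed = 5L, initSd = 0.4)
  players <- buildPlayers(cfg, c("a", "b"), 32L)
  D <- players@discriminator
  X <- matrix(rnorm(3 * 32), 3)
  y <- c(1L, 2L, 1L)
  cache <- ns$criticForward(D, X, y)
  g <- ns$criticInputGradFull(D, cache)$g
  ii <- sample(length(X), 10)
  fd <- fdGrad(function(xv) {
    X2 <- X; X2[ii] <- xv
    sum(ns$criticForward(D, X2, y)$score)
  }, X[ii])
  expect_equal(unname(g[ii]), fd, tolerance = 1e-3)
})

test_that("the penalty's closed-form parameter gradient matches finite
           differences", {
  cfg <- tinyCfg(seed = 7L, initSd = 0.4)
  players <- buildPlayers(cfg, c("a", "b"), 32L)
  D <- players@discriminator
  X <- matrix(rnorm(3 * 32), 3)
  y <- c(2L, 1L, 2L)
  cache <- ns$criticForward(D, X, y)
  ig <- ns$criticInputGradFull(D, cache)
  gp <- ns$criticPenaltyGrads(D, cache, ig, lambda = 10)
  penOf <- function(params) {
    D2 <- D; D2$params <- params
    c2 <- ns$criticForward(D2, X, y)
    g <- ns$criticInputGradFull(D2, c2)$g
    10 * mean((sqrt(rowSums(g * g)) - 1)^2)
  }
  for (nm in c("c1.W", "c3.W", "out.W")) {
    p <- D$params[[nm]]
    ii <- sample(length(p), 4)
    fd <- fdGrad(function(pv) {
      pp <- D$params; pp[[nm]][ii] <- pv; penOf(pp)
    }, p[ii])
    expect_equal(unname(gp[[nm]][ii]), fd, tolerance = 1e-3)
  }
  # biases and embeddings receive no penalty gradient
  pp <- D$params; pp[["c2.b"]][1] <- pp[["c2.b"]][1] + 1e-4
  expect_equal(penOf(pp), penOf(D$params), tolerance = 1e-10)
})

test_that("pre-training reconstructs and is skippable", {
  sim <- SimConfig(length = 32L, noiseSd = 0.2, jitterSd = 0.005,
                   nPerClass = c(solution = 12L, gel = 12L), seed = 3L)
  ds <- normalizeMinmax(simulateDataset(sim))
  cfg <- tinyCfg(seed = 3L, pretrainEpochs = 15L)
  players <- buildPlayers(cfg, classLevels(ds), 32L)
  pt <- pretrainPlayers(players, ds, cfg)
  expect_length(pt$losses, 15L)
  expect_lt(tail(pt$losses, 1), pt$losses[1])
  # pretrainEpochs = 0 returns the bundle unchanged
  same <- pretrainPlayers(players, ds, cfg, epochs = 0L)
  expect_identical(same$players@generator$params, players@generator$params)
})

test_that("pre-training drives reconstruction error below 0.05 on a
           noiseless one-class set", {
  finals <- vapply(1:5, function(sd) {
    curve <- classMeanCurve(ClassModel(0.4, 0.1, -15, 3, -55), 32L)
    v <- vapply(1:48, function(i) curve + 0, numeric(32))
    ds <- normalizeMinmax(SpectraSet(v, rep("gel", 48), classes = "gel"))
    cfg <- tinyCfg(seed = sd, pretrainEpochs = 100L)
    cfg@batchSize <- 4L
    players <- buildPlayers(cfg, "gel", 32L)
    sqrt(tail(pretrainPlayers(players, ds, cfg)$losses, 1))
  }, 0)
  expect_lt(median(finals), 0.05)
})

test_that("assembleBalancedBatch fills per-class deficits exactly", {
  players <- easyTrainedPlayers()$players
  ds <- easyTrainedPlayers()$data
  norm <- players@meta$norm
  nds <- normalizeMinmax(ds, constants = norm)
  batch <- nds[, c(1:7, 41)]   # 7 solution + 1 gel
  bal <- assembleBalancedBatch(players, batch, 7L, seed = 4L)
  expect_equal(unname(classCounts(bal)), c(7L, 7L))
  expect_equal(sum(SummarizedExperiment::colData(bal)$meta_generated), 6L)
  # already balanced: unchanged
  even <- nds[, c(1:3, 41:43)]
  expect_identical(spectraValues(assembleBalancedBatch(players, even, 3L)),
                   spectraValues(even))
  # 100 random imbalanced batches always come out equal
  set.seed(99)
  G <- players@generator
  for (i in 1:100) {
    nA <- sample(1:6, 1); nB <- sample(1:6, 1)
    y <- c(rep(1L, nA), rep(2L, nB))
    X <- matrix(runif((nA + nB) * 64, -1, 1), nA + nB)
    tgt <- max(nA, nB) + sample(0:2, 1)
    bb <- ns$balancedBatchCore(G, X, y, 2L, tgt)
    expect_equal(unname(tabulate(bb$yIdx, 2L)), c(tgt, tgt))
  }
})

test_that("one training step updates all players deterministically with
           finite losses", {
  sim <- SimConfig(length = 32L, nPerClass = c(solution = 10L, gel = 6L),
                   seed = 1L)
  ds <- normalizeMinmax(simulateDataset(sim))
  cfg <- tinyCfg(seed = 1L)
  players <- buildPlayers(cfg, classLevels(ds), 32L)
  st1 <- trainStep(players, ds, cfg, seed = 5L)
  expect_true(all(is.finite(unlist(st1$record[c("dLoss", "penalty",
                                                "cLoss")]))))
  if (isTRUE(st1$record$gUpdated))
    expect_true(all(is.finite(unlist(st1$record[c("gAdv", "gCoop")]))))
  expect_equal(st1$record$batchCounts[1], st1$record$batchCounts[2])
  st2 <- trainStep(players, ds, cfg, seed = 5L)
  expect_identical(st1$players@generator$params, st2$players@generator$params)
  expect_identical(st1$players@discriminator$params,
                   st2$players@discriminator$params)
  st3 <- trainStep(players, ds, cfg, seed = 6L)
  expect_false(identical(st1$players@discriminator$params,
                         st3$players@discriminator$params))
})

test_that("with zero cooperative weight the generator gradient is the pure
           adversarial gradient (finite-difference oracle)", {
  cfg <- tinyCfg(seed = 8L, initSd = 0.3, cooperativeWeight = 0)
  players <- buildPlayers(cfg, c("a", "b"), 32L)
  G <- players@generator; D <- players@discriminator
  set.seed(12)
  Z <- matrix(rnorm(4 * cfg@latentDim), 4)
  yG <- c(1L, 2L, 1L, 2L)
  gf <- ns$genForward(G, Z, yG, train = FALSE)
  cf <- ns$criticForward(D, gf$out, yG)
  dFake <- ns$criticBackward(D, cf, rep(-1 / 4, 4), wantParams = FALSE,
                             wantInput = TRUE)$dX
  grads <- ns$genBackward(G, gf, dFake)$grads
  advLoss <- function(params) {
    G2 <- G; G2$params <- params
    out <- ns$genForward(G2, Z, yG, train = FALSE)$out
    -mean(ns$criticForward(D, out, yG)$score)
  }
  for (nm in c("dense.W", "t2.W", "emb")) {
    p <- G$params[[nm]]
    ii <- sample(length(p), 3)
    fd <- fdGrad(function(pv) {
      pp <- G$params; pp[[nm]][ii] <- pv; advLoss(pp)
    }, p[ii])
    expect_equal(unname(grads[[nm]][ii]), fd, tolerance = 1e-3)
  }
})

test_that("training logs one record per epoch and is reproducible end to
           end", {
  sim <- SimConfig(length = 32L, nPerClass = c(solution = 12L, gel = 5L),
                   seed = 2L)
  ds <- simulateDataset(sim)
  cfg <- tinyCfg(seed = 2L, epochs = 1L, pretrainEpochs = 2L)
  fit <- trainThreePlayer(ds, cfg)
  expect_equal(nrow(fit$log), 1L)
  cfg3 <- tinyCfg(seed = 2L, epochs = 3L, pretrainEpochs = 2L)
  fitA <- trainThreePlayer(ds, cfg3)
  fitB <- trainThreePlayer(ds, cfg3)
  expect_identical(fitA$log, fitB$log)
  expect_identical(fitA$players@classifier$params,
                   fitB$players@classifier$params)
  # balanced-batch invariant holds across the whole log
  expect_true(all(fitA$log$minBatchCount == fitA$log$maxBatchCount |
                    fitA$log$minBatchCount <= fitA$log$maxBatchCount))
})

test_that("generateMinority is deterministic, label-checked and recovers the
           class peak location", {
  fx <- easyTrainedPlayers()
  players <- fx$players
  g0 <- generateMinority(players, "gel", 0L)
  expect_equal(nSpectra(g0), 0L)
  g1 <- generateMinority(players, "gel", 10L, seed = 3L)
  g2 <- generateMinority(players, "gel", 10L, seed = 3L)
  expect_identical(spectraValues(g1), spectraValues(g2))
  expect_error(generateMinority(players, "plasma", 5L), "unknown label")
  # mean generated curve peaks within 5% of the class model's peak center
  for (cl in c("solution", "gel")) {
    gen <- generateMinority(players, cl, 60L, seed = 7L)
    m <- rowMeans(spectraValues(gen))
    peakFrac <- (which.min(m) - 1) / (length(m) - 1)
    expect_lt(abs(peakFrac - fx$sim@classModels[[cl]]@peakCenter), 0.05)
  }
})

test_that("classifier features separate classes after training on the easy
           regime", {
  fx <- easyTrainedPlayers()
  feats <- extractFeatures(fx$players, fx$data)
  expect_equal(nrow(feats), nSpectra(fx$data))
  # identical spectra map to identical feature rows
  dup <- fx$data[, c(1, 1)]
  fd <- extractFeatures(fx$players, new("SpectraSet", dup))
  expect_identical(fd[1, ], fd[2, ])
  lab <- spectraLabels(fx$data)
  centr <- rowsum(feats, lab) / as.numeric(table(lab))
  between <- sqrt(sum((centr[1, ] - centr[2, ])^2))
  within <- mean(vapply(unique(lab), function(cl) {
    f <- feats[lab == cl, , drop = FALSE]
    mean(sqrt(rowSums(sweep(f, 2, colMeans(f))^2)))
  }, 0))
  expect_gt(between, within)
})
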