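# The three-player framework: a class-conditional generator, a Wasserstein
# critic with gradient penalty, and a CNN classifier, trained jointly.
# Adversarial learning (generator vs critic) makes generated spectra
# realistic; cooperative learning (generator + classifier) makes them
# class-distinguishable; every classifier batch is balanced by filling
# minority deficits with generated samples.

mostSquareFactors <- function(L) {
  r <- max(Filter(function(d) L %% d == 0L, seq_len(floor(sqrt(L)))))
  c(as.integer(r), as.integer(L / r))
}

resolveReshape <- function(cfg, length) {
  if (all(cfg@reshape > 0L)) {
    if (prod(cfg@reshape) != length)
      stop("reshape (", cfg@reshape[1], " x ", cfg@reshape[2],
           ") is incompatible with spectrum length ", length)
    cfg@reshape
  } else mostSquareFactors(length)
}

#' Build the three players
#'
#' Constructs the critic (4 blocks of \[Conv2D, LeakyReLU\] plus a
#' class-embedding-conditioned linear score head), the generator (latent +
#' class embedding through a dense layer and 4 blocks of \[Conv2DTranspose,
#' LeakyReLU, BatchNorm\], final tanh), and the classifier (4 conv blocks, a
#' feature layer and a softmax head), all with 4x4 kernels, stride 2, same
#' padding and random-normal initialization. The 1-D spectrum of length L is
#' laid out on a `rows x cols` grid (`config@reshape`, default most-square
#' factorization).
#'
#' @param config a [ThreePlayerConfig-class].
#' @param classes ordered class labels.
#' @param length spectrum length.
#' @param norm optional normalization constants (as stored by
#'   [normalizeMinmax()]) used to denormalize generated spectra.
#' @return an untrained [PlayerBundle-class].
#' @export
buildPlayers <- function(config, classes, length, norm = NULL) {
  stopifnot(is(config, "ThreePlayerConfig"))
  validObject(config)
  classes <- as.character(classes)
  rc <- resolveReshape(config, as.integer(length))
  withSeed(deriveSeed(config@seed, "init"), {
    G <- buildGenerator(config, length(classes), rc[1], rc[2])
    D <- buildCritic(config, length(classes), rc[1], rc[2])
    C <- buildClassifier(config, length(classes), rc[1], rc[2])
    new("PlayerBundle", generator = G, discriminator = D, classifier = C,
        meta = list(classes = classes, length = as.integer(length),
                    reshape = rc, config = config, norm = norm,
                    trained = FALSE))
  })
}

#' Critic probes with known input gradients
#'
#' Tiny stand-ins for the critic used to validate the gradient penalty
#' analytically: `linearCriticProbe(w)` scores `x . w` (constant gradient
#' `w`), `constantCriticProbe(value)` scores a constant (zero gradient).
#'
#' @param w weight vector (length = spectrum length).
#' @return an object accepted by [gradientPenalty()].
#' @export
linearCriticProbe <- function(w)
  structure(list(w = as.numeric(w)), class = "linearCriticProbe")

#' @rdname linearCriticProbe
#' @param value the constant score.
#' @export
constantCriticProbe <- function(value = 0)
  structure(list(value = value), class = "constantCriticProbe")

probeInputGrad <- function(disc, X, yIdx) {
  if (inherits(disc, "linearCriticProbe")) {
    matrix(disc$w, nrow(X), length(disc$w), byrow = TRUE)
  } else if (inherits(disc, "constantCriticProbe")) {
    matrix(0, nrow(X), ncol(X))
  } else if (is(disc, "PlayerBundle")) {
    cache <- criticForward(disc@discriminator, X, yIdx)
    criticInputGradFull(disc@discriminator, cache)$g
  } else stop("unsupported discriminator object")
}

#' Gradient penalty on real/fake interpolates
#'
#' Draws `epsilon ~ U(0, 1)` per sample, forms `xhat = epsilon * real +
#' (1 - epsilon) * fake`, and returns
#' `lambda * mean((||grad_xhat D(xhat, label)||_2 - 1)^2)`. The input
#' gradient is computed analytically by backpropagation to the input.
#'
#' @param discriminator a [PlayerBundle-class] (its critic is used) or a
#'   probe from [linearCriticProbe()] / [constantCriticProbe()].
#' @param realBatch,fakeBatch numeric matrices, one sample per row, same
#'   shape.
#' @param labels integer class indices (1-based), one per sample.
#' @param lambda penalty coefficient (default 10).
#' @param seed integer seed for the interpolation draws.
#' @return the scalar penalty.
#' @examples
#' w <- rnorm(8); w <- w / sqrt(sum(w^2))
#' gradientPenalty(linearCriticProbe(w), matrix(rnorm(40), 5),
#'                 matrix(rnorm(40), 5), rep(1, 5))   # ~0: unit gradient
#' @export
gradientPenalty <- function(discriminator, realBatch, fakeBatch, labels,
                            lambda = 10, seed = 1L) {
  realBatch <- as.matrix(realBatch); fakeBatch <- as.matrix(fakeBatch)
  if (!all(dim(realBatch) == dim(fakeBatch)))
    stop("realBatch and fakeBatch must have the same shape")
  n <- nrow(realBatch)
  eps <- withSeed(deriveSeed(seed, "gp-eps"), runif(n))
  xhat <- realBatch * eps + fakeBatch * (1 - eps)
  g <- probeInputGrad(discriminator, xhat, as.integer(labels))
  norms <- sqrt(rowSums(g * g))
  lambda * mean((norms - 1)^2)
}

# ---- pre-training -----------------------------------------------------------

# encoder head mapping the critic trunk output to the latent space
buildEncoderHead <- function(D, latentDim, initSd) {
  list(W = initMat(D$trunk$outDim, latentDim, initSd),
       b = numeric(latentDim))
}

#' Autoencoder pre-training of generator and critic trunk
#'
#' Initializes the adversarial game the way balancing GANs with gradient
#' penalty do: an encoder sharing the critic's convolutional trunk maps real
#' spectra to the latent space, the class-conditional generator decodes them,
#' and both are trained by mean-squared reconstruction for
#' `config@pretrainEpochs` epochs. Reconstruction batches are drawn
#' class-balanced (minority samples re-drawn with replacement), applying the
#' framework's balanced-batch principle to the initialization as well —
#' otherwise the objective is dominated by the majority class and the class
#' embedding never learns to decode minority spectra. With
#' `pretrainEpochs = 0` the bundle is returned unchanged.
#'
#' @param players a [PlayerBundle-class].
#' @param train a [SpectraSet-class], normalized to \[-1, 1\].
#' @param config a [ThreePlayerConfig-class].
#' @param epochs override of `config@pretrainEpochs`.
#' @return list with `players` (updated bundle) and `losses` (per-epoch mean
#'   reconstruction loss).
#' @export
pretrainPlayers <- function(players, train, config = players@meta$config,
                            epochs = config@pretrainEpochs) {
  stopifnot(is(players, "PlayerBundle"), is(train, "SpectraSet"))
  if (epochs == 0L) return(list(players = players, losses = numeric()))
  X <- t(spectraValues(train))
  yIdx <- match(spectraLabels(train), players@meta$classes)
  G <- players@generator; D <- players@discriminator
  enc <- withSeed(deriveSeed(config@seed, "enc-init"),
                  buildEncoderHead(D, config@latentDim, config@initSd))
  encAdam <- adamInit(enc)
  encBn <- list(mean = numeric(config@latentDim),
                var = rep(1, config@latentDim))
  losses <- numeric(epochs)
  n <- nrow(X)
  byClass <- split(seq_len(n), yIdx)
  perClass <- ceiling(n / length(byClass))
  for (ep in seq_len(epochs)) {
    ord <- withSeed(deriveSeed(config@seed, "pretrain-epoch", ep), {
      # class-balanced epoch: equal draws per class, with replacement for
      # classes smaller than the per-class quota
      sample(unlist(lapply(byClass, function(ix)
        ix[sample.int(length(ix), perClass, replace = TRUE)])))
    })
    bs <- split(ord, ceiling(seq_along(ord) / config@batchSize))
    epLoss <- 0
    for (b in bs) {
      Xb <- X[b, , drop = FALSE]
      tf <- trunkForward(D$trunk, D$params, "c", Xb, D$slope)
      Zraw <- tf$h %*% enc$W + rep(enc$b, each = length(b))
      # standardize the latent (non-affine batch normalization) so the
      # code the decoder learns to invert lives on the unit scale of the
      # sampling prior
      zb <- bnForward(1L, ncol(Zraw), rep(1, ncol(Zraw)),
                      numeric(ncol(Zraw)), Zraw, encBn, train = TRUE)
      encBn <- zb$state
      Z <- zb$out
      gf <- genForward(G, Z, yIdx[b], train = TRUE)
      G$bnState <- gf$newState
      diff <- gf$out - Xb
      loss <- mean(diff * diff)
      if (!is.finite(loss))
        stop("non-finite reconstruction loss in pre-training epoch ", ep)
      epLoss <- epLoss + loss * length(b)
      dOut <- 2 * diff / length(diff)
      gb <- genBackward(G, gf, dOut)
      dZraw <- bnBackward(1L, ncol(Zraw), rep(1, ncol(Zraw)), zb, gb$dZ)$dX
      encGrads <- list(W = crossprod(tf$h, dZraw), b = colSums(dZraw))
      dh <- tcrossprod(dZraw, enc$W)
      tb <- trunkBackward(D$trunk, D$params, "c", tf$caches, dh,
                          wantParams = TRUE, wantInput = FALSE)
      G <- applyAdam(G, gb$grads, config)
      upd <- adamStep(enc, encGrads, encAdam, config@learningRate,
                      config@beta1, config@beta2)
      enc <- upd$params; encAdam <- upd$state
      updD <- adamStep(D$params, tb$grads, D$adam, config@learningRate,
                       config@beta1, config@beta2)
      D$params <- updD$params; D$adam <- updD$state
    }
    losses[ep] <- epLoss / length(ord)
  }
  # fit the class-conditional latent prior to the encoded training spectra,
  # so class-c generation samples the latent region that decodes to class c
  Zraw <- trunkForward(D$trunk, D$params, "c", X, D$slope)$h %*% enc$W +
    rep(enc$b, each = n)
  # standardize with the encoder-BN running statistics: the population
  # counterpart of the balanced-batch standardization used in pre-training
  # (full-data statistics would be shifted toward the majority class)
  Zall <- sweep(sweep(Zraw, 2, encBn$mean), 2,
                sqrt(encBn$var + 1e-5), "/")
  pooledSd <- mean(apply(Zall, 2, sd))
  G$latentPrior$factors <- vector("list", G$nClasses)
  G$latentPrior$ridge <- 0.05 * pooledSd
  for (ci in unique(yIdx)) {
    Zc <- Zall[yIdx == ci, , drop = FALSE]
    mu <- colMeans(Zc)
    G$latentPrior$mu[ci, ] <- mu
    # full empirical covariance factor: draws stay in the affine span of the
    # class's observed codes (plus a small isotropic ridge)
    G$latentPrior$factors[[ci]] <- if (nrow(Zc) > 1L)
      sweep(Zc, 2, mu) / sqrt(nrow(Zc) - 1) else
        matrix(pooledSd, 1L, ncol(Zc))
  }
  # calibrate the decoder's batch-norm running statistics on the balanced
  # code population it was trained on, in one pass (momentum 0 overwrites
  # the stale stats accumulated while weights were still moving);
  # adversarial training and generation then run against these frozen stats
  calIdx <- unlist(lapply(byClass, function(ix) rep_len(ix, perClass)))
  calib <- genForward(G, Zall[calIdx, , drop = FALSE], yIdx[calIdx],
                      train = TRUE, momentum = 0)
  G$bnState <- calib$newState
  players@generator <- G
  players@discriminator <- D
  players@meta$pretrainLosses <- losses
  list(players = players, losses = losses)
}

# ---- balanced batches -------------------------------------------------------

# matrix-level balanced batch: fill per-class deficits with generator output
# (train-mode batch statistics, as in in-graph generation)
balancedBatchCore <- function(G, X, yIdx, nClasses, perClassTarget) {
  counts <- tabulate(yIdx, nClasses)
  deficit <- pmax(perClassTarget - counts, 0L)
  nGen <- sum(deficit)
  if (nGen == 0L)
    return(list(X = X, yIdx = yIdx, generated = rep(FALSE, nrow(X)),
                genCache = NULL))
  yGen <- rep(seq_len(nClasses), deficit)
  gf <- genForward(G, latentDraw(G, yGen), yGen, train = FALSE)
  list(X = rbind(X, gf$out), yIdx = c(yIdx, yGen),
       generated = c(rep(FALSE, nrow(X)), rep(TRUE, nGen)), genCache = gf)
}

#' Assemble a balanced classifier batch
#'
#' Appends generator output, conditioned on each deficient class, until every
#' class reaches `perClassTarget` samples. Generated samples are flagged in
#' `meta_generated`.
#'
#' @param players a [PlayerBundle-class].
#' @param realBatch a [SpectraSet-class] on the generator's \[-1, 1\] scale.
#' @param perClassTarget target per-class count (>= current max count).
#' @param seed integer seed for the latent draws.
#' @return a [SpectraSet-class] with equal per-class counts.
#' @export
assembleBalancedBatch <- function(players, realBatch, perClassTarget,
                                  seed = 1L) {
  stopifnot(is(players, "PlayerBundle"), is(realBatch, "SpectraSet"))
  cls <- players@meta$classes
  counts <- classCounts(realBatch)[cls]
  if (perClassTarget < max(counts, na.rm = TRUE))
    stop("perClassTarget must be >= the largest per-class count")
  X <- t(spectraValues(realBatch))
  yIdx <- match(spectraLabels(realBatch), cls)
  bb <- withSeed(deriveSeed(seed, "balance"),
                 balancedBatchCore(players@generator, X, yIdx, length(cls),
                                   as.integer(perClassTarget)))
  nGen <- sum(bb$generated)
  if (nGen == 0L) return(realBatch)
  appendSynthetic(realBatch,
                  t(bb$X[bb$generated, , drop = FALSE]),
                  cls[bb$yIdx[bb$generated]], "gen")
}

# ---- training ---------------------------------------------------------------

# one iteration: critic update (Wasserstein + gradient penalty), generator
# update (adversarial + cooperative), classifier update (balanced batch CE);
# uses the ambient RNG stream
trainStepCore <- function(G, D, C, Xb, ybIdx, cfg, nClasses) {
  n <- nrow(Xb)
  lam <- cfg@gpCoefficient
  # -- critic update(s)
  dLoss <- NA_real_; penalty <- NA_real_
  for (ic in seq_len(cfg@nCritic)) {
    gf <- genForward(G, latentDraw(G, ybIdx), ybIdx, train = FALSE)
    fake <- gf$out
    cr <- criticForward(D, Xb, ybIdx)
    cf <- criticForward(D, fake, ybIdx)
    advD <- mean(cf$score) - mean(cr$score)
    gr <- criticBackward(D, cr, rep(-1 / n, n))$grads
    gfk <- criticBackward(D, cf, rep(1 / n, n))$grads
    eps <- runif(n)
    xhat <- Xb * eps + fake * (1 - eps)
    ch <- criticForward(D, xhat, ybIdx)
    ig <- criticInputGradFull(D, ch)
    norms <- sqrt(rowSums(ig$g^2))
    penalty <- lam * mean((norms - 1)^2)
    gp <- criticPenaltyGrads(D, ch, ig, lam)
    dLoss <- advD + penalty
    if (!is.finite(dLoss)) stop("non-finite critic loss")
    D <- applyAdam(D, addGrads(addGrads(gr, gfk), gp), cfg)
  }
  # -- generator update: adversarial + cooperative. The update only fires
  # while the critic is a valid witness (real scoring above fake on this
  # batch): when the generator outruns the critic, ascending the critic's
  # score would push generation off the data manifold, so the critic gets
  # to catch up first.
  gAdv <- NA_real_; gCoop <- NA_real_
  gUpdated <- is.finite(advD) && advD < 0
  if (gUpdated) {
    yG <- sample.int(nClasses, n, replace = TRUE)
    gf2 <- genForward(G, latentDraw(G, yG), yG, train = FALSE)
    cf2 <- criticForward(D, gf2$out, yG)
    gAdv <- -mean(cf2$score)
    dFake <- criticBackward(D, cf2, rep(-1 / n, n), wantParams = FALSE,
                            wantInput = TRUE)$dX
    gCoop <- 0
    if (cfg@cooperativeWeight != 0) {
      kf <- clfForward(C, gf2$out)
      ce <- ceLossGrad(kf$logits, yG)
      gCoop <- ce$loss
      dFake <- dFake + cfg@cooperativeWeight *
        clfBackward(C, kf, ce$dLogits, wantParams = FALSE,
                    wantInput = TRUE)$dX
    }
    if (!is.finite(gAdv + gCoop)) stop("non-finite generator loss")
    gb <- genBackward(G, gf2, dFake)
    G <- applyAdam(G, gb$grads, cfg)
  }
  # -- classifier update on the balanced batch: every class is topped up to
  # the batch size, so generated samples appear for all classes (abundantly
  # for the minority) and generation artifacts cannot act as a class cue
  target <- max(cfg@batchSize, max(tabulate(ybIdx, nClasses)))
  bb <- balancedBatchCore(G, Xb, ybIdx, nClasses, target)
  kf2 <- clfForward(C, bb$X)
  ce2 <- ceLossGrad(kf2$logits, bb$yIdx)
  if (!is.finite(ce2$loss)) stop("non-finite classifier loss")
  C <- applyAdam(C, clfBackward(C, kf2, ce2$dLogits)$grads, cfg)
  list(G = G, D = D, C = C,
       rec = list(dLoss = dLoss, gAdv = gAdv, gCoop = gCoop,
                  penalty = penalty, cLoss = ce2$loss, gUpdated = gUpdated,
                  batchCounts = tabulate(bb$yIdx, nClasses)))
}

#' One three-player training iteration
#'
#' Performs `nCritic` critic updates (Wasserstein loss plus gradient
#' penalty), one generator update (adversarial term plus
#' `cooperativeWeight` times the classifier cross-entropy on generated
#' samples against their conditioning labels), and one classifier update
#' (cross-entropy on the balanced batch). The generator update fires only
#' while the critic is a valid witness — scoring real above generated on the
#' batch — otherwise the critic catches up first (`record$gUpdated` says
#' which happened). Deterministic for fixed `(players, batch, seed)`.
#'
#' @param players a [PlayerBundle-class].
#' @param batch a [SpectraSet-class] on the \[-1, 1\] scale.
#' @param config a [ThreePlayerConfig-class].
#' @param seed integer seed for this step's draws.
#' @return list with `players` (updated) and `record` (losses, penalty,
#'   per-class balanced-batch counts).
#' @export
trainStep <- function(players, batch, config = players@meta$config,
                      seed = 1L) {
  stopifnot(is(players, "PlayerBundle"), is(batch, "SpectraSet"))
  if (nSpectra(batch) == 0L) stop("empty batch")
  cls <- players@meta$classes
  Xb <- t(spectraValues(batch))
  ybIdx <- match(spectraLabels(batch), cls)
  st <- withSeed(deriveSeed(seed, "step"),
                 trainStepCore(players@generator, players@discriminator,
                               players@classifier, Xb, ybIdx, config,
                               length(cls)))
  players@generator <- st$G
  players@discriminator <- st$D
  players@classifier <- st$C
  list(players = players, record = st$rec)
}

#' Train the three-player framework
#'
#' Normalizes the training spectra to \[-1, 1\] (storing the constants for
#' later denormalization), runs autoencoder pre-training, then
#' `config@epochs` epochs of three-player iterations over shuffled batches
#' with Adam. Fully deterministic for fixed `(trainData, config)`.
#'
#' @param trainData a [SpectraSet-class] with >= 2 classes present (raw
#'   scale; normalization is handled internally).
#' @param config a [ThreePlayerConfig-class].
#' @param evalData optional [SpectraSet-class]; when given, per-epoch macro
#'   F-score of the classifier on it is logged.
#' @param verbose print per-epoch losses.
#' @return list with `players` (trained [PlayerBundle-class]) and `log`
#'   (data.frame, one row per epoch: mean critic/generator/cooperative/
#'   classifier losses, penalty, the fraction of steps in which the
#'   generator updated (`gUpdateRate`; see [trainStep()] for the witness
#'   gate), min/max per-class balanced-batch counts, optional eval macro F;
#'   `gAdv`/`gCoop` are `NA` in epochs where the generator never updated).
#' @examples
#' \donttest{
#' ds <- simulateDataset(SimConfig(length = 64,
#'                                 nPerClass = c(solution = 40, gel = 8)))
#' fit <- trainThreePlayer(ds, scaledThreePlayerConfig(epochs = 2,
#'                                                     pretrainEpochs = 2))
#' fit$log
#' }
#' @export
trainThreePlayer <- function(trainData, config = scaledThreePlayerConfig(),
                             evalData = NULL, verbose = FALSE) {
  stopifnot(is(trainData, "SpectraSet"))
  counts <- classCounts(trainData)
  if (sum(counts > 0L) < 2L) stop("need at least 2 classes present")
  normTrain <- normalizeMinmax(trainData)
  norm <- S4Vectors::metadata(normTrain)$norm
  cls <- classLevels(trainData)
  players <- buildPlayers(config, cls, spectrumLength(trainData), norm)
  pt <- pretrainPlayers(players, normTrain, config)
  players <- pt$players
  X <- t(spectraValues(normTrain))
  yIdx <- match(spectraLabels(normTrain), cls)
  n <- nrow(X)
  G <- players@generator; D <- players@discriminator; C <- players@classifier
  evalX <- NULL; evalY <- NULL
  if (!is.null(evalData)) {
    ne <- normalizeMinmax(evalData, constants = norm)
    evalX <- t(spectraValues(ne))
    evalY <- spectraLabels(evalData)
  }
  logRows <- vector("list", config@epochs)
  for (ep in seq_len(config@epochs)) {
    res <- withSeed(deriveSeed(config@seed, "train-epoch", ep), {
      ord <- sample.int(n)
      bs <- split(ord, ceiling(seq_along(ord) / config@batchSize))
      out <- vector("list", length(bs))
      for (bi in seq_along(bs)) {
        b <- bs[[bi]]
        st <- trainStepCore(G, D, C, X[b, , drop = FALSE], yIdx[b],
                            config, length(cls))
        G <- st$G; D <- st$D; C <- st$C
        out[[bi]] <- st$rec
      }
      # recalibrate the generator's frozen batch-norm statistics against its
      # current weights on class-balanced prior draws (one forward pass)
      yc <- rep(seq_along(cls), each = max(config@batchSize,
                                           ceiling(n / length(cls))))
      G$bnState <- genForward(G, latentDraw(G, yc), yc, train = TRUE,
                              momentum = 0)$newState
      list(G = G, D = D, C = C, recs = out)
    })
    G <- res$G; D <- res$D; C <- res$C
    recs <- res$recs
    meanOr <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    row <- data.frame(
      epoch = ep,
      dLoss = mean(vapply(recs, `[[`, 0, "dLoss")),
      gAdv = meanOr(vapply(recs, `[[`, 0, "gAdv")),
      gCoop = meanOr(vapply(recs, `[[`, 0, "gCoop")),
      penalty = mean(vapply(recs, `[[`, 0, "penalty")),
      cLoss = mean(vapply(recs, `[[`, 0, "cLoss")),
      gUpdateRate = mean(vapply(recs, `[[`, TRUE, "gUpdated")),
      minBatchCount = min(vapply(recs, function(r) min(r$batchCounts), 0)),
      maxBatchCount = max(vapply(recs, function(r) max(r$batchCounts), 0)))
    if (!is.null(evalX)) {
      pred <- cls[max.col(softmaxProbs(clfForward(C, evalX)$logits),
                          ties.method = "first")]
      row$evalMacroF <- computeMetrics(evalY, pred, cls)$macro[["f_score"]]
    }
    logRows[[ep]] <- row
    if (verbose)
      message(sprintf("epoch %3d  D %.4f  G %.4f  coop %.4f  C %.4f", ep,
                      row$dLoss, row$gAdv, row$gCoop, row$cLoss))
  }
  players@generator <- G
  players@discriminator <- D
  players@classifier <- C
  players@meta$trained <- TRUE
  list(players = players, log = do.call(rbind, logRows))
}

# ---- using trained players --------------------------------------------------

#' Generate minority-class spectra
#'
#' Draws `n` latent vectors and decodes them conditioned on `classLabel`.
#' Output is denormalized to the original scale by default (using the
#' constants stored at training time) and flagged `meta_generated`.
#'
#' @param players a trained [PlayerBundle-class].
#' @param classLabel class to condition on.
#' @param n number of spectra.
#' @param seed integer seed.
#' @param rescale denormalize to the original scale (default TRUE).
#' @return a [SpectraSet-class] of `n` generated spectra.
#' @export
generateMinority <- function(players, classLabel, n, seed = 1L,
                             rescale = TRUE) {
  stopifnot(is(players, "PlayerBundle"))
  cls <- players@meta$classes
  ci <- match(as.character(classLabel), cls)
  if (is.na(ci)) stop("unknown label '", classLabel, "'")
  L <- players@meta$length
  if (n == 0L)
    return(SpectraSet(matrix(0, L, 0), character(), classes = cls))
  G <- players@generator
  out <- withSeed(deriveSeed(seed, "generate"), {
    yg <- rep(ci, n)
    genForward(G, latentDraw(G, yg), yg, train = FALSE)$out
  })
  ds <- SpectraSet(t(out), rep(cls[ci], n), classes = cls,
                   meta = data.frame(meta_generated = rep(TRUE, n)))
  nm <- players@meta$norm
  if (rescale && !is.null(nm)) {
    S4Vectors::metadata(ds)$norm <- nm
    ds <- denormalize(ds)
  }
  ds
}

# normalize a SpectraSet with the bundle's stored constants (no leakage)
normalizeForPlayers <- function(players, spectra) {
  nm <- players@meta$norm
  if (is.null(nm)) return(t(spectraValues(spectra)))
  t(spectraValues(normalizeMinmax(spectra, constants = nm)))
}

#' Intermediate-layer features of the classifier
#'
#' Activations of the classifier's penultimate (feature) layer, one row per
#' spectrum — the representation used for 2-D embedding plots of real versus
#' generated samples.
#'
#' @param players a trained [PlayerBundle-class].
#' @param spectra a [SpectraSet-class] (raw scale).
#' @return numeric matrix (spectra x featureDim).
#' @export
extractFeatures <- function(players, spectra) {
  stopifnot(is(players, "PlayerBundle"), is(spectra, "SpectraSet"))
  X <- normalizeForPlayers(players, spectra)
  clfForward(players@classifier, X)$feat
}

#' Classify spectra with the bundled classifier
#'
#' @param players a trained [PlayerBundle-class].
#' @param spectra a [SpectraSet-class] (raw scale).
#' @return list with `labels` (predicted, ties broken to the lowest class
#'   index) and `probs` (n x classes probability matrix).
#' @export
classifySpectra <- function(players, spectra) {
  stopifnot(is(players, "PlayerBundle"), is(spectra, "SpectraSet"))
  X <- normalizeForPlayers(players, spectra)
  probs <- softmaxProbs(clfForward(players@classifier, X)$logits)
  colnames(probs) <- players@meta$classes
  list(labels = players@meta$classes[max.col(probs, ties.method = "first")],
       probs = probs)
}

#' Train the CNN classifier alone
#'
#' The classifier of the three-player framework trained on its own by
#' cross-entropy — the protocol used for the no-augmentation baseline and for
#' sampling-based augmenters.
#'
#' @param trainData a [SpectraSet-class] (raw scale).
#' @param config a [ThreePlayerConfig-class] (`epochs`, optimizer and
#'   classifier architecture fields are used).
#' @return a [PlayerBundle-class] whose classifier is trained (generator and
#'   critic stay at initialization).
#' @export
trainClassifier <- function(trainData, config = scaledThreePlayerConfig()) {
  stopifnot(is(trainData, "SpectraSet"))
  normTrain <- normalizeMinmax(trainData)
  norm <- S4Vectors::metadata(normTrain)$norm
  cls <- classLevels(trainData)
  players <- buildPlayers(config, cls, spectrumLength(trainData), norm)
  X <- t(spectraValues(normTrain))
  yIdx <- match(spectraLabels(normTrain), cls)
  C <- players@classifier
  n <- nrow(X)
  for (ep in seq_len(config@epochs)) {
    C <- withSeed(deriveSeed(config@seed, "clf-epoch", ep), {
      ord <- sample.int(n)
      bs <- split(ord, ceiling(seq_along(ord) / config@batchSize))
      for (b in bs) {
        kf <- clfForward(C, X[b, , drop = FALSE])
        ce <- ceLossGrad(kf$logits, yIdx[b])
        C <- applyAdam(C, clfBackward(C, kf, ce$dLogits)$grads, config)
      }
      C
    })
  }
  players@classifier <- C
  players@meta$trained <- TRUE
  players
}

# three-player GAN as a registered augmenter: the harness recognizes the
# returned bundle and evaluates its jointly-trained classifier
registerAugmenter("threeplayer-gan", function(train, targetCounts, seed,
                                              protocol = NULL, ...) {
  cfg <- if (!is.null(protocol) && !is.null(protocol$gan)) protocol$gan
         else scaledThreePlayerConfig()
  cfg@seed <- as.integer(seed)
  trainThreePlayer(train, cfg)
})
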