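#' @import methods
#' @import S4Vectors
#' @import SummarizedExperiment
#' @importFrom stats approx coef lm pt predict residuals rnorm runif setNames
#' @importFrom utils modifyList
NULL

#' SpectraSet: labeled one-dimensional spectra
#'
#' A `SpectraSet` holds a collection of equal-length one-dimensional spectra
#' (for example impedance phase-angle curves) together with one class label per
#' spectrum. It extends [SummarizedExperiment::SummarizedExperiment]: the
#' single assay `"spectra"` is a numeric matrix with one column per spectrum
#' and one row per measurement index, and `colData` carries `id`, `label` and
#' any `meta_*` columns (experiment id, well id, original frequency range,
#' generated/synthetic flags, ...). The ordered class inventory lives in
#' `metadata(x)$classes`; min-max normalization constants, when present, in
#' `metadata(x)$norm`.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [SpectraSet()], [readSpectra()], [simulateDataset()]
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  msg <- character()
  if (!"spectra" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'spectra' is missing")
  else {
    v <- SummarizedExperiment::assay(object, "spectra")
    if (!is.numeric(v)) msg <- c(msg, "assay 'spectra' must be numeric")
    else if (length(v) && !all(is.finite(v)))
      msg <- c(msg, "all spectrum values must be finite")
    if (nrow(v) < 1L) msg <- c(msg, "spectrum length must be > 0")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"label" %in% colnames(cd)) msg <- c(msg, "colData must contain 'label'")
  cls <- S4Vectors::metadata(object)$classes
  if (is.null(cls)) msg <- c(msg, "metadata()$classes is missing")
  else if ("label" %in% colnames(cd) && ncol(object) > 0 &&
           !all(cd$label %in% cls))
    msg <- c(msg, "every spectrum label must be one of metadata()$classes")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectraSet
#'
#' @param values numeric matrix, one spectrum per column (length x n), or a
#'   single numeric vector for a one-spectrum set.
#' @param labels character vector of class labels, one per spectrum.
#' @param classes ordered class inventory; defaults to the sorted unique labels.
#' @param meta optional `data.frame` of per-spectrum metadata (columns are
#'   stored as given; conventionally prefixed `meta_`).
#' @param ids spectrum identifiers; default `"s1"`, `"s2"`, ...
#' @return a validated [SpectraSet-class] object.
#' @examples
#' ss <- SpectraSet(matrix(rnorm(40), nrow = 10), rep(c("gel", "solution"), 2))
#' ss
#' @export
SpectraSet <- function(values, labels, classes = NULL, meta = NULL, ids = NULL) {
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- ncol(values)
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("need one label per spectrum (", n, " spectra, ", length(labels),
         " labels)")
  if (is.null(classes)) classes <- sort(unique(labels))
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(n))
  cd <- S4Vectors::DataFrame(id = as.character(ids), label = labels)
  if (!is.null(meta) && ncol(as.data.frame(meta)) > 0) {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (nrow(meta) != n) stop("meta must have one row per spectrum")
    for (cn in colnames(meta)) cd[[cn]] <- meta[[cn]]
  }
  colnames(values) <- cd$id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(spectra = values), colData = cd)
  S4Vectors::metadata(se)$classes <- as.character(classes)
  new("SpectraSet", se)
}

#' @describeIn SpectraSet the length x n matrix of spectrum values.
#' @param x a `SpectraSet`.
#' @export
spectraValues <- function(x) SummarizedExperiment::assay(x, "spectra")

#' @describeIn SpectraSet character vector of per-spectrum class labels.
#' @export
spectraLabels <- function(x) as.character(SummarizedExperiment::colData(x)$label)

#' @describeIn SpectraSet the ordered class inventory.
#' @export
classLevels <- function(x) S4Vectors::metadata(x)$classes

#' @describeIn SpectraSet the common spectrum length.
#' @export
spectrumLength <- function(x) nrow(x)

#' @describeIn SpectraSet number of spectra in the set.
#' @export
nSpectra <- function(x) ncol(x)

#' @describeIn SpectraSet named per-class spectrum counts (all classes,
#'   including empty ones).
#' @export
classCounts <- function(x) {
  cls <- classLevels(x)
  cnt <- table(factor(spectraLabels(x), levels = cls))
  setNames(as.integer(cnt), cls)
}

setMethod("show", "SpectraSet", function(object) {
  cat("SpectraSet with", nSpectra(object), "spectra of length",
      spectrumLength(object), "\n")
  cc <- classCounts(object)
  cat("  classes:", paste0(names(cc), " (", cc, ")", collapse = ", "), "\n")
  nm <- S4Vectors::metadata(object)$norm
  if (!is.null(nm))
    cat(sprintf("  normalized to [%g, %g] (original range [%g, %g])\n",
                nm$lo, nm$hi, nm$min, nm$max))
})

#' ImbalanceSpec: an imbalanced training-split design
#'
#' Describes one row of an imbalanced-split design: which class is the
#' majority and which the minority, and how many training spectra to draw from
#' each. The balanced ratio (minority / majority training count) is derived,
#' never stored, so it can not drift out of sync.
#'
#' @slot majorityClass,minorityClass class labels.
#' @slot majorityN,minorityN per-class training counts.
#' @seealso [makeImbalancedSplit()], [balancedRatio()]
#' @export
setClass("ImbalanceSpec", representation(
  majorityClass = "character", minorityClass = "character",
  majorityN = "integer", minorityN = "integer"))

setValidity("ImbalanceSpec", function(object) {
  msg <- character()
  if (object@majorityN < 1L || object@minorityN < 1L)
    msg <- c(msg, "class counts must be positive")
  if (object@minorityN > object@majorityN)
    msg <- c(msg, "minorityN must not exceed majorityN")
  if (object@majorityClass == object@minorityClass)
    msg <- c(msg, "majority and minority class must differ")
  if (length(msg)) msg else TRUE
})

#' @rdname ImbalanceSpec-class
#' @param majorityClass,minorityClass class labels.
#' @param majorityN,minorityN per-class training counts.
#' @examples
#' ImbalanceSpec("solution", "gel", 150, 4)
#' @export
ImbalanceSpec <- function(majorityClass, minorityClass, majorityN, minorityN) {
  new("ImbalanceSpec", majorityClass = as.character(majorityClass),
      minorityClass = as.character(minorityClass),
      majorityN = as.integer(majorityN), minorityN = as.integer(minorityN))
}

#' @describeIn ImbalanceSpec-class the balanced ratio minorityN / majorityN at
#'   full precision (display rounds to 3 decimals).
#' @param spec an `ImbalanceSpec`.
#' @export
balancedRatio <- function(spec) spec@minorityN / spec@majorityN

setMethod("show", "ImbalanceSpec", function(object) {
  cat(sprintf("ImbalanceSpec: majority %s (n=%d), minority %s (n=%d), ratio %.3f\n",
              object@majorityClass, object@majorityN, object@minorityClass,
              object@minorityN, round(balancedRatio(object), 3)))
})

#' ClassModel: parametric mean curve of one spectrum class
#'
#' A Gaussian resonance-like dip/peak on a linear baseline, parameterized on a
#' normalized index axis t in \[0, 1\]:
#' `offset + slope * t + depth * exp(-(t - center)^2 / (2 * width^2))`.
#'
#' @slot peakCenter fractional peak position in \[0, 1\].
#' @slot peakWidth peak width as a fraction of the axis (> 0).
#' @slot peakDepth signed peak amplitude (negative = dip, as in phase-angle
#'   resonance curves).
#' @slot baselineSlope,baselineOffset linear baseline parameters.
#' @export
setClass("ClassModel", representation(
  peakCenter = "numeric", peakWidth = "numeric", peakDepth = "numeric",
  baselineSlope = "numeric", baselineOffset = "numeric"))

setValidity("ClassModel", function(object) {
  msg <- character()
  if (object@peakCenter < 0 || object@peakCenter > 1)
    msg <- c(msg, "peakCenter must lie in [0, 1]")
  if (object@peakWidth <= 0) msg <- c(msg, "peakWidth must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname ClassModel-class
#' @param peakCenter,peakWidth,peakDepth,baselineSlope,baselineOffset see slots.
#' @examples
#' ClassModel(peakCenter = 0.45, peakWidth = 0.08, peakDepth = -20)
#' @export
ClassModel <- function(peakCenter = 0.5, peakWidth = 0.1, peakDepth = -15,
                       baselineSlope = 0, baselineOffset = -55) {
  new("ClassModel", peakCenter = peakCenter, peakWidth = peakWidth,
      peakDepth = peakDepth, baselineSlope = baselineSlope,
      baselineOffset = baselineOffset)
}

setMethod("show", "ClassModel", function(object) {
  cat(sprintf(
    "ClassModel: center %.3f, width %.3f, depth %.2f, baseline %.2f + %.2f t\n",
    object@peakCenter, object@peakWidth, object@peakDepth,
    object@baselineOffset, object@baselineSlope))
})

#' SimConfig: synthetic spectrum simulator settings
#'
#' Defines the study conditions for the synthetic hydrogel-like spectra:
#' per-class mean-curve models, per-class sample counts, additive white noise,
#' per-spectrum peak-center jitter (experiment-to-experiment frequency-range
#' variation), and a between-class `similarity` knob (0 = classes as
#' configured, 1 = class means fully blended into the across-class average;
#' high values emulate the near-identical solution/gel curves of the
#' alpha-CD/PEG system).
#'
#' @slot length spectrum length (number of measurement indices).
#' @slot classModels named list of [ClassModel-class], one per class.
#' @slot nPerClass named integer vector of per-class counts.
#' @slot noiseSd additive Gaussian noise standard deviation.
#' @slot similarity blend weight in \[0, 1\] toward the across-class mean curve.
#' @slot jitterSd per-spectrum random shift (sd) of the peak center.
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig", representation(
  length = "integer", classModels = "list", nPerClass = "integer",
  noiseSd = "numeric", similarity = "numeric", jitterSd = "numeric",
  seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@length < 2L) msg <- c(msg, "length must be >= 2")
  if (length(object@classModels) < 2L) msg <- c(msg, "need at least 2 classes")
  if (is.null(names(object@classModels)) ||
      !identical(sort(names(object@classModels)), sort(names(object@nPerClass))))
    msg <- c(msg, "classModels and nPerClass must share the same class names")
  if (any(object@nPerClass < 1L)) msg <- c(msg, "all class counts must be >= 1")
  if (object@noiseSd < 0 || object@jitterSd < 0)
    msg <- c(msg, "noiseSd and jitterSd must be >= 0")
  if (object@similarity < 0 || object@similarity > 1)
    msg <- c(msg, "similarity must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param length,classModels,nPerClass,noiseSd,similarity,jitterSd,seed see
#'   slots. Defaults emulate a 96-well sol-gel screen: a deep narrow solution
#'   resonance dip versus a shallower, broader, shifted gel dip on a common
#'   phase-angle baseline.
#' @examples
#' cfg <- SimConfig(nPerClass = c(solution = 150, gel = 6))
#' simulateDataset(cfg)
#' @export
SimConfig <- function(length = 200L,
                      classModels = list(
                        solution = ClassModel(peakCenter = 0.42, peakWidth = 0.07,
                                              peakDepth = -22, baselineSlope = 4,
                                              baselineOffset = -58),
                        gel = ClassModel(peakCenter = 0.58, peakWidth = 0.12,
                                         peakDepth = -13, baselineSlope = 4,
                                         baselineOffset = -58)),
                      nPerClass = c(solution = 96L, gel = 96L),
                      noiseSd = 0.5, similarity = 0, jitterSd = 0.01,
                      seed = 1L) {
  np <- setNames(as.integer(nPerClass), names(nPerClass))
  new("SimConfig", length = as.integer(length), classModels = classModels,
      nPerClass = np, noiseSd = noiseSd, similarity = similarity,
      jitterSd = jitterSd, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: length %d, classes {%s}, noise sd %.3g, similarity %.2f, jitter sd %.3g, seed %d\n",
    object@length,
    paste0(names(object@nPerClass), ":", object@nPerClass, collapse = ", "),
    object@noiseSd, object@similarity, object@jitterSd, object@seed))
})

#' AugmenterSpec: oversampling settings
#'
#' @slot name augmenter identifier (e.g. `"smote"`, `"b-smote"`).
#' @slot kNeighbors number of nearest minority neighbours, in \[1, 5\].
#' @slot targetCounts named integer vector of per-class target counts.
#' @slot seed integer RNG seed.
#' @export
setClass("AugmenterSpec", representation(
  name = "character", kNeighbors = "integer", targetCounts = "integer",
  seed = "integer"))

setValidity("AugmenterSpec", function(object) {
  msg <- character()
  if (object@kNeighbors < 1L || object@kNeighbors > 5L)
    msg <- c(msg, "kNeighbors must lie in [1, 5]")
  if (length(object@targetCounts) && is.null(names(object@targetCounts)))
    msg <- c(msg, "targetCounts must be named by class")
  if (length(msg)) msg else TRUE
})

#' @rdname AugmenterSpec-class
#' @param name,kNeighbors,targetCounts,seed see slots.
#' @export
AugmenterSpec <- function(name = "smote", kNeighbors = 3L,
                          targetCounts = integer(), seed = 1L) {
  new("AugmenterSpec", name = name, kNeighbors = as.integer(kNeighbors),
      targetCounts = setNames(as.integer(targetCounts), names(targetCounts)),
      seed = as.integer(seed))
}

#' ThreePlayerConfig: architecture and training constants
#'
#' All architecture/optimizer constants of the three-player framework. The
#' defaults are the full-scale settings (length-800 spectra): Adam with
#' learning rate 2e-4 and momenta (0.5, 0.9); 150 epochs plus 100 autoencoder
#' pre-training epochs; gradient-penalty coefficient 10; 4 blocks of
#' \[Conv2D, LeakyReLU\] in the critic (kernels 64,128,128,256) and classifier
#' (32,32,128,256); 4 blocks of \[Conv2DTranspose, LeakyReLU, BatchNorm\] in
#' the generator (128,128,64,channels) ending in tanh; 4x4 kernels, stride 2,
#' same padding, random-normal init (sd 0.02), LeakyReLU slope 0.2.
#' [scaledThreePlayerConfig()] gives a desk-scale variant for short spectra.
#'
#' @slot epochs,pretrainEpochs adversarial / autoencoder pre-training epochs.
#' @slot learningRate,beta1,beta2 Adam settings shared by all three players.
#' @slot gpCoefficient gradient-penalty coefficient (lambda).
#' @slot latentDim generator latent dimension.
#' @slot embedDim class-embedding dimension for conditioning.
#' @slot batchSize minibatch size.
#' @slot leakySlope LeakyReLU negative slope.
#' @slot initSd random-normal initializer standard deviation.
#' @slot discKernels,genKernels,clfKernels per-block kernel counts (the last
#'   generator entry is the output channel count).
#' @slot kernelSize,strides 2-D kernel size and stride (same padding).
#' @slot featureDim classifier penultimate (feature) layer width.
#' @slot reshape integer (rows, cols) mapping a length-L spectrum to a 2-D
#'   grid; `c(0, 0)` means "most-square factorization of L".
#' @slot cooperativeWeight weight of the classifier cross-entropy term in the
#'   generator objective.
#' @slot nCritic critic updates per generator update.
#' @slot seed integer RNG seed.
#' @export
setClass("ThreePlayerConfig", representation(
  epochs = "integer", pretrainEpochs = "integer", learningRate = "numeric",
  beta1 = "numeric", beta2 = "numeric", gpCoefficient = "numeric",
  latentDim = "integer", embedDim = "integer", batchSize = "integer",
  leakySlope = "numeric", initSd = "numeric", discKernels = "integer",
  genKernels = "integer", clfKernels = "integer", kernelSize = "integer",
  strides = "integer", featureDim = "integer", reshape = "integer",
  cooperativeWeight = "numeric", nCritic = "integer", seed = "integer"))

setValidity("ThreePlayerConfig", function(object) {
  msg <- character()
  if (object@gpCoefficient < 0) msg <- c(msg, "gpCoefficient must be >= 0")
  if (any(c(object@epochs, object@pretrainEpochs) < 0))
    msg <- c(msg, "epoch counts must be >= 0")
  if (any(c(object@latentDim, object@embedDim, object@batchSize,
            object@featureDim, object@nCritic) < 1L))
    msg <- c(msg, "dimensions, batch size and nCritic must be positive")
  if (length(object@discKernels) != 4L || length(object@clfKernels) != 4L ||
      length(object@genKernels) != 4L)
    msg <- c(msg, "each network needs exactly 4 blocks of kernels")
  if (length(msg)) msg else TRUE
})

#' @rdname ThreePlayerConfig-class
#' @param epochs,pretrainEpochs,learningRate,beta1,beta2,gpCoefficient see slots.
#' @param latentDim,embedDim,batchSize,leakySlope,initSd see slots.
#' @param discKernels,genKernels,clfKernels,kernelSize,strides see slots.
#' @param featureDim,reshape,cooperativeWeight,nCritic,seed see slots.
#' @examples
#' ThreePlayerConfig()
#' scaledThreePlayerConfig(epochs = 40)
#' @export
ThreePlayerConfig <- function(epochs = 150L, pretrainEpochs = 100L,
                              learningRate = 2e-4, beta1 = 0.5, beta2 = 0.9,
                              gpCoefficient = 10, latentDim = 128L,
                              embedDim = 32L, batchSize = 32L,
                              leakySlope = 0.2, initSd = 0.02,
                              discKernels = c(64L, 128L, 128L, 256L),
                              genKernels = c(128L, 128L, 64L, 1L),
                              clfKernels = c(32L, 32L, 128L, 256L),
                              kernelSize = c(4L, 4L), strides = c(2L, 2L),
                              featureDim = 64L, reshape = c(0L, 0L),
                              cooperativeWeight = 1, nCritic = 1L, seed = 1L) {
  new("ThreePlayerConfig", epochs = as.integer(epochs),
      pretrainEpochs = as.integer(pretrainEpochs), learningRate = learningRate,
      beta1 = beta1, beta2 = beta2, gpCoefficient = gpCoefficient,
      latentDim = as.integer(latentDim), embedDim = as.integer(embedDim),
      batchSize = as.integer(batchSize), leakySlope = leakySlope,
      initSd = initSd, discKernels = as.integer(discKernels),
      genKernels = as.integer(genKernels), clfKernels = as.integer(clfKernels),
      kernelSize = as.integer(kernelSize), strides = as.integer(strides),
      featureDim = as.integer(featureDim), reshape = as.integer(reshape),
      cooperativeWeight = cooperativeWeight, nCritic = as.integer(nCritic),
      seed = as.integer(seed))
}

#' @describeIn ThreePlayerConfig-class desk-scale settings for short spectra
#'   (length ~100-200): same optimizer, penalty, block structure and kernel
#'   geometry as the full-scale defaults, with narrower networks and fewer
#'   epochs so a full run takes seconds on one CPU core. The initializer sd
#'   is raised to 0.1: the full-scale sd of 0.02 is variance-preserving for
#'   kernels of fan-in ~2000, and 0.1 is its equivalent at these widths
#'   (fan-in ~250), keeping activation magnitudes comparable layer to layer.
#' @param ... overrides passed on to `ThreePlayerConfig()`.
#' @export
scaledThreePlayerConfig <- function(...) {
  args <- modifyList(list(
    epochs = 40L, latentDim = 32L, embedDim = 8L, initSd = 0.1,
    discKernels = c(8L, 16L, 16L, 32L), genKernels = c(32L, 32L, 16L, 1L),
    clfKernels = c(8L, 8L, 16L, 32L), featureDim = 32L), list(...))
  do.call(ThreePlayerConfig, args)
}

setMethod("show", "ThreePlayerConfig", function(object) {
  cat(sprintf(
    paste0("ThreePlayerConfig: %d epochs (+%d pretrain), Adam(lr=%g, b1=%g, ",
           "b2=%g), lambda=%g\n  critic (%s) | generator (%s) | classifier (%s)\n",
           "  latent %d, embed %d, batch %d, cooperative weight %g, seed %d\n"),
    object@epochs, object@pretrainEpochs, object@learningRate, object@beta1,
    object@beta2, object@gpCoefficient,
    paste(object@discKernels, collapse = ","),
    paste(object@genKernels, collapse = ","),
    paste(object@clfKernels, collapse = ","),
    object@latentDim, object@embedDim, object@batchSize,
    object@cooperativeWeight, object@seed))
})

#' PlayerBundle: the three trained (or initialized) networks
#'
#' Holds the generator, discriminator (critic) and classifier plus the shared
#' training metadata (class inventory, spectrum length, 2-D reshape,
#' normalization constants, config). Access networks through
#' [generateMinority()], [extractFeatures()], [classifySpectra()] rather than
#' slots.
#'
#' @slot generator,discriminator,classifier internal network structures.
#' @slot meta list: classes, length, reshape, config, norm.
#' @export
setClass("PlayerBundle", representation(
  generator = "list", discriminator = "list", classifier = "list",
  meta = "list"))

setMethod("show", "PlayerBundle", function(object) {
  m <- object@meta
  cat(sprintf(
    "PlayerBundle: %d classes {%s}, spectrum length %d (grid %dx%d)%s\n",
    length(m$classes), paste(m$classes, collapse = ", "), m$length,
    m$reshape[1], m$reshape[2],
    if (isTRUE(m$trained)) ", trained" else ", untrained"))
})

#' LabeledSeries: phase labels along a concentration-ordered series
#'
#' @slot feature the fitted scalar summary, one value per well.
#' @slot labels factor with levels `before`/`after` (contiguous two-block
#'   structure).
#' @slot transitionIndex first index of the `after` block.
#' @slot fitDiagnostics list of fit parameters and residual sum of squares.
#' @export
setClass("LabeledSeries", representation(
  feature = "numeric", labels = "factor", transitionIndex = "integer",
  fitDiagnostics = "list"))

setValidity("LabeledSeries", function(object) {
  n <- length(object@feature)
  k <- object@transitionIndex
  lab <- as.character(object@labels)
  expect <- ifelse(seq_len(n) < k, "before", "after")
  if (length(lab) != n) return("labels and feature lengths differ")
  if (!identical(lab, expect))
    return("labels must be 'before' below transitionIndex and 'after' from it on")
  TRUE
})

setMethod("show", "LabeledSeries", function(object) {
  cat(sprintf("LabeledSeries: %d wells, transition at index %d (%d before / %d after)\n",
              length(object@feature), object@transitionIndex,
              sum(object@labels == "before"), sum(object@labels == "after")))
})

#' MetricsReport: repeated-experiment evaluation results
#'
#' @slot records data.frame with one row per (spec, method, repetition):
#'   per-class and macro precision/recall/F-score plus bookkeeping columns.
#' @slot summary data.frame of mean/sd per (method, ratio, metric).
#' @slot nRepetitions number of repetitions per cell.
#' @export
setClass("MetricsReport", representation(
  records = "data.frame", summary = "data.frame", nRepetitions = "integer"))

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport:", nrow(object@records), "repetition records,",
      object@nRepetitions, "repetitions per cell\n")
  if (nrow(object@summary)) {
    sm <- object@summary[object@summary$metric == "f_score", , drop = FALSE]
    for (i in seq_len(nrow(sm)))
      cat(sprintf("  %-16s ratio %.3f  macro F = %.3f +/- %.3f\n",
                  sm$method[i], sm$ratio[i], sm$mean[i], sm$sd[i]))
  }
})
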