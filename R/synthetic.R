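# Synthetic resonance-like phase-angle spectra: class-dependent Gaussian
# dip/peak on a linear baseline, between-class similarity blending, per-
# spectrum peak jitter (experiment-to-experiment frequency variation), and
# additive white Gaussian noise.

#' Mean curve of a spectrum class
#'
#' Evaluates `offset + slope * t + depth * exp(-(t - center)^2 / (2 width^2))`
#' at `t = i / (length - 1)`, `i = 0 .. length - 1`.
#'
#' @param model a [ClassModel-class].
#' @param length number of points (>= 2).
#' @param centerShift optional additive shift of the peak center (used for
#'   per-spectrum jitter).
#' @return numeric vector of length `length`.
#' @examples
#' plot(classMeanCurve(ClassModel(0.4, 0.08, -20), 200), type = "l")
#' @export
classMeanCurve <- function(model, length, centerShift = 0) {
  stopifnot(is(model, "ClassModel"))
  length <- as.integer(length)
  if (length < 2L) stop("length must be >= 2")
  t <- seq(0, 1, length.out = length)
  ctr <- model@peakCenter + centerShift
  model@baselineOffset + model@baselineSlope * t +
    model@peakDepth * exp(-(t - ctr)^2 / (2 * model@peakWidth^2))
}

# blended per-class curve: (1 - s) * class curve + s * across-class average,
# all curves evaluated with the same center shift
blendedCurve <- function(models, cls, length, similarity, centerShift = 0) {
  curves <- vapply(models, classMeanCurve, numeric(length), length = length,
                   centerShift = centerShift)
  (1 - similarity) * curves[, cls] + similarity * rowMeans(curves)
}

#' Simulate a labeled imbalanced spectrum dataset
#'
#' For each class, draws `nPerClass` spectra as the similarity-blended class
#' mean curve with a per-spectrum Gaussian shift of the peak center
#' (`jitterSd`) plus i.i.d. Gaussian noise (`noiseSd`). Deterministic under
#' `config@seed`.
#'
#' @param config a [SimConfig-class].
#' @return a [SpectraSet-class] with `meta_experiment` tagging and labels
#'   attached.
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  cls <- names(config@classModels)
  L <- config@length
  withSeed(deriveSeed(config@seed, "simulate"), {
    mats <- list(); labs <- character()
    for (cl in cls) {
      n <- config@nPerClass[[cl]]
      m <- matrix(0, L, n)
      for (j in seq_len(n)) {
        shift <- if (config@jitterSd > 0) rnorm(1, 0, config@jitterSd) else 0
        m[, j] <- blendedCurve(config@classModels, cl, L, config@similarity,
                               shift)
      }
      if (config@noiseSd > 0)
        m <- m + matrix(rnorm(L * n, 0, config@noiseSd), L, n)
      mats[[cl]] <- m
      labs <- c(labs, rep(cl, n))
    }
    SpectraSet(do.call(cbind, mats), labs, classes = cls)
  })
}

#' Simulate a concentration-ordered well-plate scan
#'
#' Emulates a 96-well concentration sweep through a sol-gel transition: the
#' per-well mean curve moves sigmoidally from the first class's model to the
#' second's as the well index crosses the transition, and wells at or below
#' `floor(transitionFrac * nWells)` carry the first class's label, the rest
#' the second's. The scalar summary at either class's peak center therefore
#' varies sigmoidally across wells, which is what the phase-labeling
#' procedures fit.
#'
#' @param nWells number of wells (>= 4).
#' @param transitionFrac fraction in (0, 1): the transition sits after well
#'   `floor(transitionFrac * nWells)`.
#' @param config a [SimConfig-class] (its first two classes are used;
#'   `nPerClass` is ignored).
#' @param transitionWidth sigmoid width in wells (default `nWells / 24`, i.e.
#'   gelation spread over a few wells).
#' @return list with `dataset` (a [SpectraSet-class], wells in order) and
#'   `trueTransitionIndex` (first well of the second class; labeling
#'   procedures should recover it).
#' @examples
#' scan <- simulatePlatescan(96, 0.5, SimConfig(noiseSd = 0))
#' scan$trueTransitionIndex
#' @export
simulatePlatescan <- function(nWells, transitionFrac, config,
                              transitionWidth = nWells / 24) {
  stopifnot(is(config, "SimConfig"))
  nWells <- as.integer(nWells)
  if (nWells < 4L) stop("nWells must be >= 4")
  if (transitionFrac <= 0 || transitionFrac >= 1)
    stop("transitionFrac must lie in (0, 1)")
  cls <- names(config@classModels)[1:2]
  L <- config@length
  k <- floor(transitionFrac * nWells)   # wells 1..k belong to the first class
  withSeed(deriveSeed(config@seed, "platescan"), {
    w <- 1 / (1 + exp(-((seq_len(nWells) - (k + 0.5)) / transitionWidth)))
    m <- matrix(0, L, nWells)
    for (i in seq_len(nWells)) {
      shift <- if (config@jitterSd > 0) rnorm(1, 0, config@jitterSd) else 0
      cA <- blendedCurve(config@classModels, cls[1], L, config@similarity, shift)
      cB <- blendedCurve(config@classModels, cls[2], L, config@similarity, shift)
      m[, i] <- (1 - w[i]) * cA + w[i] * cB
    }
    if (config@noiseSd > 0)
      m <- m + matrix(rnorm(L * nWells, 0, config@noiseSd), L, nWells)
    labs <- c(rep(cls[1], k), rep(cls[2], nWells - k))
    ds <- SpectraSet(m, labs, classes = cls,
                     meta = data.frame(meta_well = seq_len(nWells)))
    list(dataset = ds, trueTransitionIndex = k + 1L)
  })
}
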