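# Sampling-based oversampling baselines, implemented from their defining
# rules, plus the augmenter registry that all methods (including the
# three-player GAN) plug into.
#
# SMOTE: each synthetic sample is x_i + u * (x_nn - x_i) with u ~ U(0, 1),
# x_nn one of the k nearest minority neighbours of minority sample x_i.
# Borderline-SMOTE (variant 1): parents are restricted to DANGER samples,
# i.e. minority samples whose m-neighbourhood among ALL training samples is
# majority-dominated (m/2 <= #majority < m); interpolation stays within the
# minority class.

# Euclidean k nearest neighbours of column j among columns `pool` (self
# excluded); returns pool indices ordered by distance, ties by index.
nearestNeighbours <- function(values, j, pool, k) {
  pool <- setdiff(pool, j)
  d <- sqrt(colSums((values[, pool, drop = FALSE] - values[, j])^2))
  pool[order(d, pool)][seq_len(min(k, length(pool)))]
}

# u in [0,1]: one interpolation draw; exposed for exactness tests
smoteInterpolate <- function(xi, xnn, u) xi + u * (xnn - xi)

# shared interpolation engine: parents round-robin over `parents`, neighbours
# drawn among `neighbourPool` (minority members)
smoteEngine <- function(values, parents, neighbourPool, k, nNew) {
  out <- matrix(0, nrow(values), nNew)
  pn <- length(parents)
  for (s in seq_len(nNew)) {
    p <- parents[((s - 1L) %% pn) + 1L]
    nn <- nearestNeighbours(values, p, neighbourPool, k)
    pick <- nn[sample.int(length(nn), 1L)]
    out[, s] <- smoteInterpolate(values[, p], values[, pick], runif(1))
  }
  out
}

appendSynthetic <- function(train, newValues, newLabels, method) {
  if (ncol(newValues) == 0L) return(train)
  v <- cbind(spectraValues(train), newValues)
  cd <- SummarizedExperiment::colData(train)
  n0 <- ncol(train); n1 <- ncol(newValues)
  ids <- c(cd$id, paste0(method, "_", seq_len(n1)))
  labs <- c(spectraLabels(train), newLabels)
  gen0 <- if ("meta_generated" %in% colnames(cd)) cd$meta_generated else
    rep(FALSE, n0)
  meta <- data.frame(meta_generated = c(gen0, rep(TRUE, n1)))
  mcols <- setdiff(grep("^meta_", colnames(cd), value = TRUE), "meta_generated")
  for (mc in mcols) {
    mv <- cd[[mc]]
    fill <- if (is.numeric(mv)) NA_real_ else NA_character_
    meta[[mc]] <- c(mv, rep(fill, n1))
  }
  out <- SpectraSet(v, labs, classes = classLevels(train), meta = meta,
                    ids = ids)
  S4Vectors::metadata(out)$norm <- S4Vectors::metadata(train)$norm
  out
}

checkSmotePre <- function(counts, targets, k) {
  for (cl in names(targets)) {
    if (targets[[cl]] < counts[[cl]])
      stop("targetCounts for '", cl, "' is below the current count")
    if (targets[[cl]] > counts[[cl]]) {
      if (counts[[cl]] < 2L)
        stop("cannot interpolate: minority class '", cl, "' has fewer than 2 samples")
      if (k >= counts[[cl]])
        stop("kNeighbors (", k, ") must be smaller than the size of class '",
             cl, "' (", counts[[cl]], ")")
    }
  }
}

#' SMOTE oversampling
#'
#' Grows each class listed in `spec@targetCounts` to its target by linear
#' interpolation between a class member (parents cycle round-robin for
#' coverage) and one of its `kNeighbors` nearest same-class neighbours
#' (Euclidean distance on the value vectors). Original samples are kept
#' unmodified; synthetic samples are flagged in `meta_generated`.
#'
#' @param train a [SpectraSet-class].
#' @param spec an [AugmenterSpec-class].
#' @return the augmented `SpectraSet`, reaching `targetCounts` exactly.
#' @export
smoteOversample <- function(train, spec) {
  stopifnot(is(train, "SpectraSet"), is(spec, "AugmenterSpec"))
  validObject(spec)
  counts <- classCounts(train)
  targets <- spec@targetCounts
  checkSmotePre(counts, targets, spec@kNeighbors)
  v <- spectraValues(train)
  lab <- spectraLabels(train)
  withSeed(deriveSeed(spec@seed, "smote"), {
    newV <- NULL; newL <- character()
    for (cl in names(targets)) {
      d <- targets[[cl]] - counts[[cl]]
      if (d <= 0L) next
      members <- which(lab == cl)
      syn <- smoteEngine(v, members, members, spec@kNeighbors, d)
      newV <- if (is.null(newV)) syn else cbind(newV, syn)
      newL <- c(newL, rep(cl, d))
    }
    appendSynthetic(train, if (is.null(newV)) matrix(0, nrow(v), 0) else newV,
                    newL, "smote")
  })
}

# DANGER / safe / noise partition of one minority class: m nearest neighbours
# among ALL samples; DANGER iff m/2 <= #majority-neighbours < m
borderlineDanger <- function(values, labels, cl, m) {
  members <- which(labels == cl)
  all <- seq_len(ncol(values))
  danger <- integer()
  for (j in members) {
    nn <- nearestNeighbours(values, j, all, m)
    nMaj <- sum(labels[nn] != cl)
    if (nMaj >= m / 2 && nMaj < m) danger <- c(danger, j)
  }
  danger
}

#' Borderline-SMOTE oversampling (variant 1)
#'
#' As [smoteOversample()], but parents are restricted to the DANGER subset of
#' each minority class: samples whose `kNeighbors` nearest neighbours among
#' the whole training set are majority-dominated (at least half but not all
#' from other classes). Samples with all-majority neighbourhoods are treated
#' as noise and never parent a synthetic sample. If the DANGER set is empty
#' the call falls back to plain SMOTE with a warning.
#'
#' @inheritParams smoteOversample
#' @return the augmented `SpectraSet`.
#' @export
borderlineSmoteOversample <- function(train, spec) {
  stopifnot(is(train, "SpectraSet"), is(spec, "AugmenterSpec"))
  validObject(spec)
  counts <- classCounts(train)
  targets <- spec@targetCounts
  checkSmotePre(counts, targets, spec@kNeighbors)
  if (length(counts) < 2L) stop("need a non-empty majority class")
  v <- spectraValues(train)
  lab <- spectraLabels(train)
  withSeed(deriveSeed(spec@seed, "bsmote"), {
    newV <- NULL; newL <- character()
    for (cl in names(targets)) {
      d <- targets[[cl]] - counts[[cl]]
      if (d <= 0L) next
      members <- which(lab == cl)
      danger <- borderlineDanger(v, lab, cl, spec@kNeighbors)
      parents <- if (length(danger)) danger else {
        warning("DANGER set empty for class '", cl,
                "': falling back to plain SMOTE parents")
        members
      }
      syn <- smoteEngine(v, parents, members, spec@kNeighbors, d)
      newV <- if (is.null(newV)) syn else cbind(newV, syn)
      newL <- c(newL, rep(cl, d))
    }
    appendSynthetic(train, if (is.null(newV)) matrix(0, nrow(v), 0) else newV,
                    newL, "bsmote")
  })
}

# registry: name -> function(train, targetCounts, seed, ...) -> SpectraSet
augmenterRegistry <- new.env(parent = emptyenv())

#' Augmenter registry
#'
#' All augmentation methods are dispatched through a named registry so that
#' external methods (other GAN variants, diffusion models, ...) can plug into
#' the same evaluation harness. Built-ins: `"none"`, `"smote"`, `"b-smote"`,
#' `"threeplayer-gan"`.
#'
#' @param name augmenter identifier.
#' @param fn `function(train, targetCounts, seed, protocol)` returning an
#'   augmented [SpectraSet-class] (or, for model-based methods, an object the
#'   evaluation harness knows how to use).
#' @return `registerAugmenter` invisibly returns `name`; `listAugmenters`
#'   the registered names.
#' @export
registerAugmenter <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = augmenterRegistry)
  invisible(name)
}

#' @rdname registerAugmenter
#' @export
listAugmenters <- function() sort(ls(augmenterRegistry))

getAugmenter <- function(name) {
  if (!exists(name, envir = augmenterRegistry, inherits = FALSE))
    stop("unknown augmenter '", name, "'; registered: ",
         paste(listAugmenters(), collapse = ", "))
  get(name, envir = augmenterRegistry, inherits = FALSE)
}

#' Augment a training set to class balance
#'
#' Sets every class's target count to the majority count and dispatches to
#' the named augmenter; output class counts are all equal to the majority
#' count. An already balanced input is returned unchanged.
#'
#' @param train a [SpectraSet-class] with >= 2 classes present.
#' @param augmenter registered augmenter name (see [listAugmenters()]).
#' @param seed integer seed.
#' @param kNeighbors neighbour count for the SMOTE-family methods.
#' @return the balanced `SpectraSet`.
#' @examples
#' cfg <- SimConfig(nPerClass = c(solution = 150, gel = 4))
#' classCounts(augmentToBalance(simulateDataset(cfg), "smote", seed = 1))
#' @export
augmentToBalance <- function(train, augmenter = "smote", seed = 1L,
                             kNeighbors = 3L) {
  stopifnot(is(train, "SpectraSet"))
  counts <- classCounts(train)
  counts <- counts[counts > 0L]
  if (length(counts) < 2L) stop("train must contain at least 2 classes")
  target <- max(counts)
  if (all(counts == target)) return(train)
  fn <- getAugmenter(augmenter)
  fn(train, targetCounts = setNames(rep(target, length(counts)), names(counts)),
     seed = seed, kNeighbors = kNeighbors)
}

# built-in registrations (threeplayer-gan registers in threeplayer.R)
registerAugmenter("none", function(train, targetCounts, seed, ...) train)
registerAugmenter("smote", function(train, targetCounts, seed,
                                    kNeighbors = 3L, ...) {
  smoteOversample(train, AugmenterSpec("smote", kNeighbors, targetCounts, seed))
})
registerAugmenter("b-smote", function(train, targetCounts, seed,
                                      kNeighbors = 3L, ...) {
  borderlineSmoteOversample(
    train, AugmenterSpec("b-smote", kNeighbors, targetCounts, seed))
})
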