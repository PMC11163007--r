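# Evaluation protocol: repeated imbalanced-split experiments, per-class and
# macro precision/recall/F-score, method comparison, paired one-sided t-test
# and report export.

#' Per-class and macro precision, recall and F-score
#'
#' For each class c: precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F = 2 P R / (P + R). Macro values are the unweighted class means.
#' Zero-denominator convention: a metric with zero denominator is 0, and
#' F = 0 when P + R = 0.
#'
#' @param trueLabels,predictedLabels equal-length label vectors.
#' @param classes class inventory (defines the averaging set and order).
#' @return list with `perClass` (data.frame: class, tp, fp, fn, tn,
#'   precision, recall, f_score) and `macro` (named numeric).
#' @examples
#' computeMetrics(c("a", "a", "b"), c("a", "b", "b"), c("a", "b"))$macro
#' @export
computeMetrics <- function(trueLabels, predictedLabels, classes) {
  trueLabels <- as.character(trueLabels)
  predictedLabels <- as.character(predictedLabels)
  if (length(trueLabels) != length(predictedLabels))
    stop("label vectors must have equal length")
  if (!all(c(trueLabels, predictedLabels) %in% classes))
    stop("labels outside the class inventory")
  n <- length(trueLabels)
  per <- lapply(classes, function(cl) {
    tp <- sum(trueLabels == cl & predictedLabels == cl)
    fp <- sum(trueLabels != cl & predictedLabels == cl)
    fn <- sum(trueLabels == cl & predictedLabels != cl)
    tn <- n - tp - fp - fn
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    data.frame(class = cl, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = p, recall = r, f_score = f)
  })
  per <- do.call(rbind, per)
  list(perClass = per,
       macro = c(precision = mean(per$precision), recall = mean(per$recall),
                 f_score = mean(per$f_score)))
}

#' Paired one-sided t-test (a greater than b)
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = a - b` and the sample standard
#' deviation (n - 1 denominator); the p-value is the upper tail of Student's
#' t with n - 1 degrees of freedom (alternative: mean of `a` exceeds mean of
#' `b`).
#'
#' @param a,b equal-length numeric vectors of paired results (e.g. per-
#'   repetition F-scores of two methods).
#' @return list with `t` and `p`.
#' @export
pairedOneSidedT <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- a - b
  s <- sd(d)
  if (s == 0) stop("degenerate paired test: all differences equal")
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = pt(t, df = n - 1, lower.tail = FALSE))
}

# train + evaluate one (train, test, method) cell; returns macro + per-class
evaluateMethod <- function(train, test, method, seed, protocol) {
  cls <- classLevels(train)
  if (method == "threeplayer-gan") {
    fit <- getAugmenter(method)(train, targetCounts = NULL, seed = seed,
                                protocol = protocol)
    players <- fit$players
  } else {
    aug <- augmentToBalance(train, method, seed = seed,
                            kNeighbors = protocol$kNeighbors %||% 3L)
    cfg <- protocol$clf %||% scaledThreePlayerConfig()
    cfg@seed <- as.integer(seed)
    players <- trainClassifier(aug, cfg)
  }
  pred <- classifySpectra(players, test)$labels
  computeMetrics(spectraLabels(test), pred, cls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a repeated imbalanced-split experiment
#'
#' For every (imbalance spec, method, repetition): draw the imbalanced train
#' split with a seed derived from `baseSeed`, augment / train with the
#' method, evaluate the resulting classifier on the held-out test set, and
#' compute per-class and macro metrics. Each repetition re-draws both the
#' split and the network initialization (all deterministically from
#' `baseSeed`).
#'
#' @param dataset a [SpectraSet-class].
#' @param specs list of [ImbalanceSpec-class].
#' @param methods character vector of registered augmenter names.
#' @param nRepetitions repetitions per cell (the study protocol uses 10).
#' @param baseSeed integer root seed.
#' @param protocol list of protocol settings: `gan` (a
#'   [ThreePlayerConfig-class] for the three-player method), `clf` (config
#'   for baseline classifier training), `kNeighbors`.
#' @return a [MetricsReport-class].
#' @export
runExperiment <- function(dataset, specs, methods, nRepetitions = 10L,
                          baseSeed = 1L, protocol = list()) {
  stopifnot(is(dataset, "SpectraSet"))
  if (is(specs, "ImbalanceSpec")) specs <- list(specs)
  rows <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    for (method in methods) {
      for (rep in seq_len(nRepetitions)) {
        seed <- deriveSeed(baseSeed, "cell", si, method, rep)
        sp <- makeImbalancedSplit(dataset, spec, seed)
        m <- evaluateMethod(sp$train, sp$test, method, seed, protocol)
        rows[[length(rows) + 1L]] <- data.frame(
          spec = si, ratio = balancedRatio(spec), method = method, rep = rep,
          class = c(m$perClass$class, "MACRO"),
          precision = c(m$perClass$precision, m$macro[["precision"]]),
          recall = c(m$perClass$recall, m$macro[["recall"]]),
          f_score = c(m$perClass$f_score, m$macro[["f_score"]]))
      }
    }
  }
  records <- do.call(rbind, rows)
  mac <- records[records$class == "MACRO", , drop = FALSE]
  cells <- unique(mac[, c("method", "ratio")])
  summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- mac[mac$method == cells$method[i] & mac$ratio == cells$ratio[i], ]
    do.call(rbind, lapply(c("precision", "recall", "f_score"), function(mt)
      data.frame(method = cells$method[i], ratio = cells$ratio[i],
                 metric = mt, mean = mean(sel[[mt]]), sd = sd(sel[[mt]]),
                 n_reps = nrow(sel))))
  }))
  rownames(records) <- NULL
  rownames(summ) <- NULL
  new("MetricsReport", records = records, summary = summ,
      nRepetitions = as.integer(nRepetitions))
}

#' Export an evaluation report
#'
#' Writes `summary.csv` (columns method, ratio, metric, mean, sd, n_reps),
#' `records.json` (all per-repetition values), and optionally feature
#' matrices from [extractFeatures()] (one `features_<name>.csv` each, with
#' labels) for external 2-D embedding plots. Deterministic: re-export is
#' byte-identical.
#'
#' @param report a [MetricsReport-class].
#' @param path output directory (created if needed).
#' @param features optional named list of matrices (or of
#'   `list(features =, labels =)`).
#' @return invisibly, the paths written.
#' @export
exportReport <- function(report, path, features = NULL) {
  stopifnot(is(report, "MetricsReport"))
  if (nrow(report@records) == 0L) stop("empty report")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  sm <- report@summary
  smPath <- file.path(path, "summary.csv")
  fmt <- function(x) if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
  lines <- c(paste(colnames(sm), collapse = ","),
             vapply(seq_len(nrow(sm)), function(i)
               paste(vapply(sm[i, ], fmt, ""), collapse = ","), ""))
  con <- file(smPath, "wb"); writeLines(lines, con); close(con)
  written <- c(written, smPath)
  recPath <- file.path(path, "records.json")
  con <- file(recPath, "wb")
  writeLines(jsonlite::toJSON(report@records, digits = NA, pretty = TRUE), con)
  close(con)
  written <- c(written, recPath)
  for (nm in names(features)) {
    f <- features[[nm]]
    mat <- if (is.list(f)) f$features else f
    lab <- if (is.list(f)) f$labels else rep(NA_character_, nrow(mat))
    fp <- file.path(path, paste0("features_", nm, ".csv"))
    hdr <- paste(c("label", paste0("f", seq_len(ncol(mat)))), collapse = ",")
    body <- vapply(seq_len(nrow(mat)), function(i)
      paste(c(lab[i], sprintf("%.17g", mat[i, ])), collapse = ","), "")
    con <- file(fp, "wb"); writeLines(c(hdr, body), con); close(con)
    written <- c(written, fp)
  }
  invisible(written)
}
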