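# File I/O, preprocessing and imbalanced splitting for labeled 1-D spectra.
# Native format: UTF-8 delimited text, header id,label,v1,...,vL (+ optional
# meta_* columns), one spectrum per row, L fixed per file.

# run expr with a locally seeded RNG, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# deterministic 31-bit substream seed derived from a root seed and a tag
deriveSeed <- function(seed, ...) {
  parts <- c(as.character(seed), vapply(list(...), as.character, ""))
  h <- 0
  for (ch in utf8ToInt(paste(parts, collapse = "/")))
    h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Read labeled spectra from a delimited text file
#'
#' Reads the native spectra format: header `id,label,v1,...,vL` plus optional
#' `meta_*` columns, one spectrum per row. All spectra in a file share the
#' same length L.
#'
#' @param path file to read.
#' @param sep field delimiter (default comma).
#' @return a [SpectraSet-class].
#' @seealso [writeSpectra()]
#' @export
readSpectra <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- tryCatch(
    data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                      colClasses = list(character = c("id", "label"))),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  if (nrow(dt) == 0L) stop("no spectra in ", path)
  need <- c("id", "label")
  if (!all(need %in% colnames(dt)))
    stop("missing required columns: ", paste(setdiff(need, colnames(dt)),
                                             collapse = ", "))
  vcols <- grep("^v[0-9]+$", colnames(dt), value = TRUE)
  if (length(vcols) == 0L) stop("no value columns (v1, v2, ...) in ", path)
  vcols <- vcols[order(as.integer(sub("^v", "", vcols)))]
  vals <- as.matrix(dt[, vcols, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(dt[, vcols, drop = FALSE], is.numeric, TRUE))
    badrow <- which(is.na(suppressWarnings(as.numeric(dt[[vcols[bad[1]]]]))))[1]
    stop("non-numeric value in row ", badrow, ", column ", vcols[bad[1]])
  }
  if (anyNA(vals)) {
    badrow <- which(rowSums(is.na(vals)) > 0)[1]
    stop("parse error: missing/non-numeric value in row ", badrow)
  }
  mcols <- grep("^meta_", colnames(dt), value = TRUE)
  meta <- if (length(mcols)) dt[, mcols, drop = FALSE] else NULL
  dimnames(vals) <- NULL
  SpectraSet(t(vals), labels = dt$label, meta = meta, ids = dt$id)
}

#' Write labeled spectra to a delimited text file
#'
#' Values are serialized at full double precision (`%.17g`), so
#' write-read-write round-trips are byte-identical.
#'
#' @param x a [SpectraSet-class].
#' @param path output file.
#' @param sep field delimiter.
#' @export
writeSpectra <- function(x, path, sep = ",") {
  stopifnot(is(x, "SpectraSet"))
  validObject(x)
  v <- spectraValues(x)
  cd <- SummarizedExperiment::colData(x)
  mcols <- grep("^meta_", colnames(cd), value = TRUE)
  header <- c("id", "label", paste0("v", seq_len(nrow(v))), mcols)
  fmtNum <- function(z) sprintf("%.17g", z)
  lines <- vapply(seq_len(ncol(v)), function(j) {
    fields <- c(cd$id[j], cd$label[j], fmtNum(v[, j]))
    for (mc in mcols) {
      mv <- cd[[mc]][j]
      fields <- c(fields, if (is.numeric(mv)) fmtNum(mv) else as.character(mv))
    }
    paste(fields, collapse = sep)
  }, "")
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot write ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(paste(header, collapse = sep), lines), con)
  invisible(NULL)
}

#' Convert a frequency axis to a sequence index axis
#'
#' Repeated plate scans use different sensors and frequency windows, so raw
#' spectra are not comparable on a shared Hz axis. Following the standard
#' preprocessing for such data, the frequency axis is discarded and values are
#' re-indexed 1..N by measurement order; the original range is recorded.
#'
#' @param values numeric vector of measurements.
#' @param frequencies strictly increasing numeric vector (Hz), same length.
#' @return `values` unchanged, with attribute `freqRange = c(min, max)` and
#'   `index = 1:N`.
#' @examples
#' v <- toSequenceIndex(rnorm(5), seq(26013.75, 37000, length.out = 5))
#' attr(v, "freqRange")
#' @export
toSequenceIndex <- function(values, frequencies) {
  if (length(values) != length(frequencies))
    stop("values and frequencies must have equal length")
  if (length(frequencies) > 1L && any(diff(frequencies) <= 0))
    stop("frequencies must be strictly increasing")
  out <- as.numeric(values)
  attr(out, "freqRange") <- range(frequencies)
  attr(out, "index") <- seq_along(out)
  out
}

#' Min-max normalize a SpectraSet
#'
#' Affinely maps the global dataset minimum to `lo` and maximum to `hi`
#' (default \[-1, 1\], matching the generator's bounded tanh output). The
#' constants are stored in `metadata(x)$norm` for exact inversion, and can be
#' supplied (`constants`) to apply a training split's normalization to test
#' data without leakage.
#'
#' @param x a [SpectraSet-class].
#' @param lo,hi target range.
#' @param constants optional list with `min`/`max` (e.g. the `norm` metadata of
#'   an already-normalized training set).
#' @return the normalized `SpectraSet`.
#' @seealso [denormalize()]
#' @export
normalizeMinmax <- function(x, lo = -1, hi = 1, constants = NULL) {
  stopifnot(is(x, "SpectraSet"), lo < hi)
  v <- spectraValues(x)
  mn <- if (!is.null(constants)) constants$min else min(v)
  mx <- if (!is.null(constants)) constants$max else max(v)
  if (mx == mn) {
    warning("constant dataset: mapping all values to (lo + hi) / 2")
    vn <- matrix((lo + hi) / 2, nrow(v), ncol(v), dimnames = dimnames(v))
  } else {
    vn <- lo + (v - mn) * (hi - lo) / (mx - mn)
  }
  SummarizedExperiment::assay(x, "spectra") <- vn
  S4Vectors::metadata(x)$norm <- list(lo = lo, hi = hi, min = mn, max = mx)
  x
}

#' @describeIn normalizeMinmax invert a previous [normalizeMinmax()] using the
#'   stored constants.
#' @export
denormalize <- function(x) {
  stopifnot(is(x, "SpectraSet"))
  nm <- S4Vectors::metadata(x)$norm
  if (is.null(nm)) stop("no normalization constants stored in metadata()$norm")
  v <- spectraValues(x)
  if (nm$max == nm$min) {
    vo <- matrix(nm$min, nrow(v), ncol(v), dimnames = dimnames(v))
  } else {
    vo <- nm$min + (v - nm$lo) * (nm$max - nm$min) / (nm$hi - nm$lo)
  }
  SummarizedExperiment::assay(x, "spectra") <- vo
  S4Vectors::metadata(x)$norm <- NULL
  x
}

#' Resample spectra to a new length by linear interpolation
#'
#' Interpolates each spectrum onto `targetLength` equally spaced points over
#' its original index range (endpoints preserved). Supports desk-scale runs
#' shorter than the instrument's native length.
#'
#' @param x a [SpectraSet-class] or a numeric vector.
#' @param targetLength new length (>= 2).
#' @return object of the same kind as `x`.
#' @export
setGeneric("resampleLength", function(x, targetLength)
  standardGeneric("resampleLength"))

#' @rdname resampleLength
setMethod("resampleLength", "numeric", function(x, targetLength) {
  targetLength <- as.integer(targetLength)
  if (targetLength < 2L) stop("targetLength must be >= 2")
  if (targetLength == length(x)) return(as.numeric(x))
  approx(x = seq_along(x), y = x,
         xout = seq(1, length(x), length.out = targetLength))$y
})

#' @rdname resampleLength
setMethod("resampleLength", "SpectraSet", function(x, targetLength) {
  v <- spectraValues(x)
  vn <- apply(v, 2, resampleLength, targetLength = targetLength)
  cd <- SummarizedExperiment::colData(x)
  mcols <- grep("^meta_", colnames(cd), value = TRUE)
  meta <- if (length(mcols)) as.data.frame(cd[, mcols, drop = FALSE]) else NULL
  out <- SpectraSet(vn, spectraLabels(x), classes = classLevels(x),
                    meta = meta, ids = cd$id)
  S4Vectors::metadata(out)$norm <- S4Vectors::metadata(x)$norm
  out
})

#' Draw an imbalanced training split
#'
#' Stratified simple random sampling without replacement: exactly
#' `spec@majorityN` majority and `spec@minorityN` minority spectra go to the
#' training set; all remaining spectra form the test set. Deterministic for a
#' given `(x, spec, seed)`.
#'
#' @param x a [SpectraSet-class].
#' @param spec an [ImbalanceSpec-class].
#' @param seed integer seed.
#' @return list with elements `train`, `test` (both `SpectraSet`) and
#'   `realized` (the realized [ImbalanceSpec-class]).
#' @examples
#' cfg <- SimConfig(nPerClass = c(solution = 181, gel = 107))
#' ds <- simulateDataset(cfg)
#' sp <- makeImbalancedSplit(ds, ImbalanceSpec("solution", "gel", 150, 4), 1)
#' balancedRatio(sp$realized)
#' @export
makeImbalancedSplit <- function(x, spec, seed = 1L) {
  stopifnot(is(x, "SpectraSet"), is(spec, "ImbalanceSpec"))
  validObject(spec)
  lab <- spectraLabels(x)
  need <- setNames(c(spec@majorityN, spec@minorityN),
                   c(spec@majorityClass, spec@minorityClass))
  for (cl in names(need)) {
    have <- sum(lab == cl)
    if (have < need[[cl]])
      stop("class '", cl, "' has ", have, " spectra but ", need[[cl]],
           " are requested")
  }
  idx <- withSeed(deriveSeed(seed, "split"), {
    unlist(lapply(names(need), function(cl)
      sort(sample(which(lab == cl), need[[cl]]))), use.names = FALSE)
  })
  idx <- sort(idx)
  train <- x[, idx]
  test <- x[, setdiff(seq_len(ncol(x)), idx)]
  S4Vectors::metadata(train)$classes <- classLevels(x)
  S4Vectors::metadata(test)$classes <- classLevels(x)
  list(train = new("SpectraSet", train), test = new("SpectraSet", test),
       realized = ImbalanceSpec(spec@majorityClass, spec@minorityClass,
                                sum(spectraLabels(train) == spec@majorityClass),
                                sum(spectraLabels(train) == spec@minorityClass)))
}
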