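# Phase labeling along a concentration-ordered series of spectra:
#  - sigmoid (4PL) inflection labeling, as used for thermogelling systems;
#  - two-segment linear regression intersection labeling, as used when the
#    feature-vs-concentration relation shows a slope break instead of a step.

#' Scalar summary feature per spectrum
#'
#' Reduces each spectrum of a concentration-ordered set to one scalar, the
#' series the labeling procedures fit. Which scalar best tracks gelation is
#' instrument-dependent, so the reducer is selectable; `"at"` (value at a
#' fixed measurement index, typically the resonance peak) is the default.
#'
#' @param x a [SpectraSet-class], ordered by concentration.
#' @param reducer one of `"at"`, `"min"`, `"max"`, `"mean"`.
#' @param index measurement index for `reducer = "at"`.
#' @return numeric vector, one value per spectrum, order preserved.
#' @export
seriesFeature <- function(x, reducer = c("at", "min", "max", "mean"),
                          index = NULL) {
  stopifnot(is(x, "SpectraSet"))
  if (nSpectra(x) == 0L) stop("empty dataset")
  reducer <- match.arg(reducer)
  v <- spectraValues(x)
  switch(reducer,
    at = {
      if (is.null(index)) stop("reducer 'at' needs an index")
      index <- as.integer(index)
      if (index < 1L || index > nrow(v)) stop("index out of range")
      v[index, ]
    },
    min = apply(v, 2, min),
    max = apply(v, 2, max),
    mean = colMeans(v))
}

labeledSeries <- function(feature, transitionIndex, diagnostics) {
  n <- length(feature)
  k <- as.integer(transitionIndex)
  labs <- factor(ifelse(seq_len(n) < k, "before", "after"),
                 levels = c("before", "after"))
  new("LabeledSeries", feature = as.numeric(feature), labels = labs,
      transitionIndex = k, fitDiagnostics = diagnostics)
}

#' Label a series by sigmoid (4PL) inflection
#'
#' Fits the 4-parameter logistic `f(x) = a + (b - a) / (1 + exp(-(x - x0)/s))`
#' to `(index, feature)` by least squares. Wells before the inflection `x0`
#' are labeled `before` (solution), wells from the first index beyond `x0` on
#' are labeled `after` (gel). Initialization: `a`, `b` from the edge means,
#' `x0` at the steepest finite difference, `s = n / 10`, with up to 5 jittered
#' restarts.
#'
#' @param feature numeric series (length >= 5).
#' @return a [LabeledSeries-class]; `fitDiagnostics` holds `a`, `b`, `x0`,
#'   `s` and the residual sum of squares.
#' @examples
#' f <- 1 / (1 + exp(-(1:96 - 48.5) / 3))
#' labelBySigmoidInflection(f)
#' @export
labelBySigmoidInflection <- function(feature) {
  feature <- as.numeric(feature)
  n <- length(feature)
  if (n < 5L) stop("need at least 5 points")
  if (sd(feature) == 0)
    stop("constant feature: sigmoid fit is non-identifiable")
  idx <- seq_len(n)
  a0 <- mean(head(feature, 3)); b0 <- mean(tail(feature, 3))
  d <- diff(feature)
  x00 <- which.max(abs(d)) + 0.5
  s0 <- n / 10
  df <- data.frame(x = idx, y = feature)
  fit <- NULL
  start <- list(a = a0, b = b0, x0 = x00, s = s0)
  for (try in 0:5) {
    st <- if (try == 0) start else
      withSeed(deriveSeed(1000 + try, "sigfit"), list(
        a = a0 * (1 + rnorm(1, 0, 0.1)) + rnorm(1, 0, 0.05),
        b = b0 * (1 + rnorm(1, 0, 0.1)) + rnorm(1, 0, 0.05),
        x0 = x00 + rnorm(1, 0, n / 10), s = s0 * exp(rnorm(1, 0, 0.5))))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a + (b - a) / (1 + exp(-(x - x0) / s)),
                        data = df, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("sigmoid fit did not converge after restarts (start: a=", a0,
         ", b=", b0, ", x0=", x00, ", s=", s0, ")")
  p <- as.list(coef(fit))
  rss <- sum(residuals(fit)^2)
  k <- floor(p$x0) + 1L              # smallest index strictly above x0
  k <- max(1L, min(n + 1L, k))
  labeledSeries(feature, k, list(a = p$a, b = p$b, x0 = p$x0, s = p$s,
                                 rss = rss, method = "sigmoid"))
}

# OLS fit of y ~ x on a contiguous index window; returns (intercept, slope, rss)
olsSegment <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  beta <- if (sxx == 0) 0 else sum((x - xb) * (y - yb)) / sxx
  alpha <- yb - beta * xb
  res <- y - alpha - beta * x
  c(alpha = alpha, beta = beta, rss = sum(res^2))
}

#' Label a series by two-segment regression intersection
#'
#' For each candidate breakpoint `k` (both sides keeping >= 3 points), fits
#' ordinary least-squares lines to points `1..k` and `k+1..n` and picks the
#' `k` minimizing total RSS (ties broken to the smallest `k`). The transition
#' index is the intersection point of the two best-fit lines, rounded up:
#' wells before it are `before` (solution), the intersection well and later
#' are `after` (gel). If the lines are (near-)parallel, or cross away from
#' the breakpoint where the two segments meet (as happens for plateau-like
#' segments with tiny slopes), the procedure falls back to `k + 1` with a
#' warning.
#'
#' @param feature numeric series (length >= 6).
#' @return a [LabeledSeries-class]; `fitDiagnostics` holds the breakpoint,
#'   both line fits, the intersection abscissa and the total RSS.
#' @examples
#' labelByTwoLineIntersection(abs(1:100 - 50))
#' @export
labelByTwoLineIntersection <- function(feature) {
  feature <- as.numeric(feature)
  n <- length(feature)
  if (n < 6L) stop("need at least 6 points")
  idx <- seq_len(n)
  ks <- 3:(n - 3)
  best <- NULL
  for (k in ks) {
    l <- olsSegment(idx[1:k], feature[1:k])
    r <- olsSegment(idx[(k + 1):n], feature[(k + 1):n])
    tot <- l[["rss"]] + r[["rss"]]
    if (is.null(best) || tot < best$tot - 1e-12) best <- list(k = k, l = l,
                                                             r = r, tot = tot)
  }
  dbeta <- best$l[["beta"]] - best$r[["beta"]]
  xint <- if (abs(dbeta) < 1e-10) NA_real_ else
    (best$r[["alpha"]] - best$l[["alpha"]]) / dbeta
  # the crossing is only meaningful where the two segments meet; plateau-like
  # segments have near-equal slopes whose intersection can land far away
  if (is.na(xint) || xint < best$k - 2 || xint > best$k + 3) {
    warning("best-fit lines do not intersect near the breakpoint; ",
            "falling back to the breakpoint")
    k <- best$k + 1L
    xint <- NA_real_
  } else {
    k <- as.integer(ceiling(xint - 1e-9))   # guard exact-hit float noise
  }
  labeledSeries(feature, k, list(
    breakpoint = best$k, leftFit = as.list(best$l), rightFit = as.list(best$r),
    intersection = xint, rss = best$tot, method = "two-line"))
}
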