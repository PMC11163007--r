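# independent oracles used to validate the implementation paths

# brute-force 'same'-padded strided 2-D convolution (nested loops)
naiveConv2d <- function(X, W, b, inR, inC, Cin, Cout, kh = 4, kw = 4,
                        sh = 2, sw = 2) {
  n <- nrow(X)
  outR <- ceiling(inR / sh); outC <- ceiling(inC / sw)
  padTop <- max((outR - 1) * sh + kh - inR, 0) %/% 2
  padLeft <- max((outC - 1) * sw + kw - inC, 0) %/% 2
  out <- matrix(0, n, outR * outC * Cout)
  for (s in seq_len(n)) {
    for (orow in seq_len(outR)) for (ocol in seq_len(outC))
      for (co in seq_len(Cout)) {
        acc <- b[co]
        for (i in seq_len(kh)) for (j in seq_len(kw))
          for (ci in seq_len(Cin)) {
            r <- (orow - 1) * sh + i - padTop
            cc <- (ocol - 1) * sw + j - padLeft
            if (r >= 1 && r <= inR && cc >= 1 && cc <= inC) {
              p <- (r - 1) * inC + cc
              k <- (i - 1) * kw + j
              acc <- acc + X[s, (p - 1) * Cin + ci] * W[(k - 1) * Cin + ci, co]
            }
          }
        out[s, ((orow - 1) * outC + ocol - 1) * Cout + co] <- acc
      }
  }
  out
}

# brute-force confusion-matrix metrics (independent counting loop)
oracleMetrics <- function(truth, pred, classes) {
  per <- sapply(classes, function(cl) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(truth)) {
      if (truth[i] == cl && pred[i] == cl) tp <- tp + 1
      if (truth[i] != cl && pred[i] == cl) fp <- fp + 1
      if (truth[i] == cl && pred[i] != cl) fn <- fn + 1
    }
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p = p, r = r, f = f)
  })
  list(precision = mean(per["p", ]), recall = mean(per["r", ]),
       f_score = mean(per["f", ]))
}

# all-pairs Euclidean k nearest neighbours (columns of `values`)
oracleKnn <- function(values, j, pool, k) {
  pool <- setdiff(pool, j)
  d <- apply(values[, pool, drop = FALSE], 2,
             function(v) sqrt(sum((v - values[, j])^2)))
  pool[order(d, pool)][seq_len(k)]
}

# grid-refined 4PL fit oracle: coarse grid over (x0, s), closed-form (a, b)
# by linear least squares given the logistic shape
oracleSigmoidX0 <- function(y) {
  n <- length(y); x <- seq_len(n)
  best <- NULL
  for (x0 in seq(2, n - 1, by = 0.25)) for (s in c(0.5, 1, 2, 4, 8, 16)) {
    g <- 1 / (1 + exp(-(x - x0) / s))
    fit <- lm(y ~ g)
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(x0 = x0, rss = rss)
  }
  best$x0
}

# central finite-difference gradient of f at x
fdGrad <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
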