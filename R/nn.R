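# Minimal convolutional network engine for the three-player framework.
#
# There is no deep-learning framework dependency: the networks ARE the
# method, and they are small enough that base-R matrix algebra (im2col
# convolutions) trains them in seconds at desk scale. Everything here is
# internal; the public surface lives in threeplayer.R.
#
# Batch layout: a batch is a matrix X (n x P*C), one sample per row, with
# flat feature index q = (p - 1) * C + c, where p is the row-major spatial
# position on the (rows x cols) grid and c the channel.
#
# Gradient penalty: the critic is a chain of linear maps and LeakyReLU, hence
# piecewise linear in its input. With activation masks frozen (they are
# constant almost everywhere), the input gradient g = grad_x D(x) is an
# explicit linear form in the weights, and the exact parameter gradient of
# the penalty lambda * mean((||g|| - 1)^2) follows from one extra
# forward-style pass:
#   backward pass:  u_k = grad wrt h_k,  q_k = mask_k * u_k,  g = u_0
#   r = dPenalty/dg,  v_0 = r,  v_k = mask_k * (A_k v_{k-1})
#   dPenalty/dA_k = q_k (x) v_{k-1}   (conv weight-gradient pairing)
#   dPenalty/dw_out(trunk part) = v_L;  biases and embeddings get zero.
# This is verified against finite differences in the test suite.

# ---- layout helpers ---------------------------------------------------------

# (n x P*C) -> (n*P x C), rows ordered sample-fastest
toMat <- function(X, n, P, C)
  matrix(aperm(array(X, c(n, C, P)), c(1, 3, 2)), n * P, C)

# (n*P x C) -> (n x P*C)
fromMat <- function(M, n, P, C)
  matrix(aperm(array(M, c(n, P, C)), c(1, 3, 2)), n, P * C)

initMat <- function(nr, nc, sd) matrix(rnorm(nr * nc, 0, sd), nr, nc)

# ---- convolution geometry ---------------------------------------------------

# 'same' padding geometry mapping (inR, inC) -> (ceil(inR/sh), ceil(inC/sw));
# pos[op, k] is the input spatial position read by output position op at
# kernel offset k (0 = zero padding)
convGeom <- function(inR, inC, kh, kw, sh, sw) {
  outR <- ceiling(inR / sh); outC <- ceiling(inC / sw)
  padTop <- max((outR - 1) * sh + kh - inR, 0) %/% 2
  padLeft <- max((outC - 1) * sw + kw - inC, 0) %/% 2
  nOut <- outR * outC; K <- kh * kw
  pos <- matrix(0L, nOut, K)
  for (orow in seq_len(outR)) for (ocol in seq_len(outC)) {
    op <- (orow - 1L) * outC + ocol
    for (i in seq_len(kh)) for (j in seq_len(kw)) {
      r <- (orow - 1L) * sh + i - padTop
      cc <- (ocol - 1L) * sw + j - padLeft
      if (r >= 1L && r <= inR && cc >= 1L && cc <= inC)
        pos[op, (i - 1L) * kw + j] <- (r - 1L) * inC + cc
    }
  }
  list(inR = inR, inC = inC, outR = outR, outC = outC, nOut = nOut,
       K = K, pos = pos, Pin = inR * inC)
}

# conv layer: geometry + channel bookkeeping + precomputed gather/scatter maps
convLayer <- function(inR, inC, Cin, Cout, kh = 4L, kw = 4L, sh = 2L, sw = 2L) {
  g <- convGeom(inR, inC, kh, kw, sh, sw)
  KC <- g$K * Cin
  colIdx <- integer(g$nOut * KC); pad <- logical(g$nOut * KC)
  q <- 0L
  for (op in seq_len(g$nOut)) for (k in seq_len(g$K)) {
    p <- g$pos[op, k]
    for (c in seq_len(Cin)) {
      q <- q + 1L
      if (p > 0L) colIdx[q] <- (p - 1L) * Cin + c else { colIdx[q] <- 1L
        pad[q] <- TRUE }
    }
  }
  ops <- vector("list", g$K); ps <- vector("list", g$K)
  for (k in seq_len(g$K)) {
    sel <- which(g$pos[, k] > 0L)
    ops[[k]] <- sel; ps[[k]] <- g$pos[sel, k]
  }
  c(g, list(Cin = Cin, Cout = Cout, KC = KC, colIdx = colIdx,
            padCols = which(pad), ops = ops, ps = ps))
}

convIm2col <- function(ly, X) {
  n <- nrow(X)
  A <- X[, ly$colIdx, drop = FALSE]
  if (length(ly$padCols)) A[, ly$padCols] <- 0
  matrix(aperm(array(A, c(n, ly$KC, ly$nOut)), c(1, 3, 2)), n * ly$nOut, ly$KC)
}

# scatter-add adjoint of convIm2col: (n*nOut x KC) -> (n x Pin*Cin)
convScatter <- function(ly, dM) {
  n <- nrow(dM) %/% ly$nOut
  dM3 <- array(dM, c(n, ly$nOut, ly$KC))
  arr <- array(0, c(n, ly$Pin, ly$Cin))
  for (k in seq_len(ly$K)) {
    sel <- ly$ops[[k]]
    if (!length(sel)) next
    cols <- ((k - 1L) * ly$Cin + 1L):(k * ly$Cin)
    arr[, ly$ps[[k]], ] <- arr[, ly$ps[[k]], , drop = FALSE] +
      dM3[, sel, cols, drop = FALSE]
  }
  matrix(aperm(arr, c(1, 3, 2)), n, ly$Pin * ly$Cin)
}

# forward: returns output (n x nOut*Cout) and the im2col cache
convForward <- function(ly, W, b, X, bias = TRUE) {
  n <- nrow(X)
  M <- convIm2col(ly, X)
  Y <- M %*% W
  if (bias) Y <- Y + rep(b, each = nrow(Y))
  list(out = fromMat(Y, n, ly$nOut, ly$Cout), M = M)
}

# backward: weight/bias grads and input grad
convBackward <- function(ly, W, M, dOut, wantInput = TRUE) {
  n <- nrow(dOut)
  dY <- toMat(dOut, n, ly$nOut, ly$Cout)
  list(dW = crossprod(M, dY), db = colSums(dY),
       dX = if (wantInput) convScatter(ly, tcrossprod(dY, W)) else NULL)
}

# input grad only (frozen weights)
convBackwardData <- function(ly, W, dOut) {
  n <- nrow(dOut)
  convScatter(ly, tcrossprod(toMat(dOut, n, ly$nOut, ly$Cout), W))
}

# linear forward without bias (gradient-penalty v-propagation)
convForwardLin <- function(ly, W, V) {
  n <- nrow(V)
  fromMat(convIm2col(ly, V) %*% W, n, ly$nOut, ly$Cout)
}

# weight grad of a bilinear pairing <Q, conv(V)> (gradient penalty)
convWeightGrad <- function(ly, V, Q) {
  n <- nrow(V)
  crossprod(convIm2col(ly, V), toMat(Q, n, ly$nOut, ly$Cout))
}

# ---- transposed convolution -------------------------------------------------

# convT maps the small grid (inR, inC, Cin) up to (inR*sh, inC*sw, Cout); it
# is the exact adjoint of a stride-(sh, sw) 'same' conv big -> small with
# weight W of shape (K*Cout x Cin)
convTLayer <- function(inR, inC, Cin, Cout, kh = 4L, kw = 4L,
                       sh = 2L, sw = 2L) {
  big <- convLayer(inR * sh, inC * sw, Cout, Cin, kh, kw, sh, sw)
  stopifnot(big$nOut == inR * inC)
  list(rev = big, Cin = Cin, Cout = Cout, Pin = inR * inC,
       Pout = big$Pin, outR = inR * sh, outC = inC * sw)
}

convTForward <- function(ly, W, b, Xs) {
  n <- nrow(Xs)
  Xm <- toMat(Xs, n, ly$Pin, ly$Cin)          # (n*Psmall x Cin)
  big <- convScatter(ly$rev, tcrossprod(Xm, W))
  big <- big + matrix(rep(b, ly$Pout), n, ly$Pout * ly$Cout, byrow = TRUE)
  list(out = big, Xm = Xm)
}

convTBackward <- function(ly, W, Xm, dBig, wantInput = TRUE) {
  n <- nrow(dBig)
  Mb <- convIm2col(ly$rev, dBig)              # (n*Psmall x K*Cout)
  dW <- crossprod(Mb, Xm)
  db <- colSums(toMat(dBig, n, ly$Pout, ly$Cout))
  dXs <- if (wantInput) fromMat(Mb %*% W, n, ly$Pin, ly$Cin) else NULL
  list(dW = dW, db = db, dX = dXs)
}

# ---- batch normalization (per channel over batch x spatial) ----------------

bnForward <- function(P, C, gamma, beta, X, state, train, momentum = 0.99,
                      eps = 1e-5) {
  n <- nrow(X)
  M <- toMat(X, n, P, C)
  if (train) {
    mu <- colMeans(M)
    va <- colMeans(M * M) - mu * mu
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * va
  } else {
    mu <- state$mean; va <- state$var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (M - rep(mu, each = n * P)) * rep(istd, each = n * P)
  Y <- xhat * rep(gamma, each = n * P) + rep(beta, each = n * P)
  list(out = fromMat(Y, n, P, C), xhat = xhat, istd = istd, state = state,
       train = train)
}

bnBackward <- function(P, C, gamma, cache, dOut) {
  n <- nrow(dOut)
  m <- n * P
  dY <- toMat(dOut, n, P, C)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  gi <- rep(gamma * cache$istd, each = m)
  dX <- if (isTRUE(cache$train)) {
    # batch statistics participate in the forward pass
    gi / m * (m * dY - rep(dbeta, each = m) -
                cache$xhat * rep(dgamma, each = m))
  } else {
    gi * dY   # frozen statistics: plain per-channel affine map
  }
  list(dX = fromMat(dX, n, P, C), dgamma = dgamma, dbeta = dbeta)
}

# ---- activations, losses ----------------------------------------------------

leakyMask <- function(Z, slope) ifelse(Z > 0, 1, slope)

softmaxProbs <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy on integer class indices; dLogits is d(mean loss)/d logits
ceLossGrad <- function(logits, yIdx) {
  n <- nrow(logits)
  probs <- softmaxProbs(logits)
  py <- probs[cbind(seq_len(n), yIdx)]
  loss <- -mean(log(pmax(py, 1e-12)))
  dL <- probs
  dL[cbind(seq_len(n), yIdx)] <- dL[cbind(seq_len(n), yIdx)] - 1
  list(loss = loss, dLogits = dL / n, probs = probs)
}

# ---- Adam -------------------------------------------------------------------

adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adamStep <- function(params, grads, st, lr, b1, b2, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(params = params, state = st)
}

addGrads <- function(a, b) {
  for (nm in names(b)) {
    if (is.null(b[[nm]])) next
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

# ---- the three networks -----------------------------------------------------

# conv trunk shared by critic and classifier: 4 x [conv (4,4) stride (2,2)
# same, LeakyReLU]
buildTrunk <- function(rows, cols, kernels, cfg) {
  chans <- c(1L, kernels)
  layers <- vector("list", 4L)
  r <- rows; cc <- cols
  for (i in 1:4) {
    layers[[i]] <- convLayer(r, cc, chans[i], chans[i + 1],
                             cfg@kernelSize[1], cfg@kernelSize[2],
                             cfg@strides[1], cfg@strides[2])
    r <- layers[[i]]$outR; cc <- layers[[i]]$outC
  }
  list(layers = layers, outDim = r * cc * kernels[4])
}

trunkInitParams <- function(trunk, cfg, prefix) {
  p <- list()
  for (i in 1:4) {
    ly <- trunk$layers[[i]]
    p[[paste0(prefix, i, ".W")]] <- initMat(ly$KC, ly$Cout, cfg@initSd)
    p[[paste0(prefix, i, ".b")]] <- numeric(ly$Cout)
  }
  p
}

trunkForward <- function(trunk, params, prefix, X, slope) {
  h <- X; caches <- vector("list", 4L)
  for (i in 1:4) {
    ly <- trunk$layers[[i]]
    cf <- convForward(ly, params[[paste0(prefix, i, ".W")]],
                      params[[paste0(prefix, i, ".b")]], h)
    mask <- leakyMask(cf$out, slope)
    h <- cf$out * mask
    caches[[i]] <- list(M = cf$M, mask = mask)
  }
  list(h = h, caches = caches)
}

# backward through the trunk; dh = grad wrt trunk output; collects weight
# grads (unless paramsOff) and optionally the input grad
trunkBackward <- function(trunk, params, prefix, caches, dh,
                          wantParams = TRUE, wantInput = TRUE) {
  grads <- list()
  for (i in 4:1) {
    ly <- trunk$layers[[i]]
    dz <- dh * caches[[i]]$mask
    needIn <- wantInput || i > 1L
    if (wantParams) {
      bk <- convBackward(ly, params[[paste0(prefix, i, ".W")]],
                         caches[[i]]$M, dz, wantInput = needIn)
      grads[[paste0(prefix, i, ".W")]] <- bk$dW
      grads[[paste0(prefix, i, ".b")]] <- bk$db
      dh <- bk$dX
    } else {
      dh <- if (needIn)
        convBackwardData(ly, params[[paste0(prefix, i, ".W")]], dz) else NULL
    }
  }
  list(grads = grads, dX = dh)
}

# projection-conditional critic: score(x, y) = b + w . h(x) + <emb[y], h(x)>
# with h the conv-trunk features. The label interacts multiplicatively with
# the features, so the critic can penalize realistic-but-wrong-class samples
# (a purely additive f(x) + g(y) score cannot, which degenerates the
# conditional game into an unconditional one dominated by the majority
# class). Still piecewise linear in x, so the penalty gradients stay exact.
buildCritic <- function(cfg, nClasses, rows, cols) {
  trunk <- buildTrunk(rows, cols, cfg@discKernels, cfg)
  params <- trunkInitParams(trunk, cfg, "c")
  params$emb <- initMat(nClasses, trunk$outDim, cfg@initSd)
  params[["out.W"]] <- initMat(trunk$outDim, 1L, cfg@initSd)
  params[["out.b"]] <- 0
  list(kind = "critic", trunk = trunk, params = params,
       slope = cfg@leakySlope, nClasses = nClasses,
       adam = adamInit(params))
}

criticForward <- function(D, X, yIdx) {
  tf <- trunkForward(D$trunk, D$params, "c", X, D$slope)
  e <- D$params$emb[yIdx, , drop = FALSE]
  score <- as.numeric(tf$h %*% D$params[["out.W"]]) +
    rowSums(e * tf$h) + D$params[["out.b"]]
  list(score = score, h = tf$h, caches = tf$caches, yIdx = yIdx, n = nrow(X))
}

# per-sample gradient of the score wrt trunk features: w + emb[y_i]
criticTopGrad <- function(D, yIdx, n) {
  matrix(D$params[["out.W"]][, 1L], n, D$trunk$outDim, byrow = TRUE) +
    D$params$emb[yIdx, , drop = FALSE]
}

embRowsum <- function(M, yIdx, emb) {
  out <- matrix(0, nrow(emb), ncol(emb))
  agg <- rowsum(M, group = yIdx)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

# dScore: numeric vector, d(loss)/d(score_i)
criticBackward <- function(D, cache, dScore, wantParams = TRUE,
                           wantInput = FALSE) {
  n <- cache$n
  grads <- list()
  if (wantParams) {
    grads[["out.W"]] <- crossprod(cache$h, matrix(dScore, ncol = 1L))
    grads[["out.b"]] <- sum(dScore)
    grads$emb <- embRowsum(cache$h * dScore, cache$yIdx, D$params$emb)
  }
  dh <- criticTopGrad(D, cache$yIdx, n) * dScore
  tb <- trunkBackward(D$trunk, D$params, "c", cache$caches, dh,
                      wantParams = wantParams, wantInput = wantInput)
  grads <- c(grads, tb$grads)
  list(grads = grads, dX = tb$dX)
}

# per-sample input gradient g_i = grad_x D(x_i, y_i); also returns the
# backward-pass masked signals q_k needed by the penalty parameter gradient
criticInputGradFull <- function(D, cache) {
  dh <- criticTopGrad(D, cache$yIdx, cache$n)
  qs <- vector("list", 4L)
  for (i in 4:1) {
    ly <- D$trunk$layers[[i]]
    q <- dh * cache$caches[[i]]$mask
    qs[[i]] <- q
    dh <- convBackwardData(ly, D$params[[paste0("c", i, ".W")]], q)
  }
  list(g = dh, qs = qs)
}

# exact parameter gradient of p = lambda * mean((||g|| - 1)^2) given the
# forward cache and the input-grad pass (masks frozen; see file header)
criticPenaltyGrads <- function(D, cache, ig, lambda) {
  n <- cache$n
  g <- ig$g
  norms <- sqrt(rowSums(g * g))
  r <- g * ((2 * lambda / n) * (norms - 1) / pmax(norms, 1e-12))
  v <- r
  grads <- list()
  for (i in 1:4) {
    ly <- D$trunk$layers[[i]]
    grads[[paste0("c", i, ".W")]] <- convWeightGrad(ly, v, ig$qs[[i]])
    vlin <- convForwardLin(ly, D$params[[paste0("c", i, ".W")]], v)
    v <- vlin * cache$caches[[i]]$mask
  }
  # u_top per sample is w + emb[y_i]; dp/dw = sum_i v_i, dp/demb[c] = class sums
  grads[["out.W"]] <- matrix(colSums(v), ncol = 1L)
  grads$emb <- embRowsum(v, cache$yIdx, D$params$emb)
  grads
}

buildClassifier <- function(cfg, nClasses, rows, cols) {
  trunk <- buildTrunk(rows, cols, cfg@clfKernels, cfg)
  params <- trunkInitParams(trunk, cfg, "k")
  params[["f1.W"]] <- initMat(trunk$outDim, cfg@featureDim, cfg@initSd)
  params[["f1.b"]] <- numeric(cfg@featureDim)
  params[["f2.W"]] <- initMat(cfg@featureDim, nClasses, cfg@initSd)
  params[["f2.b"]] <- numeric(nClasses)
  list(kind = "classifier", trunk = trunk, params = params,
       slope = cfg@leakySlope, nClasses = nClasses, adam = adamInit(params))
}

clfForward <- function(C, X) {
  tf <- trunkForward(C$trunk, C$params, "k", X, C$slope)
  z1 <- tf$h %*% C$params[["f1.W"]] + rep(C$params[["f1.b"]], each = nrow(X))
  m1 <- leakyMask(z1, C$slope)
  feat <- z1 * m1
  logits <- feat %*% C$params[["f2.W"]] +
    rep(C$params[["f2.b"]], each = nrow(X))
  list(logits = logits, feat = feat, h = tf$h, m1 = m1, caches = tf$caches)
}

clfBackward <- function(C, cache, dLogits, wantParams = TRUE,
                        wantInput = FALSE) {
  grads <- list()
  dfeat <- tcrossprod(dLogits, C$params[["f2.W"]])
  if (wantParams) {
    grads[["f2.W"]] <- crossprod(cache$feat, dLogits)
    grads[["f2.b"]] <- colSums(dLogits)
  }
  dz1 <- dfeat * cache$m1
  if (wantParams) {
    grads[["f1.W"]] <- crossprod(cache$h, dz1)
    grads[["f1.b"]] <- colSums(dz1)
  }
  dh <- tcrossprod(dz1, C$params[["f1.W"]])
  tb <- trunkBackward(C$trunk, C$params, "k", cache$caches, dh,
                      wantParams = wantParams, wantInput = wantInput)
  list(grads = c(grads, tb$grads), dX = tb$dX)
}

# generator upsampling schedule: per-dim stride 1 or 2 per block such that the
# product of the strides divides the target dim; stride-2 goes to the last
# blocks so early feature maps stay small
upSchedule <- function(dim) {
  a <- 0L; d <- dim
  while (a < 4L && d %% 2L == 0L) { d <- d %/% 2L; a <- a + 1L }
  list(start = d, strides = c(rep(1L, 4L - a), rep(2L, a)))
}

buildGenerator <- function(cfg, nClasses, rows, cols) {
  sr <- upSchedule(rows); sc <- upSchedule(cols)
  ch <- c(cfg@genKernels[1], cfg@genKernels)   # input channels per block
  r <- sr$start; cc <- sc$start
  layers <- vector("list", 4L)
  for (i in 1:4) {
    layers[[i]] <- convTLayer(r, cc, ch[i], ch[i + 1],
                              cfg@kernelSize[1], cfg@kernelSize[2],
                              sr$strides[i], sc$strides[i])
    r <- layers[[i]]$outR; cc <- layers[[i]]$outC
  }
  stopifnot(r == rows, cc == cols)
  # label conditioning by element-wise multiplication of a class embedding
  # with the latent vector (balancing-GAN style); init around 1 so labels
  # start as gentle modulations
  params <- list(emb = 1 + initMat(nClasses, cfg@latentDim, cfg@initSd))
  d0 <- sr$start * sc$start * ch[1]
  params[["dense.W"]] <- initMat(cfg@latentDim, d0, cfg@initSd)
  params[["dense.b"]] <- numeric(d0)
  bnState <- list()
  for (i in 1:4) {
    params[[paste0("t", i, ".W")]] <- initMat(layers[[i]]$rev$KC,
                                              layers[[i]]$Cin, cfg@initSd)
    params[[paste0("t", i, ".b")]] <- numeric(layers[[i]]$Cout)
    if (i < 4L) {
      params[[paste0("bn", i, ".g")]] <- rep(1, layers[[i]]$Cout)
      params[[paste0("bn", i, ".b")]] <- numeric(layers[[i]]$Cout)
      bnState[[i]] <- list(mean = numeric(layers[[i]]$Cout),
                           var = rep(1, layers[[i]]$Cout))
    }
  }
  list(kind = "generator", layers = layers, params = params,
       bnState = bnState, latentDim = cfg@latentDim, slope = cfg@leakySlope,
       startDim = d0, nClasses = nClasses, adam = adamInit(params),
       # class-conditional latent prior (balancing-GAN style); fitted to the
       # encoded training latents after pre-training, standard normal before
       latentPrior = list(mu = matrix(0, nClasses, cfg@latentDim),
                          sd = matrix(1, nClasses, cfg@latentDim)))
}

# forward; train = TRUE uses batch statistics in BN (and updates the running
# stats with `momentum`; momentum 0 overwrites them — used for the post-
# pre-training calibration pass), train = FALSE applies the frozen running
# statistics as a per-channel affine map (gamma/beta still receive
# gradients). Adversarial training and generation run with train = FALSE so
# the output does not depend on batch composition.
genForward <- function(G, Z, yIdx, train = TRUE, momentum = 0.99) {
  n <- nrow(Z)
  e <- G$params$emb[yIdx, , drop = FALSE]
  inp <- Z * e
  h <- inp %*% G$params[["dense.W"]] +
    rep(G$params[["dense.b"]], each = n)
  caches <- vector("list", 4L)
  newState <- G$bnState
  eCache <- e; zCache <- Z
  for (i in 1:4) {
    ly <- G$layers[[i]]
    cf <- convTForward(ly, G$params[[paste0("t", i, ".W")]],
                       G$params[[paste0("t", i, ".b")]], h)
    if (i < 4L) {
      mask <- leakyMask(cf$out, G$slope)
      a <- cf$out * mask
      bf <- bnForward(ly$Pout, ly$Cout, G$params[[paste0("bn", i, ".g")]],
                      G$params[[paste0("bn", i, ".b")]], a,
                      newState[[i]], train, momentum)
      newState[[i]] <- bf$state
      h <- bf$out
      caches[[i]] <- list(Xm = cf$Xm, mask = mask, bn = bf)
    } else {
      h <- tanh(cf$out)
      caches[[i]] <- list(Xm = cf$Xm, out = h)
    }
  }
  list(out = h, caches = caches, inp = inp, e = eCache, Z = zCache,
       yIdx = yIdx, newState = newState)
}

genBackward <- function(G, cache, dOut) {
  grads <- list()
  dh <- dOut
  for (i in 4:1) {
    ly <- G$layers[[i]]
    if (i == 4L) {
      dz <- dh * (1 - cache$caches[[4]]$out^2)
    } else {
      cc <- cache$caches[[i]]
      bb <- bnBackward(ly$Pout, ly$Cout, G$params[[paste0("bn", i, ".g")]],
                       cc$bn, dh)
      grads[[paste0("bn", i, ".g")]] <- bb$dgamma
      grads[[paste0("bn", i, ".b")]] <- bb$dbeta
      dz <- bb$dX * cc$mask
    }
    bk <- convTBackward(ly, G$params[[paste0("t", i, ".W")]],
                        cache$caches[[i]]$Xm, dz)
    grads[[paste0("t", i, ".W")]] <- bk$dW
    grads[[paste0("t", i, ".b")]] <- bk$db
    dh <- bk$dX
  }
  n <- nrow(dh)
  grads[["dense.W"]] <- crossprod(cache$inp, dh)
  grads[["dense.b"]] <- colSums(dh)
  dInp <- tcrossprod(dh, G$params[["dense.W"]])
  dZ <- dInp * cache$e                      # inp = Z * emb[y]
  gEmb <- matrix(0, nrow(G$params$emb), ncol(G$params$emb))
  agg <- rowsum(dInp * cache$Z, group = cache$yIdx)
  gEmb[as.integer(rownames(agg)), ] <- agg
  grads$emb <- gEmb
  list(grads = grads, dZ = dZ)
}

# draw class-conditional latent vectors from the generator's latent prior:
# z = mu_c + w' L_c + ridge * eps, where L_c is the empirical covariance
# factor of class c's encoded training spectra (so samples stay in the
# affine span of observed codes), falling back to the diagonal prior when no
# factors have been fitted yet
latentDraw <- function(G, yIdx) {
  n <- length(yIdx)
  pr <- G$latentPrior
  if (is.null(pr$factors)) {
    Z <- matrix(rnorm(n * G$latentDim), n)
    return(pr$mu[yIdx, , drop = FALSE] + Z * pr$sd[yIdx, , drop = FALSE])
  }
  out <- matrix(0, n, G$latentDim)
  for (i in seq_len(n)) {
    Lc <- pr$factors[[yIdx[i]]]
    out[i, ] <- pr$mu[yIdx[i], ] + as.numeric(rnorm(nrow(Lc)) %*% Lc) +
      pr$ridge * rnorm(G$latentDim)
  }
  out
}

applyAdam <- function(net, grads, cfg) {
  upd <- adamStep(net$params, grads, net$adam, cfg@learningRate, cfg@beta1,
                  cfg@beta2)
  net$params <- upd$params
  net$adam <- upd$state
  net
}
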