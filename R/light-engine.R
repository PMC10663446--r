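# Internal encoder engine: graph preparation, cached forward pass, and
# hand-derived reverse-mode gradients for every parameter bank. All linear
# maps are stored input x output, applied as X %*% W + b.

.lnEps <- 1e-6

lnForward <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  s <- sqrt(rowMeans(xc^2) + .lnEps)
  xn <- xc / s
  list(Y = sweep(xn, 2L, g, `*`) + matrix(b, nrow(X), length(b), byrow = TRUE),
       xn = xn, s = s)
}

lnBackward <- function(dY, cache, g) {
  xn <- cache$xn; s <- cache$s
  dxn <- sweep(dY, 2L, g, `*`)
  dX <- (dxn - rowMeans(dxn) - xn * rowMeans(dxn * xn)) / s
  list(dX = dX, dg = colSums(dY * xn), db = colSums(dY))
}

# Static per-graph structure consumed by the forward pass: raw features,
# knowledge input, and the index bookkeeping for the path/distance biases.
prepareGraph <- function(ag, cfg) {
  stopifnot(is(ag, "AugmentedGraph"))
  lg <- ag@base
  Nb <- lg@nNodes
  N <- Nb + 1L
  D <- lg@dist
  maxP <- cfg$maxPathNodes

  reachable <- which(D >= 0L)             # linear indices in Nb x Nb
  unreachB <- which(D < 0L)
  ri <- ((reachable - 1L) %% Nb) + 1L     # row (source) of each reachable pair
  rj <- ((reachable - 1L) %/% Nb) + 1L
  toFull <- function(i, j) (j - 1L) * N + i
  reachIdx <- toFull(ri, rj)
  unreachIdx <- if (length(unreachB))
    toFull(((unreachB - 1L) %% Nb) + 1L, ((unreachB - 1L) %/% Nb) + 1L) else integer(0)
  kIdx <- c(toFull(rep(N, N), 1:N), toFull(1:N, rep(N, N)))
  kIdx <- unique(kIdx)

  nReach <- length(reachable)
  Np <- integer(nReach)
  posNodes <- vector("list", maxP)
  posPairs <- vector("list", maxP)
  for (n in seq_len(maxP)) { posNodes[[n]] <- integer(0); posPairs[[n]] <- integer(0) }
  for (q in seq_len(nReach)) {
    p <- lg@paths[[ri[q]]][[rj[q]]]
    if (length(p) > maxP) p <- p[seq_len(maxP)]  # model bank may be shorter
    Np[q] <- length(p)
    for (n in seq_along(p)) {
      posNodes[[n]] <- c(posNodes[[n]], p[n])
      posPairs[[n]] <- c(posPairs[[n]], q)
    }
  }
  invNp <- 1 / Np

  dClip <- pmin(D[reachable], cfg$distClip)
  uD <- sort(unique(dClip))
  dGroups <- lapply(uD, function(v) reachIdx[dClip == v])

  list(N = N, Nb = Nb, kIndex = N,
       Xi = lg@xi, Xj = lg@xj, Xe = lg@xe,
       kIn = unname(assembled(ag@knowledge) * (1 - ag@knowledgeMask)),
       kMask = unname(ag@knowledgeMask),
       maskFlags = ag@maskFlags,
       reachIdx = reachIdx, unreachIdx = unreachIdx, kIdx = kIdx,
       invNp = invNp, posNodes = posNodes, posPairs = posPairs,
       uD = uD, dGroups = dGroups)
}

# H0 per Eq. 1 plus the K-node knowledge projection; masked nodes are
# replaced by the learned mask token after projection.
.embedForward <- function(prep, pm) {
  D2 <- ncol(pm$emb.Wv)
  hv <- (prep$Xi + prep$Xj) %*% pm$emb.Wv +
    matrix(pm$emb.bv, prep$Nb, D2, byrow = TRUE)
  he <- prep$Xe %*% pm$emb.We + matrix(pm$emb.be, prep$Nb, D2, byrow = TRUE)
  H0 <- rbind(cbind(hv, he),
              as.numeric(prep$kIn %*% pm$emb.Wk) + pm$emb.bk +
                as.numeric(prep$kMask %*% pm$emb.WkMask))
  masked <- which(prep$maskFlags)
  if (length(masked))
    H0[masked, ] <- matrix(pm$emb.maskToken, length(masked), ncol(H0), byrow = TRUE)
  list(H0 = H0, masked = masked)
}

.embedBackward <- function(prep, pm, dH0, masked, grads) {
  if (length(masked)) {
    grads$emb.maskToken <- grads$emb.maskToken +
      colSums(dH0[masked, , drop = FALSE])
    dH0[masked, ] <- 0
  }
  D2 <- ncol(pm$emb.Wv)
  dBase <- dH0[seq_len(prep$Nb), , drop = FALSE]
  dK <- dH0[prep$N, ]
  dhv <- dBase[, seq_len(D2), drop = FALSE]
  dhe <- dBase[, D2 + seq_len(D2), drop = FALSE]
  grads$emb.Wv <- grads$emb.Wv + crossprod(prep$Xi + prep$Xj, dhv)
  grads$emb.bv <- grads$emb.bv + colSums(dhv)
  grads$emb.We <- grads$emb.We + crossprod(prep$Xe, dhe)
  grads$emb.be <- grads$emb.be + colSums(dhe)
  grads$emb.Wk <- grads$emb.Wk + outer(prep$kIn, dK)
  grads$emb.bk <- grads$emb.bk + dK
  grads$emb.WkMask <- grads$emb.WkMask + outer(prep$kMask, dK)
  grads
}

# Path bias (Eq. 4) over reachable base pairs; K-pairs and unreachable pairs
# take their dedicated learned scalars.
.pathBiasForward <- function(prep, pm, H0) {
  N <- prep$N
  Dp <- length(pm$path.Wa)
  C <- matrix(0, length(prep$invNp), Dp)
  maxP <- length(prep$posNodes)
  for (n in seq_len(maxP)) {
    act <- prep$posPairs[[n]]
    if (!length(act)) next
    C[act, ] <- C[act, , drop = FALSE] +
      (H0[prep$posNodes[[n]], , drop = FALSE] %*% pm$path.Wp[, , n]) *
      prep$invNp[act]
  }
  Ap <- matrix(0, N, N)
  Ap[prep$reachIdx] <- as.numeric(C %*% pm$path.Wa)
  Ap[prep$unreachIdx] <- pm$path.unreachBias
  Ap[prep$kIdx] <- pm$path.kBias
  list(Ap = Ap, C = C)
}

.pathBiasBackward <- function(prep, pm, cache, dAp, grads) {
  dReach <- dAp[prep$reachIdx]
  grads$path.Wa <- grads$path.Wa + as.numeric(crossprod(cache$C, dReach))
  grads$path.unreachBias <- grads$path.unreachBias + sum(dAp[prep$unreachIdx])
  grads$path.kBias <- grads$path.kBias + sum(dAp[prep$kIdx])
  dC <- outer(dReach, pm$path.Wa)
  dH0 <- matrix(0, prep$N, dim(pm$path.Wp)[1L])
  maxP <- length(prep$posNodes)
  for (n in seq_len(maxP)) {
    act <- prep$posPairs[[n]]
    if (!length(act)) next
    contrib <- dC[act, , drop = FALSE] * prep$invNp[act]
    nodes <- prep$posNodes[[n]]
    grads$path.Wp[, , n] <- grads$path.Wp[, , n] +
      crossprod(H0cacheRows(prep, nodes), contrib)
    back <- tcrossprod(contrib, pm$path.Wp[, , n])
    agg <- rowsum(back, group = nodes)
    dH0[as.integer(rownames(agg)), ] <- dH0[as.integer(rownames(agg)), , drop = FALSE] + agg
  }
  list(grads = grads, dH0 = dH0)
}

# .pathBiasBackward needs the same H0 rows the forward used; stored on prep
# by the engine before backward.
H0cacheRows <- function(prep, nodes) prep$H0[nodes, , drop = FALSE]

# Distance bias (Eq. 5): 2-layer bias-free MLP on the clipped hop count,
# evaluated once per distinct distance value.
.distBiasForward <- function(prep, pm) {
  N <- prep$N
  Ad <- matrix(0, N, N)
  hidden <- vector("list", length(prep$uD))
  for (q in seq_along(prep$uD)) {
    z <- pm$dist.W1 * prep$uD[q]
    hidden[[q]] <- z
    Ad[prep$dGroups[[q]]] <- sum(pm$dist.W2 * gelu(z))
  }
  Ad[prep$unreachIdx] <- pm$dist.unreachBias
  Ad[prep$kIdx] <- pm$dist.kBias
  list(Ad = Ad, hidden = hidden)
}

.distBiasBackward <- function(prep, pm, cache, dAd, grads) {
  for (q in seq_along(prep$uD)) {
    s <- sum(dAd[prep$dGroups[[q]]])
    if (s == 0) next
    z <- cache$hidden[[q]]
    grads$dist.W2 <- grads$dist.W2 + gelu(z) * s
    grads$dist.W1 <- grads$dist.W1 + pm$dist.W2 * geluGrad(z) * prep$uD[q] * s
  }
  grads$dist.unreachBias <- grads$dist.unreachBias + sum(dAd[prep$unreachIdx])
  grads$dist.kBias <- grads$dist.kBias + sum(dAd[prep$kIdx])
  grads
}

.layerForward <- function(Hin, pm, l, cfg, Apd, train) {
  D <- cfg$hidden; Nh <- cfg$nHeads; Dh <- D / Nh
  N <- nrow(Hin)
  p <- cfg$dropout
  nm <- function(s) paste0("L", l, ".", s)
  Q <- Hin %*% pm[[nm("Wq")]] + matrix(pm[[nm("bq")]], N, D, byrow = TRUE)
  K <- Hin %*% pm[[nm("Wk")]] + matrix(pm[[nm("bk")]], N, D, byrow = TRUE)
  V <- Hin %*% pm[[nm("Wv")]] + matrix(pm[[nm("bv")]], N, D, byrow = TRUE)
  if (any(!is.finite(Q)) || any(!is.finite(K)) || any(!is.finite(V)))
    stop("non-finite values entering attention layer ", l, call. = FALSE)
  A <- array(0, c(N, N, Nh)); Adrop <- array(0, c(N, N, Nh))
  O <- matrix(0, N, D)
  maskA <- if (train && p > 0) array(stats::rbinom(N * N * Nh, 1L, 1 - p),
                                     c(N, N, Nh)) else NULL
  for (k in seq_len(Nh)) {
    cols <- (k - 1L) * Dh + seq_len(Dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(Dh) + Apd
    Ak <- rowSoftmax(S)
    A[, , k] <- Ak
    Akd <- if (!is.null(maskA)) Ak * maskA[, , k] / (1 - p) else Ak
    Adrop[, , k] <- Akd
    O[, cols] <- Akd %*% V[, cols, drop = FALSE]
  }
  ln1 <- lnForward(Hin + O, pm[[nm("ln1g")]], pm[[nm("ln1b")]])
  Hhat <- ln1$Y
  F1 <- Hhat %*% pm[[nm("W1")]] + matrix(pm[[nm("b1")]], N, 4L * D, byrow = TRUE)
  G1 <- gelu(F1)
  maskG <- if (train && p > 0) matrix(stats::rbinom(N * 4L * D, 1L, 1 - p), N) else NULL
  G1d <- if (!is.null(maskG)) G1 * maskG / (1 - p) else G1
  F2 <- G1d %*% pm[[nm("W2")]] + matrix(pm[[nm("b2")]], N, D, byrow = TRUE)
  ln2 <- lnForward(F2 + Hhat, pm[[nm("ln2g")]], pm[[nm("ln2b")]])
  list(Hout = ln2$Y, Hin = Hin, Q = Q, K = K, V = V, A = A, Adrop = Adrop,
       maskA = maskA, ln1 = ln1, Hhat = Hhat, F1 = F1, G1d = G1d,
       maskG = maskG, ln2 = ln2)
}

.layerBackward <- function(dHout, cache, pm, l, cfg, grads) {
  D <- cfg$hidden; Nh <- cfg$nHeads; Dh <- D / Nh
  p <- cfg$dropout
  nm <- function(s) paste0("L", l, ".", s)
  b2c <- lnBackward(dHout, cache$ln2, pm[[nm("ln2g")]])
  grads[[nm("ln2g")]] <- grads[[nm("ln2g")]] + b2c$dg
  grads[[nm("ln2b")]] <- grads[[nm("ln2b")]] + b2c$db
  dF2 <- b2c$dX
  dHhat <- b2c$dX
  grads[[nm("W2")]] <- grads[[nm("W2")]] + crossprod(cache$G1d, dF2)
  grads[[nm("b2")]] <- grads[[nm("b2")]] + colSums(dF2)
  dG1d <- tcrossprod(dF2, pm[[nm("W2")]])
  dG1 <- if (!is.null(cache$maskG)) dG1d * cache$maskG / (1 - p) else dG1d
  dF1 <- dG1 * geluGrad(cache$F1)
  grads[[nm("W1")]] <- grads[[nm("W1")]] + crossprod(cache$Hhat, dF1)
  grads[[nm("b1")]] <- grads[[nm("b1")]] + colSums(dF1)
  dHhat <- dHhat + tcrossprod(dF1, pm[[nm("W1")]])
  b1c <- lnBackward(dHhat, cache$ln1, pm[[nm("ln1g")]])
  grads[[nm("ln1g")]] <- grads[[nm("ln1g")]] + b1c$dg
  grads[[nm("ln1b")]] <- grads[[nm("ln1b")]] + b1c$db
  dHin <- b1c$dX
  dO <- b1c$dX
  N <- nrow(dHout)
  dQ <- matrix(0, N, D); dK <- matrix(0, N, D); dV <- matrix(0, N, D)
  dApd <- matrix(0, N, N)
  for (k in seq_len(Nh)) {
    cols <- (k - 1L) * Dh + seq_len(Dh)
    dOk <- dO[, cols, drop = FALSE]
    Vk <- cache$V[, cols, drop = FALSE]
    dAkd <- tcrossprod(dOk, Vk)
    dV[, cols] <- crossprod(cache$Adrop[, , k], dOk)
    dAk <- if (!is.null(cache$maskA)) dAkd * cache$maskA[, , k] / (1 - p) else dAkd
    Ak <- cache$A[, , k]
    dS <- Ak * (dAk - rowSums(dAk * Ak))
    dApd <- dApd + dS
    dQ[, cols] <- (dS %*% cache$K[, cols, drop = FALSE]) / sqrt(Dh)
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) / sqrt(Dh)
  }
  grads[[nm("Wq")]] <- grads[[nm("Wq")]] + crossprod(cache$Hin, dQ)
  grads[[nm("bq")]] <- grads[[nm("bq")]] + colSums(dQ)
  grads[[nm("Wk")]] <- grads[[nm("Wk")]] + crossprod(cache$Hin, dK)
  grads[[nm("bk")]] <- grads[[nm("bk")]] + colSums(dK)
  grads[[nm("Wv")]] <- grads[[nm("Wv")]] + crossprod(cache$Hin, dV)
  grads[[nm("bv")]] <- grads[[nm("bv")]] + colSums(dV)
  dHin <- dHin + tcrossprod(dQ, pm[[nm("Wq")]]) + tcrossprod(dK, pm[[nm("Wk")]]) +
    tcrossprod(dV, pm[[nm("Wv")]])
  list(dHin = dHin, dApd = dApd, grads = grads)
}

# Full cached forward pass over one prepared graph. h0Delta (N x D) is the
# adversarial FLAG perturbation added to the initial embeddings.
.forwardGraph <- function(prep, pm, cfg, train = FALSE, h0Delta = NULL) {
  emb <- .embedForward(prep, pm)
  H0 <- emb$H0
  if (!is.null(h0Delta)) H0 <- H0 + h0Delta
  prep$H0 <- H0
  pb <- .pathBiasForward(prep, pm, H0)
  db <- .distBiasForward(prep, pm)
  Apd <- pb$Ap + db$Ad
  if (isTRUE(cfg$recomputeBiasPerLayer) && train)
    stop("per-layer bias recomputation is inference-only; train with shared biases",
         call. = FALSE)
  layers <- vector("list", cfg$nLayers)
  H <- H0
  for (l in seq_len(cfg$nLayers)) {
    if (isTRUE(cfg$recomputeBiasPerLayer) && l > 1L) {
      prep$H0 <- H
      Apd <- .pathBiasForward(prep, pm, H)$Ap + db$Ad
    }
    layers[[l]] <- .layerForward(H, pm, l, cfg, Apd, train)
    H <- layers[[l]]$Hout
  }
  poolIdx <- if (isTRUE(cfg$poolIncludeK)) seq_len(prep$N) else seq_len(prep$Nb)
  pooled <- colMeans(H[poolIdx, , drop = FALSE])
  list(prep = prep, emb = emb, pb = pb, db = db, layers = layers,
       H = H, pooled = pooled, poolIdx = poolIdx)
}

# Reverse pass: dPooled (D) and/or dNode (N x D) seed the gradient; returns
# parameter gradients (added into `grads`) and the gradient w.r.t. H0.
.backwardGraph <- function(fw, pm, cfg, grads, dPooled = NULL, dNode = NULL) {
  prep <- fw$prep
  N <- prep$N; D <- cfg$hidden
  dH <- matrix(0, N, D)
  if (!is.null(dNode)) dH <- dH + dNode
  if (!is.null(dPooled))
    dH[fw$poolIdx, ] <- dH[fw$poolIdx, , drop = FALSE] +
      matrix(dPooled / length(fw$poolIdx), length(fw$poolIdx), D, byrow = TRUE)
  dAp <- matrix(0, N, N)
  for (l in rev(seq_len(cfg$nLayers))) {
    lb <- .layerBackward(dH, fw$layers[[l]], pm, l, cfg, grads)
    grads <- lb$grads
    dH <- lb$dHin
    dAp <- dAp + lb$dApd
  }
  # shared bias matrices: dAp accumulates over layers and heads, and feeds
  # both the path and the distance banks
  pbb <- .pathBiasBackward(prep, pm, fw$pb, dAp, grads)
  grads <- pbb$grads
  grads <- .distBiasBackward(prep, pm, fw$db, dAp, grads)
  dH0 <- dH + pbb$dH0
  grads <- .embedBackward(prep, pm, dH0, fw$emb$masked, grads)
  list(grads = grads, dH0 = dH0)
}

# Two-layer GELU perceptron heads (task predictor, node classifier,
# descriptor and fingerprint heads).
.headForward <- function(pm, prefix, X) {
  oneRow <- is.null(dim(X))
  if (oneRow) X <- matrix(X, 1L)
  W1 <- pm[[paste0(prefix, ".W1")]]; b1 <- pm[[paste0(prefix, ".b1")]]
  W2 <- pm[[paste0(prefix, ".W2")]]; b2 <- pm[[paste0(prefix, ".b2")]]
  Z1 <- X %*% W1 + matrix(b1, nrow(X), length(b1), byrow = TRUE)
  G <- gelu(Z1)
  Y <- G %*% W2 + matrix(b2, nrow(X), length(b2), byrow = TRUE)
  list(Y = Y, X = X, Z1 = Z1, G = G, oneRow = oneRow)
}

.headBackward <- function(pm, prefix, cache, dY, grads) {
  if (is.null(dim(dY))) dY <- matrix(dY, 1L)
  W1n <- paste0(prefix, ".W1"); b1n <- paste0(prefix, ".b1")
  W2n <- paste0(prefix, ".W2"); b2n <- paste0(prefix, ".b2")
  grads[[W2n]] <- grads[[W2n]] + crossprod(cache$G, dY)
  grads[[b2n]] <- grads[[b2n]] + colSums(dY)
  dG <- tcrossprod(dY, pm[[W2n]])
  dZ1 <- dG * geluGrad(cache$Z1)
  grads[[W1n]] <- grads[[W1n]] + crossprod(cache$X, dZ1)
  grads[[b1n]] <- grads[[b1n]] + colSums(dZ1)
  list(grads = grads, dX = tcrossprod(dZ1, pm[[W1n]]))
}

zeroGrads <- function(pm) lapply(pm, function(x) { x[] <- 0; x })

`%||%` <- function(a, b) if (is.null(a)) b else a

# Decoupled-weight-decay Adam. state is NULL on the first call. lrScale is a
# named per-parameter multiplier (layer-wise learning-rate decay).
adamStep <- function(pm, grads, state, lr, weightDecay = 0,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     lrScale = NULL, frozen = character(0)) {
  if (is.null(state)) state <- list(t = 0L, m = zeroGrads(pm), v = zeroGrads(pm))
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(pm)) {
    if (nm %in% frozen) next
    g <- grads[[nm]]
    if (is.null(g)) next
    sc <- if (!is.null(lrScale) && nm %in% names(lrScale)) lrScale[[nm]] else 1
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    step <- lr * sc * (mhat / (sqrt(vhat) + eps) + weightDecay * pm[[nm]])
    pm[[nm]] <- pm[[nm]] - step
  }
  list(params = pm, state = state)
}
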