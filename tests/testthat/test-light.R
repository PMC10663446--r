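# Encoder equation fidelity, attention properties, forward-pass invariances,
# heads and parameter counting.

toyAugmented <- function(xiPlusXj, xe, edges) {
  augmentWithKNode(toyLineGraph(xiPlusXj, xe, edges), zeroKnowledge())
}

test_that("node embedding follows the concat(Wv xi + Wv xj, We xe) rule", {
  m <- toyModel(wv = 3, we = 5)
  ag <- toyAugmented(3, 1, matrix(integer(0), 0, 2))  # xi + xj = 3, xe = 1
  H0 <- embedNodes(ag, m)
  expect_equal(H0[1, ], c(9, 5))                      # hand arithmetic

  # symmetry: swapping the stored atom order leaves the row unchanged
  g <- cachedParse("CCO")
  lg <- toLineGraph(g)
  lg2 <- lg
  lg2@xi <- lg@xj; lg2@xj <- lg@xi
  cfg <- tinyConfig()
  mm <- initLightModel(cfg, seed = 5L)
  corpus <- lapply(fixtureCorpus(6L), cachedParse)
  nz <- fitNormalizer(do.call(rbind, lapply(corpus, computeDescriptors)))
  kv <- buildKnowledgeVector(g, nz)
  expect_equal(embedNodes(augmentWithKNode(lg, kv), mm),
               embedNodes(augmentWithKNode(lg2, kv), mm))

  # zero weights and biases give zero base rows
  z <- toyModel(wv = 0, we = 0)
  H0z <- embedNodes(toyAugmented(c(2, 4), c(1, 1), rbind(c(1L, 2L))), z)
  expect_true(all(H0z[1:2, ] == 0))
})

test_that("path bias reproduces the hand-computed scalar case", {
  # path (v1, v2) with initial features 2 and 4, all path projections = 1,
  # aggregation weight 1: bias = mean(2, 4) = 3
  m <- toyModel(wv = 1, we = 0)
  m@params$path.Wp[] <- 0
  m@params$path.Wp[1, 1, 1] <- 1
  m@params$path.Wp[1, 1, 2] <- 1
  m@params$path.Wp[1, 1, 3] <- 1
  m@params$path.Wa <- 1
  ag <- toyAugmented(c(2, 4), c(0, 0), rbind(c(1L, 2L)))
  Ap <- pathBias(ag, m)
  expect_equal(Ap[1, 2], 3)
  expect_equal(Ap[1, 1], 2)                 # diagonal: length-1 path (v1)
  expect_equal(Ap[2, 2], 4)

  # all path projections zero -> zero bias on reachable base pairs
  m0 <- toyModel()
  m0@params$path.Wp[] <- 0
  Ap0 <- pathBias(toyAugmented(c(1, 2), c(0, 0), rbind(c(1L, 2L))), m0)
  expect_true(all(Ap0[1:2, 1:2] == 0))
})

test_that("distance bias is the GELU MLP of the clipped hop count", {
  m <- toyModel(wv = 1, we = 0)
  m@params$dist.W1 <- 1
  m@params$dist.W2 <- 1
  ag <- toyAugmented(c(1, 1, 1), c(0, 0, 0), rbind(c(1L, 2L), c(2L, 3L)))
  Ad <- distanceBias(ag, m)
  expect_equal(Ad[1, 3], 2 * pnorm(2))      # GELU(2) with the Gaussian CDF
  expect_equal(Ad[1, 2], 1 * pnorm(1))
  expect_equal(Ad[1, 1], 0)                 # GELU(0) = 0 for any weights

  m@params$dist.W2 <- numeric(1)            # W2 = 0 kills the bias
  Ad0 <- distanceBias(ag, m)
  expect_true(all(Ad0[1:3, 1:3] == 0))
})

test_that("K-node and unreachable pairs use their dedicated learned scalars", {
  m <- toyModel()
  m@params$path.kBias <- 1.5
  m@params$path.unreachBias <- -2.5
  m@params$dist.kBias <- 0.25
  ag <- toyAugmented(c(1, 2, 3, 4), c(0, 0, 0, 0), rbind(c(1L, 2L), c(3L, 4L)))
  Ap <- pathBias(ag, m)
  Ad <- distanceBias(ag, m)
  k <- 5L
  expect_true(all(Ap[k, ] == 1.5) && all(Ap[, k] == 1.5))
  expect_equal(Ap[1, 3], -2.5)              # disconnected fragments
  expect_true(all(Ad[k, ] == 0.25))
})

test_that("attention rows are stochastic, reduce at zero bias, and are shift-invariant", {
  cfg <- tinyConfig()
  m <- initLightModel(cfg, seed = 9L)
  set.seed(31)
  H <- matrix(rnorm(6 * cfg$hidden), 6)
  bias <- matrix(rnorm(36), 6)
  A <- attentionWeights(H, bias, m, 1L)
  for (k in seq_len(cfg$nHeads))
    expect_equal(rowSums(A[, , k]), rep(1, 6), tolerance = 1e-6)

  # zero bias equals the unbiased attention formula computed independently
  A0 <- attentionWeights(H, matrix(0, 6, 6), m, 1L)
  Dh <- cfg$headDim
  Q <- H %*% m@params$L1.Wq; K <- H %*% m@params$L1.Wk
  S <- (Q[, 1:Dh] %*% t(K[, 1:Dh])) / sqrt(Dh)
  ref <- exp(S - apply(S, 1, max)); ref <- ref / rowSums(ref)
  expect_equal(A0[, , 1], ref, tolerance = 1e-10)

  # adding a constant to a full bias row leaves that row's output unchanged
  out1 <- attentionLayer(H, bias, m, 1L)
  bias2 <- bias; bias2[3, ] <- bias2[3, ] + 7
  out2 <- attentionLayer(H, bias2, m, 1L)
  expect_equal(out1[3, ], out2[3, ], tolerance = 1e-9)

  # identical node features + zero bias -> uniform attention rows
  Hsame <- matrix(1, 5, cfg$hidden)
  Au <- attentionWeights(Hsame, matrix(0, 5, 5), m, 1L)
  expect_equal(Au[, , 1], matrix(1 / 5, 5, 5), tolerance = 1e-10)

  expect_error(attentionLayer(H * NA, bias, m, 1L), "non-finite")
})

test_that("the FFN block is the post-norm residual form of the layer update", {
  cfg <- tinyConfig()
  m <- initLightModel(cfg, seed = 13L)
  set.seed(5)
  Hprev <- matrix(rnorm(4 * cfg$hidden), 4)
  Hattn <- matrix(rnorm(4 * cfg$hidden), 4)
  out <- ffnBlock(Hprev, Hattn, m, 1L)
  expect_equal(dim(out), dim(Hprev))

  # W2 = 0 (and b2 = 0) collapses the block to LN(LN(Hprev + Hattn))
  m0 <- m
  m0@params$L1.W2[] <- 0
  out0 <- ffnBlock(Hprev, Hattn, m0, 1L)
  ln <- function(X, g, b) {
    t(apply(X, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-6))) *
      rep(g, each = nrow(X)) + rep(b, each = nrow(X))
  }
  inner <- ln(Hprev + Hattn, m0@params$L1.ln1g, m0@params$L1.ln1b)
  expect_equal(out0, ln(inner, m0@params$L1.ln2g, m0@params$L1.ln2b),
               tolerance = 1e-12)

  # each row is standardized before the affine layer-norm parameters
  expect_lt(max(abs(rowMeans(out))), 1e-9)
  rowVar <- rowMeans(out^2) - rowMeans(out)^2
  expect_equal(rowVar, rep(1, 4), tolerance = 1e-3)
})

test_that("forward pass pools correctly and is deterministic", {
  cfg <- tinyConfig()
  corpus <- lapply(fixtureCorpus(6L), cachedParse)
  nz <- fitNormalizer(do.call(rbind, lapply(corpus, computeDescriptors)))
  m <- initLightModel(cfg, seed = 17L)

  g <- corpus[[2]]
  ag <- augmentWithKNode(toLineGraph(g, cfg$maxPathNodes),
                         buildKnowledgeVector(g, nz))
  f1 <- lightForward(ag, m)
  f2 <- lightForward(ag, m)
  expect_identical(f1$pooled, f2$pooled)                 # bitwise-stable
  expect_equal(f1$pooled, colMeans(f1$nodeEmbeddings))   # K included by default

  cfgNoK <- tinyConfig(poolIncludeK = FALSE)
  mNoK <- initLightModel(cfgNoK, seed = 17L)
  fNoK <- lightForward(ag, mNoK)
  n <- nrow(fNoK$nodeEmbeddings)
  expect_equal(fNoK$pooled, colMeans(fNoK$nodeEmbeddings[-n, , drop = FALSE]))

  # a 1-node graph pools to that node's embedding (K excluded)
  one <- augmentWithKNode(toLineGraph(cachedParse("C"), cfg$maxPathNodes),
                          buildKnowledgeVector(cachedParse("C"), nz))
  fOne <- lightForward(one, mNoK)
  expect_equal(fOne$pooled, fOne$nodeEmbeddings[1, ])
})

test_that("the encoder is permutation-equivariant with invariant pooling", {
  cfg <- tinyConfig()
  corpus <- lapply(fixtureCorpus(10L, seed = 33L), cachedParse)
  nz <- fitNormalizer(do.call(rbind, lapply(corpus, computeDescriptors)))
  m <- initLightModel(cfg, seed = 19L)
  set.seed(77)
  for (g in corpus[1:6]) {
    lg <- toLineGraph(g, cfg$maxPathNodes)
    n <- nNodes(lg)
    if (n < 3) next
    perm <- sample(n)
    inv <- order(perm)
    lgp <- new("LineGraph", nNodes = lg@nNodes,
               edges = matrix(inv[lg@edges], ncol = 2L),
               xi = lg@xi[perm, , drop = FALSE], xj = lg@xj[perm, , drop = FALSE],
               xe = lg@xe[perm, , drop = FALSE],
               elemI = lg@elemI[perm], elemJ = lg@elemJ[perm],
               bondType = lg@bondType[perm],
               dist = matrix(integer(0), 0, 0), paths = list(),
               maxPathNodes = lg@maxPathNodes, smiles = lg@smiles)
    lgp <- allPairsPaths(lgp, cfg$maxPathNodes)
    kv <- buildKnowledgeVector(g, nz)
    f <- lightForward(augmentWithKNode(lg, kv), m)
    fp <- lightForward(augmentWithKNode(lgp, kv), m)
    expect_equal(fp$nodeEmbeddings[seq_len(n), ],
                 f$nodeEmbeddings[perm, ], tolerance = 1e-5)
    expect_equal(fp$pooled, f$pooled, tolerance = 1e-5)
  }
})

test_that("prediction heads are exact 2-layer GELU perceptrons", {
  cfg <- tinyConfig()
  m <- initLightModel(cfg, nTasks = 3L, seed = 23L)
  pooled <- rnorm(cfg$hidden)
  out <- predictHead(pooled, m, "task")
  expect_equal(ncol(out), 3L)

  # zero weights and biases -> zero outputs
  m0 <- m
  for (nm in c("head.W1", "head.b1", "head.W2", "head.b2")) m0@params[[nm]][] <- 0
  expect_true(all(predictHead(pooled, m0, "task") == 0))

  # hand-set 1x1 chain reproduced in closed form
  m1 <- initLightModel(lightConfig(nLayers = 1, hidden = 2, nHeads = 1,
                                   dV = 1, dE = 1, seed = 2), nTasks = 1L)
  m1@params$head.W1 <- matrix(c(2, 0, 0, 0), 2, 2)
  m1@params$head.b1 <- c(0, 0)
  m1@params$head.W2 <- matrix(c(3, 0), 2, 1)
  m1@params$head.b2 <- 0
  x <- 0.7
  got <- predictHead(c(x, 0), m1, "task")[1, 1]
  expect_equal(got, 3 * (2 * x) * pnorm(2 * x), tolerance = 1e-9)

  expect_error(predictHead(matrix(rnorm(10), 1), m, "task"), "width")
  expect_error(predictHead(pooled, initLightModel(cfg, seed = 1), "task"),
               "no 'task' head")
})

test_that("parameter counts are additive and the reference config is ~1e8", {
  c1 <- countParameters(initLightModel(tinyConfig(), seed = 1))
  c2 <- countParameters(initLightModel(tinyConfig(nLayers = 4L), seed = 1))
  c3 <- countParameters(initLightModel(tinyConfig(nLayers = 6L), seed = 1))
  expect_equal(c3 - c2, c2 - c1)            # per-layer cost is constant
  perLayer <- (c2 - c1) / 2
  D <- 8
  expect_equal(perLayer, 3 * (D * D + D) + (4 * D * D + 4 * D) +
                 (4 * D * D + D) + 4 * D)   # QKV + FFN + layer norms

  big <- lightConfig()                       # 12 layers, 768 hidden, 12 heads
  # count without instantiating 80M doubles: rebuild from shapes at tiny scale
  nBig <- countParameters(initLightModel(
    lightConfig(nLayers = 1L, hidden = 768L, nHeads = 12L,
                pathDim = 64L, distDim = 64L), seed = 1))
  perLayerBig <- 3 * (768^2 + 768) + (4 * 768^2 + 4 * 768) +
    (4 * 768^2 + 768) + 4 * 768
  total <- nBig + 11 * perLayerBig
  expect_gt(total, 3e7)
  expect_lt(total, 3e8)
})
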