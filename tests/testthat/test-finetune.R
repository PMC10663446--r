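# Finetuning strategies, feature extraction and kNN probing.

smallPretrained <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- lightConfig(nLayers = 2L, hidden = 16L, nHeads = 2L, pathDim = 8L,
                       distDim = 8L, maxPathNodes = 3L, dropout = 0, seed = 1L)
    cache <<- pretrainRun(fixtureCorpus(24L, seed = 41L), cfg, nSteps = 10L,
                          batchSize = 8L, lr = 1e-3, seed = 2L)$model
    cache
  }
})

test_that("the layer-wise learning-rate schedule is exactly geometric", {
  s <- llrdSchedule(3L, 1e-3, 0.5)
  expect_equal(unname(s[c("layer3", "layer2", "layer1")]),
               c(1e-3, 5e-4, 2.5e-4))
  expect_equal(unname(s["head"]), 1e-3)
  expect_equal(unname(s["embedding"]), 1e-3 * 0.5^3)
  # exact geometric ratios at machine precision
  r <- s[paste0("layer", 3:1)]
  expect_identical(unname(r[2] / r[1]), 0.5)
  expect_identical(unname(r[3] / r[2]), 0.5)

  sFlat <- llrdSchedule(4L, 2e-4, 1)
  expect_true(all(sFlat == 2e-4))                      # gamma = 1: no decay
  sAny <- llrdSchedule(6L, 1e-3, 0.83)
  expect_true(all(diff(sAny[paste0("layer", 6:1)]) <= 0))  # non-increasing
  expect_error(llrdSchedule(3L, 1e-3, 0), "gamma")
  expect_error(llrdSchedule(3L, 1e-3, -1), "gamma")
})

test_that("ReInit changes exactly the declared top-layer parameters", {
  m <- smallPretrained()
  L <- m@config$nLayers
  expect_identical(reinitTop(m, 0L)@params, m@params)   # n = 0 is a no-op

  m2 <- reinitTop(m, 1L, seed = 9L)
  for (nm in names(m@params)) {
    grp <- LiGhT:::paramGroup(nm)
    if (grp == paste0("layer", L)) {
      if (!grepl("ln[12]g$", nm))  # fresh layer-norm gains are also 1
        expect_false(identical(m2@params[[nm]], m@params[[nm]]), label = nm)
    } else {
      expect_identical(m2@params[[nm]], m@params[[nm]])  # bitwise audit
    }
  }
  mAll <- reinitTop(m, L, seed = 9L)
  expect_identical(mAll@params$emb.Wv, m@params$emb.Wv)  # embedding untouched
  expect_false(identical(mAll@params$L1.Wq, m@params$L1.Wq))
  expect_error(reinitTop(m, L + 1L), "must lie")
})

test_that("the L2-SP penalty is the squared pull toward the reference", {
  m <- smallPretrained()
  expect_equal(l2spPenalty(m, m, 0.5), 0)               # at the pre-trained point
  expect_equal(l2spPenalty(m, m, 0), 0)
  m2 <- m
  m2@params$L1.Wq[1, 1] <- m@params$L1.Wq[1, 1] + 1
  expect_equal(l2spPenalty(m2, m, 0.5), 0.5)            # 0.5 * (delta = 1)^2
  # the head is excluded
  m3 <- m
  m3@params$pre.node.W2[1, 1] <- m@params$pre.node.W2[1, 1] + 5
  expect_equal(l2spPenalty(m3, m, 1), 0)
  bad <- m
  bad@params$L1.Wq <- bad@params$L1.Wq[, 1:2]
  expect_error(l2spPenalty(bad, m, 1), "shape mismatch")
})

test_that("penalized training stays closer to the reference than unpenalized", {
  eng <- asNamespace("LiGhT")
  m <- smallPretrained()
  cfg <- m@config
  ds <- fixtureLabeledSet(8L, seed = 51L)
  nz <- m@normalizer
  prep1 <- local({
    g <- parseSmiles(ds@smiles[1])
    eng$prepareGraph(augmentWithKNode(toLineGraph(g, cfg$maxPathNodes),
                                      buildKnowledgeVector(g, nz)), cfg)
  })
  head <- initLightModel(lightConfig(nLayers = 1L, hidden = cfg$hidden,
                                     nHeads = 1L, seed = 3L), nTasks = 1L)
  pm0 <- m@params
  for (nm in c("head.W1", "head.b1", "head.W2", "head.b2"))
    pm0[[nm]] <- head@params[[nm]]
  encNorm <- function(pm) {
    tot <- 0
    for (nm in names(pm0)) if (LiGhT:::paramGroup(nm) != "head")
      tot <- tot + sum((pm[[nm]] - pm0[[nm]])^2)
    sqrt(tot)
  }
  run <- function(lambda, steps = 5L) {
    pm <- pm0; state <- NULL; norms <- numeric(steps)
    for (s in seq_len(steps)) {
      grads <- eng$zeroGrads(pm)
      st <- eng$.supervisedGraphStep(prep1, ds@labels[1, ], pm, cfg,
                                     "classification", grads)
      grads <- st$grads
      if (lambda > 0)
        for (nm in names(pm)) if (LiGhT:::paramGroup(nm) != "head")
          grads[[nm]] <- grads[[nm]] + 2 * lambda * (pm[[nm]] - pm0[[nm]])
      upd <- eng$adamStep(pm, grads, state, lr = 1e-2)
      pm <- upd$params; state <- upd$state
      norms[s] <- encNorm(pm)
    }
    norms
  }
  free <- run(0)
  pulled <- run(1)
  expect_true(all(pulled <= free + 1e-12))
})

test_that("FLAG degenerates to the plain step at m = 0 and is norm-bounded", {
  eng <- asNamespace("LiGhT")
  m <- smallPretrained()
  cfg <- m@config
  head <- initLightModel(lightConfig(nLayers = 1L, hidden = cfg$hidden,
                                     nHeads = 1L, seed = 3L), nTasks = 1L)
  for (nm in c("head.W1", "head.b1", "head.W2", "head.b2"))
    m@params[[nm]] <- head@params[[nm]]
  g <- cachedParse("CCOc1ccccc1")
  ag <- augmentWithKNode(toLineGraph(g, cfg$maxPathNodes),
                         buildKnowledgeVector(g, m@normalizer))
  # plain gradients computed through the direct (non-FLAG) code path
  prep <- eng$prepareGraph(ag, cfg)
  fw <- eng$.forwardGraph(prep, m@params, cfg, train = FALSE)
  hc <- eng$.headForward(m@params, "head", fw$pooled)
  lgr <- eng$.supervisedLossGrad(as.numeric(hc$Y), 1, "classification")
  hb <- eng$.headBackward(m@params, "head", hc, lgr$dY, eng$zeroGrads(m@params))
  plain <- eng$.backwardGraph(fw, m@params, cfg, hb$grads,
                              dPooled = as.numeric(hb$dX))$grads
  viaFlag <- flagAugmentedLoss(m, ag, 1, m = 0L, taskType = "classification")
  expectNoDiff(viaFlag$grads, plain, tol = 1e-7)

  # after m steps the perturbation sup-norm is bounded by m * alpha
  for (mm in c(1L, 3L)) {
    r <- flagAugmentedLoss(m, ag, 1, m = mm, alpha = 1e-3)
    expect_lte(max(abs(r$delta)), mm * 1e-3 + 1e-12)
  }
  expect_error(flagAugmentedLoss(m, ag, 1, m = -1L), "m must")
})

test_that("finetuning learns a separable task; feature extraction freezes the encoder", {
  m <- smallPretrained()
  ds <- fixtureLabeledSet(40L, seed = 62L)   # test split holds both classes
  split <- scaffoldSplit(ds, seed = 1L)
  ft <- finetuneConfig(baseLr = 3e-3, epochs = 6L, batchSize = 8L,
                       taskType = "classification", seed = 3L)
  r1 <- finetuneRun(m, ds, split, ft)
  expect_true(is.finite(r1$testMetrics$auroc))
  expect_lt(r1$history$trainLoss[nrow(r1$history)], r1$history$trainLoss[1])

  r1b <- finetuneRun(m, ds, split, ft)
  expect_identical(r1$testMetrics$auroc, r1b$testMetrics$auroc)  # same seed

  fe <- finetuneConfig(mode = "feature_extraction", baseLr = 3e-3,
                       epochs = 2L, batchSize = 8L, seed = 3L)
  r2 <- finetuneRun(m, ds, split, fe)
  for (nm in names(m@params))
    if (LiGhT:::paramGroup(nm) != "head")
      expect_identical(r2$model@params[[nm]], m@params[[nm]], label = nm)
})

test_that("neural fingerprints are row-aligned, deterministic and canonical", {
  m <- smallPretrained()
  smis <- c("CCO", "c1ccccc1", "CCO", "OCC")
  X <- extractNeuralFingerprints(m, smis)
  expect_equal(dim(X), c(4L, m@config$hidden))
  expect_identical(X[1, ], X[3, ])                      # duplicates agree
  expect_equal(unname(X[1, ]), unname(X[4, ]), tolerance = 1e-5)  # respelling
  expect_error(extractNeuralFingerprints(m, c("CCO", "C1CC")), "indices: 2")
})

test_that("kNN voting follows the exact-match, fraction and tie rules", {
  trainX <- matrix(c(0, 0, 1, 1, 2, 2, 3, 3), ncol = 2, byrow = TRUE)
  trainY <- c(1, 1, 0, 0)
  exact <- knnPredict(trainX, trainY, matrix(c(1, 1), 1), k = 1L)
  expect_equal(exact$label, trainY[2])                  # its own label
  expect_equal(exact$prob, 1)
  votes <- knnPredict(trainX, c(1, 1, 0, 1), matrix(c(0.4, 0.4), 1), k = 3L)
  expect_equal(votes$prob, 2 / 3)
  expect_equal(votes$label, 1)
  allSame <- knnPredict(trainX, c(1, 1, 1, 1), matrix(c(9, 9), 1), k = 2L)
  expect_equal(allSame$label, 1)
  expect_error(knnPredict(trainX, trainY, matrix(0, 1, 2), k = 5L), "k must")
})
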