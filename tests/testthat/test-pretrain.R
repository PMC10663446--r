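# Masking plans, corruption, node-type vocabulary, loss terms and the
# pre-training loop.

makeBenzeneAug <- function() {
  augmentWithKNode(cachedLineGraph("c1ccccc1"), zeroKnowledge())
}

test_that("masking statistics match the rate and the 8:1:1 action ratio", {
  lg <- randomToyGraph(100L, 0.04, seed = 2)
  ag <- augmentWithKNode(lg, zeroKnowledge())
  nPlans <- 1000L
  sel <- 0; acts <- c(0, 0, 0); kSel <- 0
  set.seed(123)
  for (i in seq_len(nPlans)) {
    pl <- makeMaskPlan(ag, rate = 0.5)
    sel <- sel + sum(pl@nodeActions != 0L)
    acts <- acts + tabulate(pl@nodeActions[pl@nodeActions != 0L], 3L)
    kSel <- kSel + sum(pl@knowledgeMask)
  }
  fracSel <- sel / (nPlans * 100)
  expect_lt(abs(fracSel - 0.5), 0.01)
  props <- acts / sum(acts)
  expect_lt(abs(props[1] - 0.8), 0.01)
  expect_lt(abs(props[2] - 0.1), 0.01)
  expect_lt(abs(props[3] - 0.1), 0.01)
  expect_lt(abs(kSel / (nPlans * 712) - 0.5), 0.01)
})

test_that("edge rates and plan determinism behave as specified", {
  ag <- makeBenzeneAug()
  p0 <- makeMaskPlan(ag, rate = 0)
  expect_true(all(p0@nodeActions == 0L))
  expect_true(all(p0@knowledgeMask == 0))
  p1 <- makeMaskPlan(ag, rate = 1)
  expect_true(all(p1@nodeActions != 0L))
  a <- makeMaskPlan(ag, rate = 0.5, seed = 42L)
  b <- makeMaskPlan(ag, rate = 0.5, seed = 42L)
  expect_identical(a@nodeActions, b@nodeActions)
  expect_identical(a@knowledgeMask, b@knowledgeMask)
  expect_error(makeMaskPlan(ag, rate = 1.5), "rate")
})

test_that("graph corruption applies MASK/RANDOM/KEEP and knowledge zeroing", {
  ag <- makeBenzeneAug()
  pool <- nodePool(list(augmentWithKNode(cachedLineGraph("CCO"), zeroKnowledge())))

  planKeep <- new("MaskPlan", nodeActions = c(3L, 3L, 0L, 0L, 0L, 0L),
                  knowledgeMask = numeric(712), rate = 0.3, seed = NA_integer_)
  cr <- corruptGraph(ag, planKeep, pool)
  expect_identical(cr$graph@base@xi, ag@base@xi)       # KEEP leaves features
  expect_equal(cr$targets$selected, c(1L, 2L))         # but targets are emitted

  planMask <- new("MaskPlan", nodeActions = c(1L, 0L, 0L, 0L, 0L, 1L),
                  knowledgeMask = rep(1, 712), rate = 0.3, seed = NA_integer_)
  cr2 <- corruptGraph(ag, planMask, pool)
  expect_identical(cr2$graph@maskFlags, c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(cr2$graph@knowledgeMask, rep(1, 712))
  # fully masked knowledge means the K input is zero plus the indicator
  cfg <- tinyConfig()
  m <- initLightModel(cfg, seed = 3L)
  eng <- asNamespace("LiGhT")
  prep <- eng$prepareGraph(cr2$graph, cfg)
  expect_true(all(prep$kIn == 0))
  expect_true(all(prep$kMask == 1))
  # masked rows equal the mask token exactly
  H0 <- embedNodes(cr2$graph, m)
  expect_equal(H0[1, ], m@params$emb.maskToken)

  planRnd <- new("MaskPlan", nodeActions = c(2L, rep(0L, 5)),
                 knowledgeMask = numeric(712), rate = 0.3, seed = NA_integer_)
  cr3 <- corruptGraph(ag, planRnd, pool, seed = 9L)
  expect_false(identical(cr3$graph@base@xe[1, ], ag@base@xe[1, ]))
  expect_error(corruptGraph(ag, planRnd, list()), "batchPool is empty")
})

test_that("node-type vocabulary is unordered-pair exact with UNK fallback", {
  lgs <- list(cachedLineGraph("CC"), cachedLineGraph("C=C"))
  vocab <- buildNodeTypeVocab(lgs)
  expect_equal(vocab$size, 3L)                         # 2 types + UNK
  expect_equal(nodeTypeLabel("C|C|single", vocab),
               nodeTypeLabel(lgs[[1]], vocab, node = 1L))
  expect_equal(nodeTypeLabel("N|O|triple", vocab), vocab$unkId)
  # unordered: swapping the stored endpoint order changes nothing
  lg <- cachedLineGraph("CO")
  sw <- lg
  sw@elemI <- lg@elemJ; sw@elemJ <- lg@elemI
  v2 <- buildNodeTypeVocab(list(lg))
  expect_equal(nodeTypeLabel(sw, v2, node = 1L),
               nodeTypeLabel(lg, v2, node = 1L))
})

test_that("pre-training loss terms match hand-computed values", {
  # perfect predictions -> all terms zero
  km <- c(rep(1, 2), rep(0, 198), rep(1, 3), rep(0, 509))
  target <- c(rep(0.5, 200), rep(1, 3), rep(0, 509))
  scores <- matrix(c(100, 0, 0), 1)
  perfect <- pretrainLosses(scores, 1L,
                            descPred = rep(0.5, 200),
                            fpLogits = c(rep(100, 3), rep(-100, 509)),
                            knowledgeTarget = target, knowledgeMask = km)
  expect_lt(perfect$total, 1e-6)

  # uniform class scores give ln(K) cross-entropy
  K <- 7L
  u <- pretrainLosses(matrix(0, 3, K), c(1L, 3L, 5L),
                      descPred = numeric(200), fpLogits = numeric(512),
                      knowledgeTarget = numeric(712),
                      knowledgeMask = numeric(712))
  expect_equal(u$node_ce, log(K), tolerance = 1e-9)
  expect_equal(u$desc_rmse, 0)                         # no masked entries
  expect_equal(u$fp_ce, 0)

  # two masked descriptors, predictions (1,2) vs targets (3,2) -> rmse sqrt(2)
  km2 <- c(1, 1, rep(0, 710))
  t2 <- c(3, 2, rep(0, 710))
  r <- pretrainLosses(matrix(0, 0, 2), integer(0),
                      descPred = c(1, 2, rep(0, 198)),
                      fpLogits = numeric(512),
                      knowledgeTarget = t2, knowledgeMask = km2)
  expect_equal(r$desc_rmse, sqrt(2), tolerance = 1e-12)
  expect_equal(r$total, sqrt(2))
})

test_that("losses depend only on masked knowledge entries", {
  km <- c(rep(1, 5), rep(0, 195), rep(1, 10), rep(0, 502))
  set.seed(3)
  pred <- rnorm(200); fpl <- rnorm(512)
  t1 <- c(rnorm(200), rbinom(512, 1, 0.3))
  t2 <- t1
  t2[6:200] <- rnorm(195)                              # unmasked descriptors
  t2[200 + 11:512] <- 1 - t2[200 + 11:512]             # unmasked fp bits
  l1 <- pretrainLosses(matrix(0, 0, 2), integer(0), pred, fpl, t1, km)
  l2 <- pretrainLosses(matrix(0, 0, 2), integer(0), pred, fpl, t2, km)
  expect_identical(l1$desc_rmse, l2$desc_rmse)
  expect_identical(l1$fp_ce, l2$fp_ce)
})

test_that("analytic gradients match central differences on a corrupted graph", {
  eng <- asNamespace("LiGhT")
  cfg <- tinyConfig()
  g <- cachedParse("CC(=O)Oc1ccccc1")
  lgr <- toLineGraph(g, cfg$maxPathNodes)
  raw <- computeDescriptors(g)
  nz <- fitNormalizer(rbind(raw, raw * 1.1 + 0.3, raw * 0.9 - 0.2))
  ag <- augmentWithKNode(lgr, buildKnowledgeVector(g, nz))
  plan <- makeMaskPlan(ag, 0.5, seed = 11L)
  vocab <- buildNodeTypeVocab(list(lgr))
  cr <- corruptGraph(ag, plan, nodePool(list(ag)), vocab = vocab, seed = 12L)
  m <- initLightModel(cfg, vocabSize = vocab$size, seed = 7L)
  pm <- m@params
  prep <- eng$prepareGraph(cr$graph, cfg)
  lossOf <- function(p) eng$.pretrainGraphStep(prep, cr$targets, p, cfg,
                                               eng$zeroGrads(p), train = FALSE)$loss$total
  an <- eng$.pretrainGraphStep(prep, cr$targets, pm, cfg, eng$zeroGrads(pm),
                               train = FALSE)$grads
  set.seed(99)
  for (nm in names(pm)) {
    k <- length(pm[[nm]])
    for (ix in if (k <= 2) seq_len(k) else sample.int(k, 2)) {
      eps <- 1e-5
      pp <- pm; pp[[nm]][ix] <- pp[[nm]][ix] + eps
      pn <- pm; pn[[nm]][ix] <- pn[[nm]][ix] - eps
      num <- (lossOf(pp) - lossOf(pn)) / (2 * eps)
      expect_lt(abs(num - an[[nm]][ix]) /
                  max(1e-6, abs(num) + abs(an[[nm]][ix])), 1e-3,
                label = paste0("grad ", nm, "[", ix, "]"))
    }
  }
})

test_that("every parameter bank receives gradient from a generic batch", {
  eng <- asNamespace("LiGhT")
  cfg <- tinyConfig()
  corpus <- lapply(c("CC(=O)Oc1ccccc1", "CCCCN", "c1ccncc1CO"), cachedParse)
  raws <- do.call(rbind, lapply(corpus, computeDescriptors))
  nz <- fitNormalizer(raws)
  lgs <- lapply(corpus, toLineGraph, maxPathNodes = cfg$maxPathNodes)
  # a disconnected line graph exercises the unreachable-pair bias scalars
  a <- lgs[[2]]; b <- lgs[[3]]
  merged <- new("LineGraph", nNodes = a@nNodes + b@nNodes,
                edges = rbind(a@edges, b@edges + a@nNodes),
                xi = rbind(a@xi, b@xi), xj = rbind(a@xj, b@xj),
                xe = rbind(a@xe, b@xe),
                elemI = c(a@elemI, b@elemI), elemJ = c(a@elemJ, b@elemJ),
                bondType = c(a@bondType, b@bondType),
                dist = matrix(integer(0), 0, 0), paths = list(),
                maxPathNodes = a@maxPathNodes, smiles = "merged")
  merged <- allPairsPaths(merged, cfg$maxPathNodes)
  lgs <- c(lgs, list(merged))
  corpus <- c(corpus, corpus[2])   # knowledge vector source for the merged graph
  ags <- lapply(seq_along(corpus), function(i)
    augmentWithKNode(lgs[[i]], buildKnowledgeVector(corpus[[i]], nz)))
  vocab <- buildNodeTypeVocab(lgs)
  m <- initLightModel(cfg, vocabSize = vocab$size, seed = 7L)
  grads <- eng$zeroGrads(m@params)
  pool <- nodePool(ags)
  for (i in seq_along(ags)) {
    plan <- makeMaskPlan(ags[[i]], 0.6, seed = 100L + i)
    cr <- corruptGraph(ags[[i]], plan, pool, vocab = vocab, seed = 200L + i)
    prep <- eng$prepareGraph(cr$graph, cfg)
    grads <- eng$.pretrainGraphStep(prep, cr$targets, m@params, cfg, grads,
                                    train = FALSE)$grads
  }
  dead <- names(grads)[vapply(grads, function(g) all(g == 0), logical(1))]
  expect_length(dead, 0L)
})

test_that("a tiny pre-training run learns and is seed-reproducible", {
  cfg <- lightConfig(nLayers = 1L, hidden = 16L, nHeads = 2L, pathDim = 8L,
                     distDim = 8L, maxPathNodes = 3L, dropout = 0, seed = 1L)
  smis <- fixtureCorpus(16L, seed = 31L)
  r1 <- pretrainRun(smis, cfg, nSteps = 30L, batchSize = 8L, lr = 3e-3, seed = 5L)
  r2 <- pretrainRun(smis, cfg, nSteps = 30L, batchSize = 8L, lr = 3e-3, seed = 5L)
  expect_identical(r1$history$total, r2$history$total)  # same seed, same run
  expect_lt(mean(tail(r1$history$total, 5)), mean(head(r1$history$total, 5)))
  expect_equal(r1$nSkipped, 0L)

  # unparseable corpus entries are skipped and counted
  r3 <- pretrainRun(c(smis[1:6], "C1CC"), cfg, nSteps = 2L, batchSize = 4L,
                    seed = 5L)
  expect_equal(r3$nSkipped, 1L)

  # zero masking rate silences the node term
  r4 <- pretrainRun(smis[1:6], cfg, nSteps = 3L, batchSize = 4L,
                    maskRate = 0, seed = 5L)
  expect_true(all(r4$history$node_ce == 0))
})
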