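# Knowledge-guided masked-graph pre-training: masking plans, graph
# corruption, the node-type vocabulary, the three-term loss, and the
# training loop.

.ACTION_MASK <- 1L
.ACTION_RANDOM <- 2L
.ACTION_KEEP <- 3L

#' Draw a masking plan for one graph
#'
#' Every base node is selected independently with probability `rate`; each
#' selected node is assigned MASK / RANDOM / KEEP with probabilities
#' 0.8 / 0.1 / 0.1. Knowledge entries are masked independently at the same
#' rate (plain masking; the 8:1:1 scheme applies to nodes only). The K node
#' itself is never selected.
#'
#' @param ag an [AugmentedGraph-class].
#' @param rate masking rate in \[0, 1\] (default 0.5, the pre-training
#'   setting for both nodes and knowledge).
#' @param seed optional seed making the plan reproducible.
#' @return a [MaskPlan-class].
#' @export
makeMaskPlan <- function(ag, rate = 0.5, seed = NULL) {
  if (!is.numeric(rate) || rate < 0 || rate > 1)
    stop("rate must lie in [0, 1]", call. = FALSE)
  nb <- ag@base@nNodes
  withSeed(seed, {
    sel <- stats::rbinom(nb, 1L, rate) == 1L
    actions <- integer(nb)
    if (any(sel))
      actions[sel] <- sample(c(.ACTION_MASK, .ACTION_RANDOM, .ACTION_KEEP),
                             sum(sel), replace = TRUE, prob = c(0.8, 0.1, 0.1))
    km <- as.numeric(stats::rbinom(712L, 1L, rate))
    new("MaskPlan", nodeActions = actions, knowledgeMask = km,
        rate = rate, seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  })
}

#' Pool of raw node records for RANDOM replacement
#'
#' @param graphs list of [AugmentedGraph-class] (or [LineGraph-class])
#'   objects forming the current mini-batch.
#' @return list of node records (raw feature triple + type labels).
#' @export
nodePool <- function(graphs) {
  pool <- list()
  for (g in graphs) {
    lg <- if (is(g, "AugmentedGraph")) g@base else g
    for (i in seq_len(lg@nNodes)) {
      pool[[length(pool) + 1L]] <- list(
        xi = lg@xi[i, ], xj = lg@xj[i, ], xe = lg@xe[i, ],
        elemI = lg@elemI[i], elemJ = lg@elemJ[i], bondType = lg@bondType[i])
    }
  }
  pool
}

#' Corrupt a graph according to a masking plan
#'
#' MASK nodes are flagged for replacement by the learned mask token at
#' embedding time; RANDOM nodes get the raw feature triple of a node drawn
#' uniformly from `batchPool`; KEEP nodes stay unchanged but are still
#' predicted. Masked knowledge entries are zeroed on input with a parallel
#' 0/1 indicator channel. Targets record the original node-type keys and the
#' original knowledge vector.
#'
#' @param ag a clean [AugmentedGraph-class].
#' @param plan a [MaskPlan-class] drawn for `ag`.
#' @param batchPool node-record list from [nodePool()]; required when the
#'   plan contains RANDOM actions.
#' @param vocab optional node-type vocabulary; when given, targets include
#'   resolved class ids.
#' @param seed optional seed for the RANDOM replacement draws.
#' @return list with `graph` (corrupted [AugmentedGraph-class]) and
#'   `targets` (selected indices, type keys/labels, original knowledge,
#'   knowledge mask).
#' @export
corruptGraph <- function(ag, plan, batchPool = list(), vocab = NULL, seed = NULL) {
  stopifnot(is(ag, "AugmentedGraph"), is(plan, "MaskPlan"))
  lg <- ag@base
  if (length(plan@nodeActions) != lg@nNodes)
    stop("plan was drawn for a different graph size", call. = FALSE)
  actions <- plan@nodeActions
  rndIdx <- which(actions == .ACTION_RANDOM)
  if (length(rndIdx) > 0L && length(batchPool) == 0L)
    stop("RANDOM actions present but batchPool is empty", call. = FALSE)
  typeKey <- paste0(pmin(lg@elemI, lg@elemJ), "|", pmax(lg@elemI, lg@elemJ),
                    "|", lg@bondType)
  selected <- which(actions != 0L)
  targets <- list(
    selected = selected,
    typeKeys = typeKey[selected],
    labels = if (!is.null(vocab)) nodeTypeLabel(typeKey[selected], vocab) else NULL,
    knowledgeTarget = assembled(ag@knowledge),
    knowledgeMask = plan@knowledgeMask)
  out <- ag
  withSeed(seed, {
    if (length(rndIdx)) {
      picks <- sample.int(length(batchPool), length(rndIdx), replace = TRUE)
      for (q in seq_along(rndIdx)) {
        rec <- batchPool[[picks[q]]]
        i <- rndIdx[q]
        out@base@xi[i, ] <- rec$xi
        out@base@xj[i, ] <- rec$xj
        out@base@xe[i, ] <- rec$xe
        out@base@elemI[i] <- rec$elemI
        out@base@elemJ[i] <- rec$elemJ
        out@base@bondType[i] <- rec$bondType
      }
    }
  })
  out@maskFlags <- actions == .ACTION_MASK
  out@knowledgeMask <- plan@knowledgeMask
  list(graph = out, targets = targets)
}

#' Build the node-type vocabulary from a corpus
#'
#' A line-graph node's "type" is the unordered element pair of its source
#' bond plus the bond type — the minimal label space at bond granularity.
#' Unseen types map to a reserved UNK id.
#'
#' @param graphs list of [LineGraph-class] / [AugmentedGraph-class] objects.
#' @return list with `map` (named integer: key -> id), `unkId`, and `size`
#'   (number of classes including UNK).
#' @export
buildNodeTypeVocab <- function(graphs) {
  keys <- character(0)
  for (g in graphs) {
    lg <- if (is(g, "AugmentedGraph")) g@base else g
    keys <- c(keys, paste0(pmin(lg@elemI, lg@elemJ), "|",
                           pmax(lg@elemI, lg@elemJ), "|", lg@bondType))
  }
  keys <- sort(unique(keys), method = "radix")   # locale-independent order
  map <- stats::setNames(seq_along(keys), keys)
  list(map = map, unkId = length(keys) + 1L, size = length(keys) + 1L)
}

#' Node-type class label
#'
#' @param key node-type key(s) ("elemA|elemB|bondType", elements sorted), or
#'   a [LineGraph-class] together with `node` to label one stored node.
#' @param vocab vocabulary from [buildNodeTypeVocab()].
#' @param node optional node index when `key` is a line graph.
#' @return integer class id(s); unseen types get the UNK id.
#' @export
nodeTypeLabel <- function(key, vocab, node = NULL) {
  if (is(key, "LineGraph") || is(key, "AugmentedGraph")) {
    lg <- if (is(key, "AugmentedGraph")) key@base else key
    stopifnot(!is.null(node))
    key <- paste0(pmin(lg@elemI[node], lg@elemJ[node]), "|",
                  pmax(lg@elemI[node], lg@elemJ[node]), "|", lg@bondType[node])
  }
  id <- unname(vocab$map[key])
  id[is.na(id)] <- vocab$unkId
  id
}

#' Three-term pre-training loss
#'
#' `node_ce`: mean cross-entropy of masked-node type prediction over the
#' selected nodes; `desc_rmse`: root-mean-square error over the masked
#' descriptor entries only; `fp_ce`: mean binary cross-entropy (with logits)
#' over the masked fingerprint entries only. A term with no masked entries is
#' 0 and contributes no gradient. Total is the weighted sum (unit weights by
#' default).
#'
#' @param nodeScores matrix (nSelected x vocabSize) of class scores.
#' @param nodeLabels integer class ids of the original node types.
#' @param descPred numeric length-200 descriptor predictions (K-node head).
#' @param fpLogits numeric length-512 fingerprint logits (K-node head).
#' @param knowledgeTarget numeric length-712 original knowledge vector.
#' @param knowledgeMask numeric 0/1 length-712 mask (1 = masked, in the loss).
#' @param weights numeric length-3 term weights (node, descriptor, fingerprint).
#' @return list of class `PretrainLoss`: `node_ce`, `desc_rmse`, `fp_ce`,
#'   `total`, `weights`.
#' @export
pretrainLosses <- function(nodeScores, nodeLabels, descPred, fpLogits,
                           knowledgeTarget, knowledgeMask,
                           weights = c(1, 1, 1)) {
  nodeCe <- 0
  if (length(nodeLabels) > 0L) {
    if (is.null(dim(nodeScores))) nodeScores <- matrix(nodeScores, nrow = 1L)
    P <- rowSoftmax(nodeScores)
    nodeCe <- -mean(log(pmax(P[cbind(seq_along(nodeLabels), nodeLabels)], 1e-12)))
  }
  descMask <- knowledgeMask[1:200] == 1
  descRmse <- if (any(descMask))
    sqrt(mean((descPred[descMask] - knowledgeTarget[1:200][descMask])^2)) else 0
  fpMask <- knowledgeMask[201:712] == 1
  fpCe <- 0
  if (any(fpMask)) {
    z <- fpLogits[fpMask]
    y <- knowledgeTarget[201:712][fpMask]
    fpCe <- mean(log1pexp(z) - y * z)
  }
  out <- list(node_ce = nodeCe, desc_rmse = descRmse, fp_ce = fpCe,
              total = weights[1] * nodeCe + weights[2] * descRmse + weights[3] * fpCe,
              weights = weights)
  class(out) <- "PretrainLoss"
  out
}

# Copy the corruption state of a corrupted AugmentedGraph onto a cached
# static graph preparation (avoids re-deriving path indices every step).
.applyCorruption <- function(prep, ag) {
  lg <- ag@base
  prep$Xi <- lg@xi; prep$Xj <- lg@xj; prep$Xe <- lg@xe
  prep$maskFlags <- ag@maskFlags
  prep$kIn <- unname(assembled(ag@knowledge) * (1 - ag@knowledgeMask))
  prep$kMask <- unname(ag@knowledgeMask)
  prep
}

# Forward + loss + gradients for one corrupted graph; grads accumulated.
.pretrainGraphStep <- function(prep, targets, pm, cfg, grads, train = TRUE,
                               weights = c(1, 1, 1)) {
  fw <- .forwardGraph(prep, pm, cfg, train = train)
  H <- fw$H
  kRow <- H[prep$N, ]
  sel <- targets$selected
  nodeCache <- NULL
  nodeScores <- matrix(0, 0L, 0L)
  if (length(sel)) {
    nodeCache <- .headForward(pm, "pre.node", H[sel, , drop = FALSE])
    nodeScores <- nodeCache$Y
  }
  descCache <- .headForward(pm, "pre.desc", kRow)
  fpCache <- .headForward(pm, "pre.fp", kRow)
  loss <- pretrainLosses(nodeScores, targets$labels,
                         as.numeric(descCache$Y), as.numeric(fpCache$Y),
                         targets$knowledgeTarget, targets$knowledgeMask,
                         weights)
  # gradients of the three mean-reduced terms
  dNode <- matrix(0, prep$N, cfg$hidden)
  if (length(sel)) {
    P <- rowSoftmax(nodeScores)
    dScores <- P
    dScores[cbind(seq_along(targets$labels), targets$labels)] <-
      dScores[cbind(seq_along(targets$labels), targets$labels)] - 1
    dScores <- weights[1] * dScores / length(sel)
    hb <- .headBackward(pm, "pre.node", nodeCache, dScores, grads)
    grads <- hb$grads
    dNode[sel, ] <- dNode[sel, , drop = FALSE] + hb$dX
  }
  descMask <- targets$knowledgeMask[1:200] == 1
  if (any(descMask) && loss$desc_rmse > 0) {
    dDesc <- numeric(200)
    dDesc[descMask] <- weights[2] *
      (as.numeric(descCache$Y)[descMask] - targets$knowledgeTarget[1:200][descMask]) /
      (sum(descMask) * loss$desc_rmse)
    hb <- .headBackward(pm, "pre.desc", descCache, dDesc, grads)
    grads <- hb$grads
    dNode[prep$N, ] <- dNode[prep$N, ] + as.numeric(hb$dX)
  }
  fpMask <- targets$knowledgeMask[201:712] == 1
  if (any(fpMask)) {
    z <- as.numeric(fpCache$Y)
    dFp <- numeric(512)
    dFp[fpMask] <- weights[3] *
      (stats::plogis(z[fpMask]) - targets$knowledgeTarget[201:712][fpMask]) / sum(fpMask)
    hb <- .headBackward(pm, "pre.fp", fpCache, dFp, grads)
    grads <- hb$grads
    dNode[prep$N, ] <- dNode[prep$N, ] + as.numeric(hb$dX)
  }
  bk <- .backwardGraph(fw, pm, cfg, grads, dNode = dNode)
  list(grads = bk$grads, loss = loss)
}

#' Run knowledge-guided masked-graph pre-training
#'
#' Parses the corpus (unparsable entries are skipped and counted), fits the
#' descriptor normalizer and node-type vocabulary on it, then optimizes the
#' three-term masked-graph objective with decoupled-weight-decay Adam.
#' Fully seeded: two runs with the same seed produce identical losses.
#'
#' @param corpus character vector of SMILES (or a path readable by
#'   [readSmiles()]).
#' @param cfg encoder configuration from [lightConfig()].
#' @param nSteps number of optimizer steps.
#' @param batchSize molecules per step (sampled with replacement when the
#'   corpus is smaller).
#' @param lr,weightDecay Adam learning rate and decoupled weight decay
#'   (reference setting: 2e-4 and 1e-6).
#' @param lrSchedule "constant", or "warmup_cosine" (linear warmup over
#'   `warmupSteps`, then cosine decay to `minLrFrac * lr`) — the usual
#'   stabilizer for short post-norm transformer runs.
#' @param warmupSteps,minLrFrac schedule parameters.
#' @param clipNorm global gradient-norm clip (Inf disables).
#' @param adamBeta1,adamBeta2 Adam moment decays; beta2 below its usual
#'   0.999 adapts faster on short runs.
#' @param tailAverage fraction of final steps whose parameters are averaged
#'   into the returned model (Polyak averaging; 0 disables). Averaging the
#'   tail of a short noisy run returns a lower-variance iterate.
#' @param maskRate masking rate for nodes and knowledge entries.
#' @param weights three loss-term weights.
#' @param seed master seed.
#' @param logFile optional CSV path receiving per-step loss terms.
#' @param verbose print progress every 50 steps.
#' @return list with `model` (a [LiGhTModel-class] carrying normalizer and
#'   vocabulary), `history` (data.frame of per-step losses), `nSkipped`
#'   (unparsable corpus entries) and `graphs` (the augmented training graphs).
#' @export
pretrainRun <- function(corpus, cfg, nSteps = 200L, batchSize = 32L,
                        lr = 2e-4, weightDecay = 1e-6,
                        lrSchedule = c("constant", "warmup_cosine"),
                        warmupSteps = max(1L, nSteps %/% 10L),
                        minLrFrac = 0.1, clipNorm = Inf,
                        adamBeta1 = 0.9, adamBeta2 = 0.999, tailAverage = 0,
                        maskRate = 0.5,
                        weights = c(1, 1, 1), seed = 1L, logFile = NULL,
                        verbose = FALSE) {
  lrSchedule <- match.arg(lrSchedule)
  lrAt <- function(step) {
    if (lrSchedule == "constant") return(lr)
    if (step <= warmupSteps) return(lr * step / warmupSteps)
    frac <- (step - warmupSteps) / max(1L, nSteps - warmupSteps)
    minLrFrac * lr + (1 - minLrFrac) * lr * 0.5 * (1 + cos(pi * frac))
  }
  if (length(corpus) == 1L && file.exists(corpus)) corpus <- readSmiles(corpus)
  parsed <- list(); nSkipped <- 0L
  for (s in corpus) {
    g <- tryCatch(parseSmiles(s), error = function(e) NULL)
    if (is.null(g)) { nSkipped <- nSkipped + 1L; next }
    parsed[[length(parsed) + 1L]] <- g
  }
  if (length(parsed) == 0L) stop("no parseable molecules in corpus", call. = FALSE)
  raw <- do.call(rbind, lapply(parsed, computeDescriptors))
  nz <- fitNormalizer(raw)
  lgs <- lapply(parsed, toLineGraph, maxPathNodes = cfg$maxPathNodes)
  ags <- vector("list", length(parsed))
  for (i in seq_along(parsed)) {
    kv <- new("KnowledgeVector",
              descriptors = applyNormalizer(nz, raw[i, ]),
              fingerprint = computeFingerprint(parsed[[i]]),
              rawDescriptors = unname(raw[i, ]))
    ags[[i]] <- augmentWithKNode(lgs[[i]], kv)
  }
  vocab <- buildNodeTypeVocab(lgs)
  model <- initLightModel(cfg, vocabSize = vocab$size, normalizer = nz,
                          vocab = vocab, seed = seed)
  pm <- model@params
  basePreps <- lapply(ags, prepareGraph, cfg = cfg)
  state <- NULL
  avgFrom <- if (tailAverage > 0) nSteps - ceiling(tailAverage * nSteps) + 1L else NA_integer_
  avgSum <- NULL; avgN <- 0L
  hist <- matrix(0, nSteps, 4L,
                 dimnames = list(NULL, c("node_ce", "desc_rmse", "fp_ce", "total")))
  withSeed(seed, {
    for (step in seq_len(nSteps)) {
      idx <- sample.int(length(ags), batchSize, replace = batchSize > length(ags))
      pool <- nodePool(ags[idx])
      grads <- zeroGrads(pm)
      terms <- c(0, 0, 0, 0)
      for (i in idx) {
        plan <- makeMaskPlan(ags[[i]], rate = maskRate)
        cr <- corruptGraph(ags[[i]], plan, batchPool = pool, vocab = vocab)
        prep <- .applyCorruption(basePreps[[i]], cr$graph)
        st <- .pretrainGraphStep(prep, cr$targets, pm, cfg, grads,
                                 train = cfg$dropout > 0, weights = weights)
        grads <- st$grads
        terms <- terms + c(st$loss$node_ce, st$loss$desc_rmse,
                           st$loss$fp_ce, st$loss$total)
      }
      grads <- lapply(grads, function(g) g / batchSize)
      if (is.finite(clipNorm)) {
        gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
        if (gn > clipNorm) grads <- lapply(grads, function(g) g * clipNorm / gn)
      }
      upd <- adamStep(pm, grads, state, lr = lrAt(step), weightDecay = weightDecay,
                      beta1 = adamBeta1, beta2 = adamBeta2)
      pm <- upd$params; state <- upd$state
      if (!is.na(avgFrom) && step >= avgFrom) {
        avgSum <- if (is.null(avgSum)) pm else mapply(`+`, avgSum, pm, SIMPLIFY = FALSE)
        avgN <- avgN + 1L
      }
      hist[step, ] <- terms / batchSize
      if (verbose && step %% 50L == 0L)
        message("step ", step, " total loss ", signif(hist[step, 4L], 4))
    }
  })
  model@params <- if (avgN > 0L) lapply(avgSum, function(x) x / avgN) else pm
  history <- as.data.frame(hist)
  history$step <- seq_len(nSteps)
  if (!is.null(logFile)) utils::write.csv(history, logFile, row.names = FALSE)
  list(model = model, history = history, nSkipped = nSkipped, graphs = ags)
}

#' Masked-node prediction accuracy on held-out molecules
#'
#' Draws one masking plan per graph, corrupts, predicts the original node
#' types of the selected nodes, and compares accuracy with the
#' majority-class baseline of the evaluation labels.
#'
#' @param model a pre-trained [LiGhTModel-class] (with vocabulary).
#' @param graphs list of clean [AugmentedGraph-class] objects.
#' @param maskRate masking rate for the evaluation plans.
#' @param seed seed for the plans.
#' @param nRepeats independent masking plans drawn per graph (more repeats
#'   tighten the accuracy estimate).
#' @return list with `accuracy`, `majorityBaseline`, `n` (evaluated nodes).
#' @export
evaluateMaskedNodes <- function(model, graphs, maskRate = 0.5, seed = 1L,
                                nRepeats = 1L) {
  cfg <- model@config
  vocab <- model@vocab
  stopIfNot(!is.null(vocab), "model carries no node-type vocabulary")
  correct <- 0L; total <- 0L; labelsAll <- integer(0)
  withSeed(seed, {
    pool <- nodePool(graphs)
    for (ag in rep(graphs, nRepeats)) {
      plan <- makeMaskPlan(ag, rate = maskRate)
      cr <- corruptGraph(ag, plan, batchPool = pool, vocab = vocab)
      if (length(cr$targets$selected) == 0L) next
      prep <- prepareGraph(cr$graph, cfg)
      fw <- .forwardGraph(prep, model@params, cfg, train = FALSE)
      sc <- .headForward(model@params, "pre.node",
                         fw$H[cr$targets$selected, , drop = FALSE])$Y
      pred <- max.col(sc, ties.method = "first")
      correct <- correct + sum(pred == cr$targets$labels)
      total <- total + length(cr$targets$labels)
      labelsAll <- c(labelsAll, cr$targets$labels)
    }
  })
  maj <- if (length(labelsAll)) max(table(labelsAll)) / length(labelsAll) else NA_real_
  list(accuracy = if (total) correct / total else NA_real_,
       majorityBaseline = maj, n = total)
}
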