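# Transfer learning: finetuning strategies (LLRD, ReInit, FLAG, L2-SP),
# feature extraction (neural fingerprints), and kNN probing.

#' Finetuning configuration
#'
#' Strategies are independently switchable. Defaults leave every strategy
#' off; the conventional settings when enabled are `llrdGamma = 0.95`,
#' `reinitTopN = 1`, `flagSteps = 3` with `flagAlpha = 1e-3`, and
#' `l2spLambda = 1e-4`.
#'
#' @param mode "finetune" (encoder trainable) or "feature_extraction"
#'   (encoder frozen; only the head trains).
#' @param baseLr base learning rate (head and top layer).
#' @param llrdGamma layer-wise learning-rate decay factor in (0, 1\];
#'   1 disables LLRD.
#' @param reinitTopN number of top transformer layers to re-initialize.
#' @param flagSteps,flagAlpha FLAG adversarial ascent steps and step size.
#' @param l2spLambda L2-SP pull strength toward the pre-trained encoder.
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param taskType "classification" or "regression".
#' @param nTasks number of label columns.
#' @param weightDecay decoupled Adam weight decay.
#' @param seed seed controlling initialization, batching and dropout.
#' @return a validated list of class `FinetuneConfig`.
#' @export
finetuneConfig <- function(mode = c("finetune", "feature_extraction"),
                           baseLr = 1e-3, llrdGamma = 1, reinitTopN = 0L,
                           flagSteps = 0L, flagAlpha = 1e-3, l2spLambda = 0,
                           epochs = 10L, batchSize = 16L,
                           taskType = c("classification", "regression"),
                           nTasks = 1L, weightDecay = 1e-6, seed = 1L) {
  mode <- match.arg(mode)
  taskType <- match.arg(taskType)
  stopIfNot(llrdGamma > 0 && llrdGamma <= 1, "llrdGamma must lie in (0, 1]")
  stopIfNot(reinitTopN >= 0L, "reinitTopN must be >= 0")
  stopIfNot(flagSteps >= 0L, "flagSteps must be >= 0")
  stopIfNot(flagAlpha > 0, "flagAlpha must be > 0")
  stopIfNot(l2spLambda >= 0, "l2spLambda must be >= 0")
  out <- list(mode = mode, baseLr = baseLr, llrdGamma = llrdGamma,
              reinitTopN = as.integer(reinitTopN),
              flagSteps = as.integer(flagSteps), flagAlpha = flagAlpha,
              l2spLambda = l2spLambda, epochs = as.integer(epochs),
              batchSize = as.integer(batchSize), taskType = taskType,
              nTasks = as.integer(nTasks), weightDecay = weightDecay,
              seed = as.integer(seed))
  class(out) <- "FinetuneConfig"
  out
}

#' Layer-wise learning-rate decay schedule
#'
#' The head and the top transformer layer train at `baseLr`; the i-th layer
#' counted from the top at `baseLr * gamma^i`; the embedding block (node and
#' knowledge embeddings plus the bias banks) at `baseLr * gamma^L`.
#'
#' @param L number of transformer layers.
#' @param baseLr base learning rate.
#' @param gamma multiplicative decay in (0, 1].
#' @return named numeric vector: `head`, `layer<L>` ... `layer1`, `embedding`.
#' @export
llrdSchedule <- function(L, baseLr, gamma) {
  if (!is.numeric(gamma) || gamma <= 0 || gamma > 1)
    stop("gamma must lie in (0, 1]", call. = FALSE)
  rates <- c(head = baseLr,
             stats::setNames(baseLr * gamma^(0:(L - 1)), paste0("layer", L:1)),
             embedding = baseLr * gamma^L)
  rates
}

# Per-parameter learning-rate multipliers realizing the LLRD schedule.
.lrScaleFromSchedule <- function(paramNames, L, gamma) {
  sched <- llrdSchedule(L, 1, gamma)
  out <- vapply(paramNames, function(nm) unname(sched[paramGroup(nm)]), numeric(1))
  stats::setNames(as.list(out), paramNames)
}

#' Re-initialize the top transformer layers
#'
#' Freshly initializes (seeded) every parameter of the top `n` layers;
#' all other parameters are returned bitwise-unchanged.
#'
#' @param model a [LiGhTModel-class].
#' @param n number of top layers to re-initialize (0 = no-op).
#' @param seed seed for the fresh draws.
#' @return the modified [LiGhTModel-class].
#' @export
reinitTop <- function(model, n, seed = 1L) {
  cfg <- model@config
  n <- as.integer(n)
  if (n < 0L || n > cfg$nLayers)
    stop("n must lie in [0, ", cfg$nLayers, "]", call. = FALSE)
  if (n == 0L) return(model)
  fresh <- initLightModel(lightConfig(
    nLayers = cfg$nLayers, hidden = cfg$hidden, nHeads = cfg$nHeads,
    pathDim = cfg$pathDim, distDim = cfg$distDim,
    maxPathNodes = cfg$maxPathNodes, distClip = cfg$distClip,
    dropout = cfg$dropout, dV = cfg$dV, dE = cfg$dE,
    knowledgeDim = cfg$knowledgeDim, seed = as.integer(seed)))
  for (l in (cfg$nLayers - n + 1L):cfg$nLayers) {
    pre <- paste0("L", l, ".")
    for (nm in grep(pre, names(model@params), fixed = TRUE, value = TRUE))
      model@params[[nm]] <- fresh@params[[nm]]
  }
  model
}

#' L2-SP penalty
#'
#' `lambda * sum ||theta - theta_ref||^2` over encoder parameters; heads are
#' excluded (they have no pre-trained reference point).
#'
#' @param model a [LiGhTModel-class] or a flat parameter list.
#' @param reference the pre-trained reference (same form).
#' @param lambda penalty weight.
#' @return numeric scalar.
#' @export
l2spPenalty <- function(model, reference, lambda) {
  pm <- if (is(model, "LiGhTModel")) model@params else model
  ref <- if (is(reference, "LiGhTModel")) reference@params else reference
  if (lambda == 0) return(0)
  tot <- 0
  for (nm in names(pm)) {
    if (paramGroup(nm) == "head") next
    if (is.null(ref[[nm]]) || length(ref[[nm]]) != length(pm[[nm]]))
      stop("parameter shape mismatch at ", nm, call. = FALSE)
    tot <- tot + sum((pm[[nm]] - ref[[nm]])^2)
  }
  lambda * tot
}

# Supervised loss + output gradient for one graph: per-task binary
# cross-entropy with logits (classification) or squared error (regression),
# with missing-label masking. y is a numeric vector (nTasks).
.supervisedLossGrad <- function(yhat, y, taskType) {
  obs <- which(!is.na(y))
  if (length(obs) == 0L) return(list(loss = 0, dY = numeric(length(yhat))))
  z <- yhat[obs]; t <- y[obs]
  if (taskType == "classification") {
    loss <- mean(log1pexp(z) - t * z)
    d <- (stats::plogis(z) - t) / length(obs)
  } else {
    loss <- mean((z - t)^2)
    d <- 2 * (z - t) / length(obs)
  }
  dY <- numeric(length(yhat)); dY[obs] <- d
  list(loss = loss, dY = dY)
}

# One supervised training step on a single graph, with optional FLAG
# adversarial perturbation of the initial node embeddings. Returns the
# (FLAG-averaged) loss and accumulated parameter gradients.
.supervisedGraphStep <- function(prep, y, pm, cfg, taskType, grads,
                                 flagSteps = 0L, flagAlpha = 1e-3,
                                 train = FALSE) {
  nSteps <- max(1L, flagSteps)
  useFlag <- flagSteps > 0L
  delta <- NULL
  lossAcc <- 0
  for (s in seq_len(nSteps)) {
    fw <- .forwardGraph(prep, pm, cfg, train = train, h0Delta = delta)
    hc <- .headForward(pm, "head", fw$pooled)
    lg <- .supervisedLossGrad(as.numeric(hc$Y), y, taskType)
    lossAcc <- lossAcc + lg$loss / nSteps
    stepGrads <- zeroGrads(pm)
    hb <- .headBackward(pm, "head", hc, lg$dY / nSteps, stepGrads)
    bk <- .backwardGraph(fw, pm, cfg, hb$grads, dPooled = as.numeric(hb$dX))
    for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + bk$grads[[nm]]
    if (useFlag && s < nSteps + 1L) {
      # ascent direction from the *unscaled* per-step gradient
      g <- bk$dH0 * nSteps
      nrm <- sqrt(sum(g^2))
      if (is.null(delta)) delta <- matrix(0, nrow(g), ncol(g))
      if (nrm > 0) delta <- delta + flagAlpha * g / nrm
    }
  }
  list(grads = grads, loss = lossAcc, delta = delta)
}

#' FLAG-augmented loss and gradients for one labelled graph
#'
#' Iterative gradient-ascent perturbation of the initial node embeddings:
#' `m` ascent steps of size `alpha` along the normalized loss gradient, with
#' the training loss accumulated as the mean over steps. `m = 0` degenerates
#' to the plain (unaugmented) loss and gradients.
#'
#' @param model a [LiGhTModel-class] with a task head.
#' @param ag an [AugmentedGraph-class].
#' @param y numeric label vector (length nTasks; NA = missing).
#' @param m number of ascent steps.
#' @param alpha ascent step size.
#' @param taskType "classification" or "regression".
#' @return list with `loss`, `grads` (named parameter gradients) and `delta`
#'   (the final perturbation, NULL when `m = 0`).
#' @export
flagAugmentedLoss <- function(model, ag, y, m = 3L, alpha = 1e-3,
                              taskType = "classification") {
  stopIfNot(m >= 0L, "m must be >= 0")
  stopIfNot(alpha > 0, "alpha must be > 0")
  cfg <- model@config
  prep <- prepareGraph(ag, cfg)
  st <- .supervisedGraphStep(prep, y, model@params, cfg, taskType,
                             zeroGrads(model@params),
                             flagSteps = as.integer(m), flagAlpha = alpha,
                             train = FALSE)
  st[c("loss", "grads", "delta")]
}

# Prediction scores for a list of prepared graphs (evaluation mode).
.predictPreps <- function(preps, pm, cfg) {
  out <- matrix(0, length(preps), length(pm$head.b2))
  for (i in seq_along(preps)) {
    fw <- .forwardGraph(preps[[i]], pm, cfg, train = FALSE)
    out[i, ] <- as.numeric(.headForward(pm, "head", fw$pooled)$Y)
  }
  out
}

.selectionMetric <- function(metrics, taskType) {
  if (taskType == "classification") metrics[["auroc"]] else -metrics[["rmse"]]
}

#' Finetune (or feature-extract) a pre-trained model on a labelled dataset
#'
#' Attaches a fresh task head, optionally re-initializes the top layers,
#' then trains with the enabled strategy set (layer-wise learning-rate
#' decay, FLAG augmentation, L2-SP pull toward the pre-trained encoder). In
#' feature-extraction mode every encoder parameter is frozen and only the
#' head trains. The epoch with the best validation metric (AUROC up /
#' RMSE down) is selected and evaluated on the test split.
#'
#' @param model a pre-trained [LiGhTModel-class] (with its normalizer).
#' @param dataset a [LabeledSet-class].
#' @param split a [SplitAssignment-class] over `dataset`.
#' @param ftCfg a [finetuneConfig()] list.
#' @return list with `model` (best-epoch parameters), `validMetrics`,
#'   `testMetrics`, `history` (per-epoch train loss and valid metric) and
#'   `predictions` (test-set scores).
#' @export
finetuneRun <- function(model, dataset, split, ftCfg = finetuneConfig()) {
  stopifnot(is(dataset, "LabeledSet"), is(split, "SplitAssignment"))
  if (length(split@train) == 0L || length(split@valid) == 0L ||
      length(split@test) == 0L)
    stop("empty split", call. = FALSE)
  cfg <- model@config
  nz <- model@normalizer
  stopIfNot(!is.null(nz), "model carries no descriptor normalizer")
  preps <- lapply(dataset@smiles, function(s) {
    g <- parseSmiles(s)
    ag <- augmentWithKNode(toLineGraph(g, cfg$maxPathNodes),
                           buildKnowledgeVector(g, nz))
    prepareGraph(ag, cfg)
  })
  model@params[c("head.W1", "head.b1", "head.W2", "head.b2")] <- NULL
  head <- initLightModel(lightConfig(
    nLayers = 1L, hidden = cfg$hidden, nHeads = 1L, dV = cfg$dV, dE = cfg$dE,
    knowledgeDim = cfg$knowledgeDim, seed = ftCfg$seed),
    nTasks = ftCfg$nTasks)
  pm <- model@params
  for (nm in c("head.W1", "head.b1", "head.W2", "head.b2"))
    pm[[nm]] <- head@params[[nm]]
  if (ftCfg$reinitTopN > 0L) {
    model@params <- pm
    model <- reinitTop(model, ftCfg$reinitTopN, seed = ftCfg$seed + 1L)
    pm <- model@params
  }
  ref <- pm  # L2-SP reference: the starting encoder
  frozen <- if (ftCfg$mode == "feature_extraction")
    setdiff(names(pm), c("head.W1", "head.b1", "head.W2", "head.b2"))
  else character(0)
  lrScale <- if (ftCfg$llrdGamma < 1)
    .lrScaleFromSchedule(names(pm), cfg$nLayers, ftCfg$llrdGamma) else NULL

  Y <- dataset@labels
  state <- NULL
  best <- list(metric = -Inf, params = pm)
  history <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                        validMetric = numeric(0))
  withSeed(ftCfg$seed, {
    for (epoch in seq_len(ftCfg$epochs)) {
      order <- sample(split@train)
      batches <- split(order, ceiling(seq_along(order) / ftCfg$batchSize))
      epochLoss <- 0
      for (batch in batches) {
        grads <- zeroGrads(pm)
        for (i in batch) {
          st <- .supervisedGraphStep(
            preps[[i]], Y[i, ], pm, cfg, ftCfg$taskType, grads,
            flagSteps = ftCfg$flagSteps, flagAlpha = ftCfg$flagAlpha,
            train = cfg$dropout > 0 && ftCfg$mode == "finetune")
          grads <- st$grads
          epochLoss <- epochLoss + st$loss
        }
        grads <- lapply(grads, function(g) g / length(batch))
        if (ftCfg$l2spLambda > 0) {
          for (nm in names(pm)) {
            if (nm %in% frozen || paramGroup(nm) == "head") next
            grads[[nm]] <- grads[[nm]] + 2 * ftCfg$l2spLambda * (pm[[nm]] - ref[[nm]])
          }
        }
        upd <- adamStep(pm, grads, state, lr = ftCfg$baseLr,
                        weightDecay = ftCfg$weightDecay,
                        lrScale = lrScale, frozen = frozen)
        pm <- upd$params; state <- upd$state
      }
      vScores <- .predictPreps(preps[split@valid], pm, cfg)
      vm <- computeMetrics(Y[split@valid, , drop = FALSE], vScores, ftCfg$taskType)
      metric <- .selectionMetric(vm, ftCfg$taskType)
      if (!is.na(metric) && metric > best$metric)
        best <- list(metric = metric, params = pm, validMetrics = vm)
      history[nrow(history) + 1L, ] <- list(epoch, epochLoss / length(split@train),
                                            metric)
    }
  })
  pmBest <- best$params
  tScores <- .predictPreps(preps[split@test], pmBest, cfg)
  tm <- computeMetrics(Y[split@test, , drop = FALSE], tScores, ftCfg$taskType)
  model@params <- pmBest
  list(model = model, validMetrics = best$validMetrics, testMetrics = tm,
       history = history, predictions = tScores)
}

#' Extract neural fingerprints from a frozen encoder
#'
#' Pooled evaluation-mode embeddings of the pre-trained encoder, one row per
#' input molecule (row order preserved). Unparsable SMILES abort with a
#' message listing the offending indices.
#'
#' @param model a pre-trained [LiGhTModel-class] (with its normalizer).
#' @param smiles character vector of molecules.
#' @return numeric matrix (n x hidden).
#' @export
extractNeuralFingerprints <- function(model, smiles) {
  cfg <- model@config
  nz <- model@normalizer
  stopIfNot(!is.null(nz), "model carries no descriptor normalizer")
  failures <- integer(0)
  graphs <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    g <- tryCatch(parseSmiles(smiles[i]), error = function(e) NULL)
    if (is.null(g)) { failures <- c(failures, i); next }
    graphs[[i]] <- g
  }
  if (length(failures))
    stop("unparsable SMILES at indices: ", paste(failures, collapse = ", "),
         call. = FALSE)
  out <- matrix(0, length(smiles), cfg$hidden)
  for (i in seq_along(smiles)) {
    ag <- augmentWithKNode(toLineGraph(graphs[[i]], cfg$maxPathNodes),
                           buildKnowledgeVector(graphs[[i]], nz))
    fw <- .forwardGraph(prepareGraph(ag, cfg), model@params, cfg, train = FALSE)
    out[i, ] <- fw$pooled
  }
  rownames(out) <- smiles
  out
}

#' k-nearest-neighbour prediction on neural fingerprints
#'
#' Euclidean-distance majority vote for binary classification: the returned
#' probability is the fraction of the k nearest training points labelled 1.
#' Neighbour ties at equal distance are broken deterministically by the
#' smaller training index; a split vote predicts the label of the nearest
#' neighbour.
#'
#' @param trainX,testX numeric feature matrices.
#' @param trainY numeric 0/1 training labels.
#' @param k number of neighbours (1 <= k <= nrow(trainX)).
#' @return list with `prob` (vote fractions) and `label` (0/1 predictions).
#' @export
knnPredict <- function(trainX, trainY, testX, k = 5L) {
  trainX <- as.matrix(trainX); testX <- as.matrix(testX)
  n <- nrow(trainX)
  if (k < 1L || k > n) stop("k must lie in [1, nrow(trainX)]", call. = FALSE)
  prob <- numeric(nrow(testX)); label <- numeric(nrow(testX))
  trainSq <- rowSums(trainX^2)
  for (q in seq_len(nrow(testX))) {
    d2 <- trainSq - 2 * as.numeric(trainX %*% testX[q, ]) + sum(testX[q, ]^2)
    ord <- order(d2, seq_len(n))   # distance, then smaller training index
    nb <- ord[seq_len(k)]
    p <- mean(trainY[nb] == 1)
    prob[q] <- p
    label[q] <- if (p > 0.5) 1 else if (p < 0.5) 0 else as.numeric(trainY[nb[1L]] == 1)
  }
  list(prob = prob, label = label)
}
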