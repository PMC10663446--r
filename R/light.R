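# Public LiGhT encoder API: configuration, parameter initialization, node
# embedding, attention biases, transformer layers, readout and heads.

#' LiGhT encoder configuration
#'
#' Defaults follow the reference configuration: 12 transformer layers, 768
#' hidden units, 12 attention heads. Distances feeding the distance encoder
#' are raw hop counts clipped at `distClip`; shortest paths feeding the path
#' encoder are truncated to `maxPathNodes` nodes.
#'
#' @param nLayers number of transformer layers.
#' @param hidden node embedding width (must be divisible by `nHeads`).
#' @param nHeads number of attention heads.
#' @param pathDim path-encoding embedding width.
#' @param distDim distance-encoding hidden width.
#' @param maxPathNodes per-position path-projection bank size.
#' @param distClip hop-count clip for the distance encoder.
#' @param dropout dropout rate on attention weights and FFN hidden units
#'   (training mode only).
#' @param poolIncludeK whether the K node participates in mean pooling.
#' @param recomputeBiasPerLayer recompute A^p/A^d from each layer's hidden
#'   states instead of sharing the matrices computed from the initial
#'   embeddings (off by default, matching the shared-bias reading).
#' @param dV,dE raw atom/bond feature dimensions (from the feature scheme).
#' @param knowledgeDim K-node input dimension (200 descriptors + 512 bits).
#' @param seed seed for parameter initialization.
#' @return a validated configuration list of class `LiGhTConfig`.
#' @export
lightConfig <- function(nLayers = 12L, hidden = 768L, nHeads = 12L,
                        pathDim = 64L, distDim = 64L, maxPathNodes = 5L,
                        distClip = 20L, dropout = 0.1, poolIncludeK = TRUE,
                        recomputeBiasPerLayer = FALSE,
                        dV = defaultFeatureScheme()$Dv,
                        dE = defaultFeatureScheme()$De,
                        knowledgeDim = 712L, seed = 1L) {
  cfg <- list(nLayers = as.integer(nLayers), hidden = as.integer(hidden),
              nHeads = as.integer(nHeads), headDim = as.integer(hidden / nHeads),
              pathDim = as.integer(pathDim), distDim = as.integer(distDim),
              maxPathNodes = as.integer(maxPathNodes),
              distClip = as.integer(distClip), dropout = dropout,
              poolIncludeK = isTRUE(poolIncludeK),
              recomputeBiasPerLayer = isTRUE(recomputeBiasPerLayer),
              dV = as.integer(dV), dE = as.integer(dE),
              knowledgeDim = as.integer(knowledgeDim), seed = as.integer(seed))
  stopIfNot(cfg$hidden %% cfg$nHeads == 0L, "hidden must be divisible by nHeads")
  stopIfNot(cfg$hidden %% 2L == 0L, "hidden must be even")
  stopIfNot(all(unlist(cfg[c("nLayers", "hidden", "nHeads", "pathDim",
                             "distDim", "maxPathNodes")]) > 0),
            "all dimensions must be positive")
  stopIfNot(cfg$dropout >= 0 && cfg$dropout < 1, "dropout must lie in [0, 1)")
  class(cfg) <- "LiGhTConfig"
  cfg
}

#' Initialize a LiGhT model
#'
#' Projection weights are drawn from a truncated normal (sigma = 0.02,
#' resampled beyond two sigma); biases and the learned bias scalars start at
#' zero; layer-norm gains at one. Pre-training heads (node classifier,
#' descriptor and fingerprint heads) are created when `vocabSize` is given;
#' a task head when `nTasks` is given.
#'
#' @param cfg a configuration from [lightConfig()].
#' @param vocabSize node-type vocabulary size (NULL to omit pretrain heads).
#' @param nTasks number of prediction targets (NULL to omit the task head).
#' @param normalizer optional [DescriptorNormalizer-class] stored with the model.
#' @param vocab optional node-type vocabulary stored with the model.
#' @param seed initialization seed; defaults to `cfg$seed`.
#' @return a [LiGhTModel-class].
#' @export
initLightModel <- function(cfg, vocabSize = NULL, nTasks = NULL,
                           normalizer = NULL, vocab = NULL, seed = cfg$seed) {
  D <- cfg$hidden; D2 <- D %/% 2L
  pm <- withSeed(seed, {
    tn <- function(...) {
      d <- c(...)
      array(truncNormal(prod(d)), dim = d)
    }
    mat <- function(a, b) matrix(truncNormal(a * b), a, b)
    p <- list(
      emb.Wv = mat(cfg$dV, D2), emb.bv = numeric(D2),
      emb.We = mat(cfg$dE, D2), emb.be = numeric(D2),
      emb.maskToken = truncNormal(D),
      emb.Wk = mat(cfg$knowledgeDim, D), emb.bk = numeric(D),
      emb.WkMask = mat(cfg$knowledgeDim, D),
      path.Wp = tn(D, cfg$pathDim, cfg$maxPathNodes),
      path.Wa = truncNormal(cfg$pathDim),
      path.kBias = 0, path.unreachBias = 0,
      dist.W1 = truncNormal(cfg$distDim),
      dist.W2 = truncNormal(cfg$distDim),
      dist.kBias = 0, dist.unreachBias = 0)
    for (l in seq_len(cfg$nLayers)) {
      nm <- function(s) paste0("L", l, ".", s)
      p[[nm("Wq")]] <- mat(D, D); p[[nm("bq")]] <- numeric(D)
      p[[nm("Wk")]] <- mat(D, D); p[[nm("bk")]] <- numeric(D)
      p[[nm("Wv")]] <- mat(D, D); p[[nm("bv")]] <- numeric(D)
      p[[nm("ln1g")]] <- rep(1, D); p[[nm("ln1b")]] <- numeric(D)
      p[[nm("W1")]] <- mat(D, 4L * D); p[[nm("b1")]] <- numeric(4L * D)
      p[[nm("W2")]] <- mat(4L * D, D); p[[nm("b2")]] <- numeric(D)
      p[[nm("ln2g")]] <- rep(1, D); p[[nm("ln2b")]] <- numeric(D)
    }
    if (!is.null(vocabSize)) {
      p$pre.node.W1 <- mat(D, D); p$pre.node.b1 <- numeric(D)
      p$pre.node.W2 <- mat(D, as.integer(vocabSize)); p$pre.node.b2 <- numeric(vocabSize)
      p$pre.desc.W1 <- mat(D, D); p$pre.desc.b1 <- numeric(D)
      p$pre.desc.W2 <- mat(D, 200L); p$pre.desc.b2 <- numeric(200L)
      p$pre.fp.W1 <- mat(D, D); p$pre.fp.b1 <- numeric(D)
      p$pre.fp.W2 <- mat(D, 512L); p$pre.fp.b2 <- numeric(512L)
    }
    if (!is.null(nTasks)) {
      p$head.W1 <- mat(D, D); p$head.b1 <- numeric(D)
      p$head.W2 <- mat(D, as.integer(nTasks)); p$head.b2 <- numeric(nTasks)
    }
    p
  })
  new("LiGhTModel", config = unclass(cfg), params = pm,
      normalizer = normalizer, vocab = vocab)
}

#' Initial node embeddings of an augmented graph
#'
#' Base rows follow the node-embedding rule
#' `concat(Wv xi + Wv xj, We xe)` (symmetric in the two endpoint atoms); the
#' K-node row is the projection of the 712-dimensional knowledge vector plus
#' the mask-indicator projection. Masked nodes are replaced by the learned
#' mask token.
#'
#' @param ag an [AugmentedGraph-class].
#' @param model a [LiGhTModel-class].
#' @return numeric matrix (nNodes x hidden).
#' @export
embedNodes <- function(ag, model) {
  cfg <- model@config
  prep <- prepareGraph(ag, cfg)
  stopIfNot(ncol(prep$Xi) == cfg$dV && ncol(prep$Xe) == cfg$dE,
            "feature dimensions do not match the model configuration")
  stopIfNot(length(prep$kIn) == cfg$knowledgeDim,
            "knowledge dimension does not match the model configuration")
  .embedForward(prep, model@params)$H0
}

#' Path-encoding attention bias matrix
#'
#' Each reachable pair's bias is the projection of the mean per-position
#' path embedding of its stored shortest path, evaluated on the initial node
#' embeddings. K-node pairs and unreachable pairs use their dedicated
#' learned scalars.
#'
#' @param ag an [AugmentedGraph-class].
#' @param model a [LiGhTModel-class].
#' @param H0 optional precomputed initial embeddings (from [embedNodes()]).
#' @return numeric matrix (nNodes x nNodes).
#' @export
pathBias <- function(ag, model, H0 = NULL) {
  cfg <- model@config
  prep <- prepareGraph(ag, cfg)
  if (is.null(H0)) H0 <- .embedForward(prep, model@params)$H0
  .pathBiasForward(prep, model@params, H0)$Ap
}

#' Distance-encoding attention bias matrix
#'
#' `a_ij = W2 GELU(W1 d_ij)` on hop counts clipped at the configured bound;
#' K-node pairs and unreachable pairs use their dedicated learned scalars.
#'
#' @inheritParams pathBias
#' @return numeric matrix (nNodes x nNodes).
#' @export
distanceBias <- function(ag, model) {
  cfg <- model@config
  prep <- prepareGraph(ag, cfg)
  .distBiasForward(prep, model@params)$Ad
}

#' One biased multi-head attention block (pre-FFN)
#'
#' Per head: `softmax(Q K' / sqrt(Dh) + A^p + A^d) V`, heads concatenated.
#'
#' @param H node feature matrix entering the layer.
#' @param bias list with components `Ap` and `Ad` (as returned by
#'   [pathBias()] / [distanceBias()]), or a single summed matrix.
#' @param model a [LiGhTModel-class].
#' @param layer layer index.
#' @return the concatenated attention output (same shape as `H`).
#' @export
attentionLayer <- function(H, bias, model, layer) {
  cfg <- model@config
  if (any(!is.finite(H))) stop("non-finite input to attentionLayer", call. = FALSE)
  Apd <- if (is.list(bias)) bias$Ap + bias$Ad else bias
  cache <- .layerForward(H, model@params, layer, cfg, Apd, train = FALSE)
  # return the pre-FFN multi-head output (concat of head outputs)
  D <- cfg$hidden; Nh <- cfg$nHeads; Dh <- D / Nh
  O <- matrix(0, nrow(H), D)
  for (k in seq_len(Nh)) {
    cols <- (k - 1L) * Dh + seq_len(Dh)
    O[, cols] <- cache$Adrop[, , k] %*% cache$V[, cols, drop = FALSE]
  }
  O
}

#' Attention probability tensor of one layer
#'
#' Convenience accessor for tests and diagnostics: the row-stochastic
#' attention matrices of every head at `layer` for input `H`.
#'
#' @inheritParams attentionLayer
#' @return array (n x n x nHeads).
#' @export
attentionWeights <- function(H, bias, model, layer) {
  cfg <- model@config
  Apd <- if (is.list(bias)) bias$Ap + bias$Ad else bias
  .layerForward(H, model@params, layer, cfg, Apd, train = FALSE)$A
}

#' Post-norm residual feed-forward block
#'
#' `Hhat = LN(Hprev + Hattn); out = LN(W2 GELU(W1 Hhat) + Hhat)` — the
#' post-norm residual form, written exactly as the layer update.
#'
#' @param Hprev layer input.
#' @param Hattn multi-head attention output from [attentionLayer()].
#' @param model a [LiGhTModel-class].
#' @param layer layer index.
#' @return layer output matrix (same shape as `Hprev`).
#' @export
ffnBlock <- function(Hprev, Hattn, model, layer) {
  pm <- model@params
  cfg <- model@config
  nm <- function(s) paste0("L", layer, ".", s)
  N <- nrow(Hprev); D <- cfg$hidden
  ln1 <- lnForward(Hprev + Hattn, pm[[nm("ln1g")]], pm[[nm("ln1b")]])
  Hhat <- ln1$Y
  F1 <- Hhat %*% pm[[nm("W1")]] + matrix(pm[[nm("b1")]], N, 4L * D, byrow = TRUE)
  F2 <- gelu(F1) %*% pm[[nm("W2")]] + matrix(pm[[nm("b2")]], N, D, byrow = TRUE)
  lnForward(F2 + Hhat, pm[[nm("ln2g")]], pm[[nm("ln2b")]])$Y
}

#' Full encoder forward pass
#'
#' Stacks the configured transformer layers with the shared path/distance
#' attention biases (computed once from the initial embeddings) and applies
#' mean pooling over the final node embeddings.
#'
#' @param ag an [AugmentedGraph-class].
#' @param model a [LiGhTModel-class].
#' @param training apply dropout (uses the ambient RNG stream).
#' @return list with `nodeEmbeddings` (nNodes x hidden) and `pooled` (hidden).
#' @export
lightForward <- function(ag, model, training = FALSE) {
  cfg <- model@config
  prep <- prepareGraph(ag, cfg)
  fw <- .forwardGraph(prep, model@params, cfg, train = training)
  list(nodeEmbeddings = fw$H, pooled = fw$pooled)
}

#' Apply a prediction head to pooled embeddings
#'
#' Two-layer GELU perceptron producing raw scores: logits for classification
#' tasks (losses apply the link), raw values for regression.
#'
#' @param pooled numeric vector (hidden) or matrix (n x hidden).
#' @param model a [LiGhTModel-class] carrying the requested head.
#' @param head one of "task", "node", "desc", "fp".
#' @return numeric matrix of head outputs (n x nOutputs).
#' @export
predictHead <- function(pooled, model, head = "task") {
  prefix <- switch(head, task = "head", node = "pre.node",
                   desc = "pre.desc", fp = "pre.fp",
                   stop("unknown head: ", head, call. = FALSE))
  if (is.null(model@params[[paste0(prefix, ".W1")]]))
    stop("model has no '", head, "' head", call. = FALSE)
  if (!is.null(dim(pooled)) && ncol(pooled) != model@config$hidden)
    stop("input width does not match the model hidden size", call. = FALSE)
  .headForward(model@params, prefix, pooled)$Y
}

#' Count trainable parameters
#'
#' @param model a [LiGhTModel-class].
#' @return integer total number of scalar parameters.
#' @export
countParameters <- function(model) {
  sum(vapply(model@params, length, numeric(1)))
}

# Parameter-group labels for layer-wise learning rates and ReInit:
# "head" (task + pretrain heads), "layer<k>", or "embedding" (node/knowledge
# embeddings and the path/distance bias banks).
paramGroup <- function(name) {
  if (grepl("^(head|pre)\\.", name)) return("head")
  m <- regmatches(name, regexec("^L([0-9]+)\\.", name))[[1]]
  if (length(m) == 2L) return(paste0("layer", m[2]))
  "embedding"
}

#' Save / load a model checkpoint
#'
#' Versioned JSON archive holding the configuration, every parameter array
#' (with dimensions), and — when present — the descriptor normalizer and the
#' node-type vocabulary, so a checkpoint is loadable across the
#' pre-training, finetuning and extraction entry points.
#'
#' @param model a [LiGhTModel-class].
#' @param path checkpoint file path (JSON).
#' @return `saveCheckpoint` returns `path` invisibly; `loadCheckpoint` the
#'   restored [LiGhTModel-class].
#' @export
saveCheckpoint <- function(model, path) {
  pm <- lapply(model@params, function(x)
    list(dim = dim(x) %||% length(x), data = as.numeric(x)))
  nz <- if (is.null(model@normalizer)) NULL else list(
    location = model@normalizer@location, scale = model@normalizer@scale,
    clipBound = model@normalizer@clipBound, nFitted = model@normalizer@nFitted,
    descriptorNames = model@normalizer@descriptorNames)
  vocab <- model@vocab
  if (!is.null(vocab) && !is.null(vocab$map))
    vocab$map <- as.list(vocab$map)   # named atomic vectors lose names in JSON
  obj <- list(format = "light-checkpoint", version = 1L,
              config = model@config, params = pm, normalizer = nz,
              vocab = vocab)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$format, "light-checkpoint"))
    stop("not a LiGhT checkpoint: ", path, call. = FALSE)
  pm <- lapply(o$params, function(p) {
    d <- as.integer(p$dim)
    if (length(d) > 1L) array(p$data, dim = d) else as.numeric(p$data)
  })
  nz <- NULL
  if (!is.null(o$normalizer))
    nz <- new("DescriptorNormalizer",
              location = o$normalizer$location, scale = o$normalizer$scale,
              clipBound = o$normalizer$clipBound,
              nFitted = as.integer(o$normalizer$nFitted),
              descriptorNames = o$normalizer$descriptorNames)
  vocab <- o$vocab
  if (!is.null(vocab) && !is.null(vocab$map)) {
    vocab$map <- vapply(vocab$map, as.integer, integer(1))
    vocab$unkId <- as.integer(vocab$unkId)
    vocab$size <- as.integer(vocab$size)
  }
  cfg <- o$config
  intFields <- c("nLayers", "hidden", "nHeads", "headDim", "pathDim", "distDim",
                 "maxPathNodes", "distClip", "dV", "dE", "knowledgeDim", "seed")
  for (f in intFields) cfg[[f]] <- as.integer(cfg[[f]])
  new("LiGhTModel", config = cfg, params = pm, normalizer = nz, vocab = vocab)
}
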