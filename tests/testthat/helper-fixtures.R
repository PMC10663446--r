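# Shared fixtures and independent oracles. Parsed molecules are memoized so
# repeated OpenBabel round-trips do not dominate the suite's runtime.

.parseCache <- new.env(parent = emptyenv())

cachedParse <- function(smiles) {
  key <- paste0("p:", smiles)
  if (is.null(.parseCache[[key]])) .parseCache[[key]] <- parseSmiles(smiles)
  .parseCache[[key]]
}

cachedLineGraph <- function(smiles, maxPathNodes = 5L) {
  key <- paste0("lg:", smiles, ":", maxPathNodes)
  if (is.null(.parseCache[[key]]))
    .parseCache[[key]] <- toLineGraph(cachedParse(smiles), maxPathNodes)
  .parseCache[[key]]
}

tinyConfig <- function(...) {
  args <- utils::modifyList(
    list(nLayers = 2L, hidden = 8L, nHeads = 2L, pathDim = 4L,
         distDim = 4L, maxPathNodes = 3L, dropout = 0, seed = 7L),
    list(...))
  do.call(lightConfig, args)
}

# A toy hand-built line graph (no chemistry) with scalar raw features, for
# closed-form checks of the embedding and bias equations.
toyLineGraph <- function(xiPlusXj, xe, edges) {
  n <- length(xiPlusXj)
  lg <- new("LineGraph", nNodes = as.integer(n),
            edges = if (nrow(edges)) matrix(as.integer(edges), ncol = 2L)
                    else matrix(integer(0), 0L, 2L),
            xi = matrix(xiPlusXj / 2, ncol = 1L),
            xj = matrix(xiPlusXj / 2, ncol = 1L),
            xe = matrix(xe, ncol = 1L),
            elemI = rep("C", n), elemJ = rep("C", n),
            bondType = rep("single", n),
            dist = matrix(integer(0), 0L, 0L), paths = list(),
            maxPathNodes = 3L, smiles = "toy")
  allPairsPaths(lg, 3L)
}

zeroKnowledge <- function() {
  new("KnowledgeVector", descriptors = numeric(200),
      fingerprint = numeric(512), rawDescriptors = numeric(200))
}

# Scalar-weight toy model over a 1-dim feature scheme: hidden = 2 so the two
# embedding halves are one coordinate each.
toyModel <- function(wv = 1, we = 0, nLayers = 1L) {
  cfg <- lightConfig(nLayers = nLayers, hidden = 2L, nHeads = 1L,
                     pathDim = 1L, distDim = 1L, maxPathNodes = 3L,
                     dropout = 0, dV = 1L, dE = 1L, seed = 3L)
  m <- initLightModel(cfg, seed = 3L)
  m@params$emb.Wv <- matrix(wv, 1L, 1L)
  m@params$emb.We <- matrix(we, 1L, 1L)
  m@params$emb.bv <- 0
  m@params$emb.be <- 0
  m
}

# Independent Floyd-Warshall oracle on an edge list (1-based, n nodes).
floydWarshall <- function(n, edges) {
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (e in seq_len(nrow(edges))) {
    D[edges[e, 1], edges[e, 2]] <- 1
    D[edges[e, 2], edges[e, 1]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D[is.infinite(D)] <- -1
  D
}

# Brute-force pairwise-concordance AUROC oracle (ties get half credit).
aurocBrute <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (s[p] > s[q]) 1 else if (s[p] == s[q]) 0.5 else 0
  tot / (length(pos) * length(neg))
}

randomToyGraph <- function(n, pEdge, seed) {
  set.seed(seed)
  edges <- which(upper.tri(matrix(0, n, n)) &
                   matrix(runif(n * n) < pEdge, n, n), arr.ind = TRUE)
  toyLineGraph(stats::runif(n, 1, 3), stats::runif(n), edges)
}

# Small deterministic fixture corpus shared across tests.
fixtureCorpus <- function(n = 40L, seed = 11L) generateFixtureMolecules(n, seed)

expectNoDiff <- function(a, b, tol = 0) {
  expect_true(all(names(a) == names(b)))
  for (nm in names(a)) {
    d <- max(abs(a[[nm]] - b[[nm]]))
    if (tol == 0) expect_identical(a[[nm]], b[[nm]], label = nm)
    else expect_lt(d, tol, label = nm)
  }
}
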