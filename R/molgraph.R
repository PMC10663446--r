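# Molecular graph construction: SMILES -> attributed heavy-atom graph ->
# molecular line graph with all-pairs shortest-path structure -> knowledge-
# node augmentation.

#' Default atom/bond featurization scheme
#'
#' Closed one-hot vocabularies with an explicit "other" slot for unknown
#' categories. Atom features: element, heavy-atom degree, formal charge,
#' chirality parity, hybridization, aromaticity, ring membership, implicit
#' hydrogen count. Bond features: bond type, conjugation, ring membership,
#' stereo wedge code.
#'
#' @return a list describing the vocabularies and the resulting feature
#'   dimensions `Dv` (atoms) and `De` (bonds).
#' @export
defaultFeatureScheme <- function() {
  sch <- list(
    elements = c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B", "Si", "other"),
    degrees = 0:6,
    charges = c(-2L, -1L, 0L, 1L, 2L),      # + other slot
    chirality = c(0L, 1L, 2L),              # molfile parity; + other slot
    hybrid = c("sp", "sp2", "sp3", "other"),
    nH = 0:4,                               # capped at 4
    bondTypes = c("single", "double", "triple", "aromatic", "other"),
    bondStereo = c(0L, 1L, 6L)              # none, wedge up, wedge down; + other
  )
  sch$Dv <- length(sch$elements) + length(sch$degrees) + length(sch$charges) + 1L +
    length(sch$chirality) + 1L + length(sch$hybrid) + 2L + length(sch$nH)
  sch$De <- length(sch$bondTypes) + 2L + length(sch$bondStereo) + 1L
  sch
}

oneHot <- function(value, vocab, other = TRUE) {
  v <- numeric(length(vocab) + as.integer(other))
  i <- match(value, vocab)
  if (is.na(i)) { if (other) v[length(v)] <- 1 } else v[i] <- 1
  v
}

# Standard organic valences used to infer implicit hydrogen counts from the
# kekulized bond-order sums; formal charge shifts the valence (N+ -> 4,
# O- -> 1, C- -> 3).
.defaultValence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                     Br = 1, I = 1, B = 3, Si = 4, Se = 2, As = 3, H = 1)

.chargeCode <- function(code) {
  # old-style molfile charge field: 1..7 -> +3,+2,+1,radical,-1,-2,-3
  map <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)
  out <- map[pmin(pmax(as.integer(code), 0L), 7L) + 1L]
  out[is.na(out)] <- 0L
  out
}

.parseMolblock <- function(lines) {
  # minimal V2000 reader for the bond-less single-atom case, which
  # ChemmineR::read.SDFset cannot represent
  counts <- lines[4L]
  na <- as.integer(substr(counts, 1L, 3L))
  nb <- as.integer(substr(counts, 4L, 6L))
  atoms <- lines[5L:(4L + na)]
  elements <- trimws(substr(atoms, 32L, 34L))
  charges <- .chargeCode(trimws(substr(atoms, 37L, 39L)))
  chg <- grep("^M  CHG", lines, value = TRUE)
  for (ln in chg) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    n <- f[1L]
    for (k in seq_len(n)) charges[f[2L * k]] <- f[2L * k + 1L]
  }
  list(nAtoms = na, nBonds = nb, elements = elements, charges = charges)
}

.componentsFromBonds <- function(n, bonds) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1L]; j <- bonds[b, 2L]
      m <- min(comp[i], comp[j])
      if (comp[i] != m || comp[j] != m) {
        comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# Bonds that lie on a cycle (non-bridges); igraph does the bridge finding.
.ringBonds <- function(n, bonds) {
  if (nrow(bonds) == 0L) return(logical(0))
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  inRing <- rep(TRUE, nrow(bonds))
  inRing[igraph::bridges(g)] <- FALSE
  inRing
}

#' Parse a SMILES string into an attributed molecular graph
#'
#' Hydrogens are implicit: only heavy atoms become graph nodes. Multi-fragment
#' inputs (salts, mixtures) are reduced to their largest connected fragment;
#' the number of discarded atoms is recorded in the `nDropped` slot. Atom and
#' bond feature vectors are encoded against the closed vocabularies of
#' `featureScheme`, with unknown categories mapped to an "other" slot.
#'
#' @param smiles a single SMILES string.
#' @param featureScheme vocabulary list from [defaultFeatureScheme()].
#' @return a [MolecularGraph-class].
#' @examples
#' g <- parseSmiles("CC")
#' nAtoms(g)  # 2
#' @export
parseSmiles <- function(smiles, featureScheme = defaultFeatureScheme()) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles)))
    stop("smiles must be a single non-empty string", call. = FALSE)
  smiles <- trimws(smiles)
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n")),
    error = function(e) "")
  if (!nzchar(txt))
    stop("unparsable SMILES: '", smiles, "'", call. = FALSE)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 5L || !grepl("V2000", lines[4L]))
    stop("unparsable SMILES: '", smiles, "'", call. = FALSE)
  mb <- .parseMolblock(lines)
  if (mb$nAtoms < 1L)
    stop("unparsable SMILES (no atoms): '", smiles, "'", call. = FALSE)

  elements <- mb$elements
  charges <- mb$charges
  atomStereo <- integer(mb$nAtoms)
  bonds <- matrix(integer(0), 0L, 2L)
  orders <- numeric(0)
  bondStereo <- integer(0)
  aromAtom <- rep(FALSE, mb$nAtoms)

  if (mb$nBonds > 0L) {
    sdfset <- suppressWarnings(
      tryCatch(ChemmineR::smiles2sdf(stats::setNames(smiles, "m")),
               error = function(e) NULL))
    if (is.null(sdfset) || !ChemmineR::validSDF(sdfset)[1L])
      stop("unparsable SMILES: '", smiles, "'", call. = FALSE)
    sdf <- sdfset[[1L]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    charges <- if ("C6" %in% colnames(ab)) .chargeCode(ab[, "C6"]) else integer(nrow(ab))
    atomStereo <- if ("C7" %in% colnames(ab)) as.integer(ab[, "C7"]) else integer(nrow(ab))
    bonds <- cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]))
    orders <- as.numeric(bb[, 3L])
    bondStereo <- if (ncol(bb) >= 4L) as.integer(bb[, 4L]) else integer(nrow(bb))
    rg <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                   error = function(e) list(RINGS = NULL, AROMATIC = NULL))
    if (length(rg$RINGS)) {
      for (k in seq_along(rg$RINGS)) {
        if (isTRUE(rg$AROMATIC[[k]])) {
          idx <- as.integer(sub("^.*_", "", rg$RINGS[[k]]))
          aromAtom[idx] <- TRUE
        }
      }
    }
  }

  # largest-fragment selection
  nDropped <- 0L
  if (mb$nAtoms > 1L) {
    comp <- .componentsFromBonds(mb$nAtoms, bonds)
    tab <- table(comp)
    keepComp <- as.integer(names(tab)[which.max(tab)])
    keep <- which(comp == keepComp)
    nDropped <- mb$nAtoms - length(keep)
    if (nDropped > 0L) {
      remap <- integer(mb$nAtoms); remap[keep] <- seq_along(keep)
      elements <- elements[keep]; charges <- charges[keep]
      atomStereo <- atomStereo[keep]; aromAtom <- aromAtom[keep]
      bkeep <- bonds[, 1L] %in% keep & bonds[, 2L] %in% keep
      bonds <- matrix(remap[bonds[bkeep, , drop = FALSE]], ncol = 2L)
      orders <- orders[bkeep]; bondStereo <- bondStereo[bkeep]
    }
  }
  n <- length(elements)
  nb <- nrow(bonds)

  # derived annotations
  degree <- integer(n)
  orderSum <- numeric(n)
  nDouble <- integer(n); nTriple <- integer(n)
  for (b in seq_len(nb)) {
    for (a in bonds[b, ]) {
      degree[a] <- degree[a] + 1L
      orderSum[a] <- orderSum[a] + orders[b]
      if (orders[b] == 2) nDouble[a] <- nDouble[a] + 1L
      if (orders[b] == 3) nTriple[a] <- nTriple[a] + 1L
    }
  }
  defv <- .defaultValence[elements]
  defv[is.na(defv)] <- degree[is.na(defv)]       # exotic elements: no implicit H
  nH <- pmax(0L, as.integer(round(defv + charges - orderSum)))
  hybrid <- ifelse(nTriple > 0L | nDouble >= 2L, "sp",
            ifelse(nDouble > 0L | aromAtom, "sp2",
            ifelse(elements %in% c("C", "N", "O", "S", "P", "B", "Si"), "sp3", "other")))
  bondRing <- .ringBonds(n, bonds)
  atomRing <- rep(FALSE, n)
  if (nb > 0L) for (b in which(bondRing)) atomRing[bonds[b, ]] <- TRUE
  bondArom <- if (nb > 0L) aromAtom[bonds[, 1L]] & aromAtom[bonds[, 2L]] & bondRing else logical(0)
  bondType <- if (nb > 0L)
    ifelse(bondArom, "aromatic",
           c("single", "double", "triple")[pmin(pmax(orders, 1), 3)])
  else character(0)
  # conjugation heuristic: both endpoints sp/sp2
  sp2ish <- hybrid %in% c("sp", "sp2")
  bondConj <- if (nb > 0L) sp2ish[bonds[, 1L]] & sp2ish[bonds[, 2L]] else logical(0)

  sch <- featureScheme
  atomFeatures <- t(vapply(seq_len(n), function(a) {
    c(oneHot(elements[a], sch$elements, other = FALSE),
      oneHot(min(degree[a], max(sch$degrees)), sch$degrees, other = FALSE),
      oneHot(charges[a], sch$charges),
      oneHot(atomStereo[a], sch$chirality),
      oneHot(hybrid[a], sch$hybrid, other = FALSE),
      as.numeric(aromAtom[a]),
      as.numeric(atomRing[a]),
      oneHot(min(nH[a], max(sch$nH)), sch$nH, other = FALSE))
  }, numeric(sch$Dv)))
  if (n == 1L) atomFeatures <- matrix(atomFeatures, nrow = 1L)
  bondFeatures <- matrix(0, nb, sch$De)
  for (b in seq_len(nb)) {
    bondFeatures[b, ] <- c(oneHot(bondType[b], sch$bondTypes, other = FALSE),
                           as.numeric(bondConj[b]),
                           as.numeric(bondRing[b]),
                           oneHot(bondStereo[b], sch$bondStereo))
  }

  g <- new("MolecularGraph",
    smiles = "",
    elements = elements, charges = as.integer(charges),
    aromatic = aromAtom, inRing = atomRing, nH = as.integer(nH),
    hybrid = hybrid,
    bonds = bonds, bondOrders = orders,
    bondAromatic = as.logical(bondArom), bondInRing = as.logical(bondRing),
    bondStereo = as.integer(bondStereo),
    atomFeatures = atomFeatures, bondFeatures = bondFeatures,
    nDropped = nDropped)
  g@smiles <- canonicalFromGraph(g)
  validObject(g)
  g
}

# V2000 molblock text for a (sub)graph; used for canonicalization and
# Murcko scaffolds.
molblockFromParts <- function(elements, charges, bonds, orders) {
  n <- length(elements); nb <- nrow(bonds)
  out <- c("", " LiGhT", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (a in seq_len(n))
    out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          0, 0, 0, elements[a]))
  for (b in seq_len(nb))
    out <- c(out, sprintf("%3d%3d%3d  0  0  0  0",
                          bonds[b, 1L], bonds[b, 2L], as.integer(round(orders[b]))))
  chg <- which(charges != 0L)
  for (a in chg)
    out <- c(out, sprintf("M  CHG%3d%4d%4d", 1L, a, charges[a]))
  c(out, "M  END", "$$$$")
}

canonicalFromParts <- function(elements, charges, bonds, orders) {
  txt <- paste(molblockFromParts(elements, charges, bonds, orders), collapse = "\n")
  can <- tryCatch(ChemmineOB::convertFormat("SDF", "CAN", txt), error = function(e) "")
  sub("[\t\n].*$", "", can)
}

# Canonical SMILES of a MolecularGraph via OpenBabel.
canonicalFromGraph <- function(g) {
  canonicalFromParts(g@elements, g@charges, g@bonds, g@bondOrders)
}

#' Transform a molecular graph into its line graph
#'
#' One line-graph node per chemical bond; two nodes are adjacent iff their
#' source bonds share an atom. Each node stores the raw feature triple
#' (endpoint atom features, bond features) consumed by the node-embedding
#' layer. Distances and shortest paths are populated by [allPairsPaths()].
#'
#' A bond-less molecule (single heavy atom) yields a one-node line graph whose
#' node stores the atom's features twice and an all-zero bond vector, so every
#' molecule stays encodable.
#'
#' @param g a [MolecularGraph-class].
#' @param maxPathNodes truncation length for stored shortest paths.
#' @return a [LineGraph-class] with `dist` and `paths` filled.
#' @examples
#' lg <- toLineGraph(parseSmiles("CCC"))
#' nNodes(lg)  # 2 bonds -> 2 nodes
#' @export
toLineGraph <- function(g, maxPathNodes = 5L) {
  stopifnot(is(g, "MolecularGraph"))
  nb <- nBonds(g)
  if (nb == 0L) {
    lg <- new("LineGraph",
      nNodes = 1L, edges = matrix(integer(0), 0L, 2L),
      xi = g@atomFeatures[1L, , drop = FALSE],
      xj = g@atomFeatures[1L, , drop = FALSE],
      xe = matrix(0, 1L, ncol(g@bondFeatures)),
      elemI = g@elements[1L], elemJ = g@elements[1L], bondType = "none",
      dist = matrix(0L, 1L, 1L), paths = list(list(1L)),
      maxPathNodes = as.integer(maxPathNodes), smiles = g@smiles)
    validObject(lg)
    return(lg)
  }
  edges <- matrix(integer(0), 0L, 2L)
  incident <- vector("list", nAtoms(g))
  for (b in seq_len(nb)) for (a in g@bonds[b, ]) incident[[a]] <- c(incident[[a]], b)
  el <- list()
  for (a in seq_len(nAtoms(g))) {
    inc <- incident[[a]]
    if (length(inc) >= 2L) {
      pr <- utils::combn(sort(inc), 2L)
      el[[length(el) + 1L]] <- t(pr)
    }
  }
  if (length(el)) {
    edges <- unique(do.call(rbind, el))
    storage.mode(edges) <- "integer"
  }
  bt <- ifelse(g@bondAromatic, "aromatic",
               c("single", "double", "triple")[pmin(pmax(g@bondOrders, 1), 3)])
  lg <- new("LineGraph",
    nNodes = nb, edges = edges,
    xi = g@atomFeatures[g@bonds[, 1L], , drop = FALSE],
    xj = g@atomFeatures[g@bonds[, 2L], , drop = FALSE],
    xe = g@bondFeatures,
    elemI = g@elements[g@bonds[, 1L]],
    elemJ = g@elements[g@bonds[, 2L]],
    bondType = bt,
    dist = matrix(integer(0), 0L, 0L), paths = list(),
    maxPathNodes = as.integer(maxPathNodes), smiles = g@smiles)
  allPairsPaths(lg, maxPathNodes)
}

#' All-pairs shortest paths of a line graph
#'
#' Breadth-first search from every node; unreachable pairs get hop count -1
#' and a NULL path. When several shortest paths exist, the tie is broken
#' canonically by the lexicographic order of the node-feature keys along the
#' path (with the smaller node index as the final fallback): the selection
#' depends only on node content, so the path-encoding bias is invariant
#' under node relabelling. Stored paths are truncated to their first
#' `maxPathNodes` nodes.
#'
#' @param lg a [LineGraph-class] with nodes and edges set.
#' @param maxPathNodes maximum number of nodes retained per stored path.
#' @return the line graph with `dist` and `paths` populated.
#' @export
allPairsPaths <- function(lg, maxPathNodes = 5L) {
  stopifnot(is(lg, "LineGraph"))
  n <- lg@nNodes
  adj <- vector("list", n)
  for (e in seq_len(nrow(lg@edges))) {
    i <- lg@edges[e, 1L]; j <- lg@edges[e, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  # canonical per-node key: the content that enters the path encoder
  key <- vapply(seq_len(n), function(i)
    paste(signif(c(lg@xi[i, ] + lg@xj[i, ], lg@xe[i, ]), 6), collapse = ","),
    character(1))
  dist <- matrix(-1L, n, n)
  paths <- vector("list", n)
  for (s in seq_len(n)) {
    d <- rep(-1L, n)
    d[s] <- 0L
    queue <- s; head <- 1L
    while (head <= length(queue)) {
      u <- queue[head]; head <- head + 1L
      for (v in adj[[u]]) {
        if (d[v] < 0L) { d[v] <- d[u] + 1L; queue <- c(queue, v) }
      }
    }
    dist[s, ] <- d
    parent <- rep(NA_integer_, n)
    pathKey <- character(n)
    pathKey[s] <- key[s]
    for (lev in seq_len(max(d))) {
      for (v in which(d == lev)) {
        preds <- adj[[v]][d[adj[[v]]] == lev - 1L]
        best <- preds[order(pathKey[preds], preds, method = "radix")][1L]
        parent[v] <- best
        pathKey[v] <- paste0(pathKey[best], "|", key[v])
      }
    }
    ps <- vector("list", n)
    for (t in seq_len(n)) {
      if (d[t] < 0L) next
      p <- t
      while (p[1L] != s) p <- c(parent[p[1L]], p)
      if (length(p) > maxPathNodes) p <- p[seq_len(maxPathNodes)]
      ps[[t]] <- p
    }
    paths[[s]] <- ps
  }
  lg@dist <- dist
  lg@paths <- paths
  lg@maxPathNodes <- as.integer(maxPathNodes)
  validObject(lg)
  lg
}

#' Append the knowledge node to a line graph
#'
#' Adds a single extra node connected to every base node. The base
#' shortest-path structure is left untouched: attention-bias entries for
#' K-node pairs use dedicated learned scalars rather than the path/distance
#' encoders, so the K node's universal connectivity cannot shortcut the
#' structural encoding.
#'
#' @param lg a [LineGraph-class].
#' @param kv a [KnowledgeVector-class] for the molecule.
#' @return an [AugmentedGraph-class].
#' @export
augmentWithKNode <- function(lg, kv) {
  if (is(lg, "AugmentedGraph"))
    stop("graph is already augmented with a knowledge node", call. = FALSE)
  stopifnot(is(lg, "LineGraph"))
  if (!is(kv, "KnowledgeVector"))
    stop("kv must be a KnowledgeVector", call. = FALSE)
  if (length(assembled(kv)) != 712L)
    stop("knowledge dimension mismatch: expected 712", call. = FALSE)
  if (length(lg@dist) == 0L)
    lg <- allPairsPaths(lg, lg@maxPathNodes)
  ag <- new("AugmentedGraph",
    base = lg, knowledge = kv, kIndex = lg@nNodes + 1L,
    maskFlags = rep(FALSE, lg@nNodes),
    knowledgeMask = numeric(712L))
  validObject(ag)
  ag
}

#' Serialize a molecular graph to JSON (and back)
#'
#' A documented plain-text form for fixtures and tests: elements, charges,
#' bonds with orders, annotation vectors, and the encoded feature matrices.
#'
#' @param g a [MolecularGraph-class].
#' @param path output file.
#' @return `graphToJson` returns `path` invisibly; `graphFromJson` returns
#'   the reconstructed [MolecularGraph-class].
#' @export
graphToJson <- function(g, path) {
  stopifnot(is(g, "MolecularGraph"))
  obj <- list(
    smiles = g@smiles, elements = g@elements, charges = g@charges,
    aromatic = g@aromatic, inRing = g@inRing, nH = g@nH, hybrid = g@hybrid,
    bonds = g@bonds, bondOrders = g@bondOrders,
    bondAromatic = g@bondAromatic, bondInRing = g@bondInRing,
    bondStereo = g@bondStereo,
    atomFeatures = g@atomFeatures, bondFeatures = g@bondFeatures,
    nDropped = g@nDropped)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname graphToJson
#' @export
graphFromJson <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  sch <- defaultFeatureScheme()
  asMat <- function(m, nc) {
    if (length(m) == 0L) return(matrix(numeric(0), 0L, nc))
    m <- as.matrix(m)
    if (ncol(m) == 1L && nc > 1L) m <- t(m)
    m
  }
  bonds <- asMat(o$bonds, 2L)
  storage.mode(bonds) <- "integer"
  af <- asMat(o$atomFeatures, sch$Dv)
  g <- new("MolecularGraph",
    smiles = o$smiles, elements = o$elements, charges = as.integer(o$charges),
    aromatic = as.logical(o$aromatic), inRing = as.logical(o$inRing),
    nH = as.integer(o$nH), hybrid = o$hybrid,
    bonds = bonds, bondOrders = as.numeric(o$bondOrders),
    bondAromatic = as.logical(o$bondAromatic),
    bondInRing = as.logical(o$bondInRing),
    bondStereo = as.integer(o$bondStereo),
    atomFeatures = af,
    bondFeatures = asMat(o$bondFeatures, sch$De),
    nDropped = as.integer(o$nDropped))
  validObject(g)
  g
}

#' Read SMILES from a .smi file or a CSV with a `smiles` column
#'
#' @param path input file; `.smi` files hold one SMILES per line (anything
#'   after the first whitespace is treated as a name and dropped), other
#'   extensions are read as CSV.
#' @return character vector of SMILES strings.
#' @export
readSmiles <- function(path) {
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    sub("\\s.*$", "", trimws(lines))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"smiles" %in% names(df))
      stop("CSV input must contain a 'smiles' column", call. = FALSE)
    as.character(df$smiles)
  }
}
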