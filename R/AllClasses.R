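#' @import methods
NULL

#' MolecularGraph: an attributed heavy-atom molecular graph
#'
#' Nodes are heavy atoms, edges are chemical bonds. Atom and bond attributes
#' are stored both as raw chemical annotations (element, charge, aromaticity,
#' implicit hydrogens, ring membership, bond order) and as fixed-length
#' one-hot feature vectors used by the encoder.
#'
#' @slot smiles canonical SMILES of the (largest-fragment) molecule.
#' @slot elements character vector of element symbols, one per atom.
#' @slot charges integer formal charges per atom.
#' @slot aromatic logical per-atom aromaticity flags.
#' @slot inRing logical per-atom ring membership.
#' @slot nH integer implicit hydrogen counts per atom.
#' @slot hybrid character per-atom hybridization ("sp", "sp2", "sp3", "other").
#' @slot bonds integer matrix (nBonds x 2) of 1-based atom indices.
#' @slot bondOrders numeric bond orders (1, 2, 3; kekulized aromatic rings
#'   keep their alternating 1/2 orders).
#' @slot bondAromatic logical per-bond aromaticity flags.
#' @slot bondInRing logical per-bond ring membership.
#' @slot bondStereo integer molfile stereo code per bond (0 none).
#' @slot atomFeatures numeric matrix (nAtoms x Dv) of encoded atom features.
#' @slot bondFeatures numeric matrix (nBonds x De) of encoded bond features.
#' @slot nDropped integer count of atoms discarded with non-largest fragments.
#' @export
setClass("MolecularGraph",
  representation(
    smiles = "character",
    elements = "character",
    charges = "integer",
    aromatic = "logical",
    inRing = "logical",
    nH = "integer",
    hybrid = "character",
    bonds = "matrix",
    bondOrders = "numeric",
    bondAromatic = "logical",
    bondInRing = "logical",
    bondStereo = "integer",
    atomFeatures = "matrix",
    bondFeatures = "matrix",
    nDropped = "integer"
  )
)

setValidity("MolecularGraph", function(object) {
  n <- length(object@elements)
  nb <- nrow(object@bonds)
  msg <- character(0)
  if (nrow(object@atomFeatures) != n) msg <- c(msg, "atomFeatures rows != nAtoms")
  if (nb > 0) {
    if (any(object@bonds < 1L) || any(object@bonds > n))
      msg <- c(msg, "bond atom indices out of range")
    key <- paste(pmin(object@bonds[, 1], object@bonds[, 2]),
                 pmax(object@bonds[, 1], object@bonds[, 2]))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate unordered bond pairs")
  }
  if (nrow(object@bondFeatures) != nb) msg <- c(msg, "bondFeatures rows != nBonds")
  if (length(msg)) msg else TRUE
})

#' LineGraph: the molecular line graph of a MolecularGraph
#'
#' One node per chemical bond; two nodes are adjacent iff their source bonds
#' share an atom. Carries the all-pairs shortest-path structure (hop counts
#' and explicit node sequences) computed by breadth-first search with
#' deterministic ascending-neighbor tie-breaking.
#'
#' @slot nNodes integer number of line-graph nodes.
#' @slot edges integer matrix (m x 2) of 1-based unordered node pairs.
#' @slot xi,xj numeric matrices (nNodes x Dv): raw atom feature vectors of the
#'   two endpoints of each source bond.
#' @slot xe numeric matrix (nNodes x De): raw bond feature vector per node.
#' @slot elemI,elemJ character endpoint element symbols per node.
#' @slot bondType character bond-type label per node (for the node-type vocabulary).
#' @slot dist integer matrix of shortest-path hop counts; -1 marks unreachable pairs.
#' @slot paths list of lists: \code{paths[[i]][[j]]} is the integer node
#'   sequence of the shortest i->j path (possibly truncated), or NULL when
#'   unreachable or paths have not been populated.
#' @slot maxPathNodes integer truncation length used when populating paths.
#' @slot smiles canonical SMILES of the source molecule.
#' @export
setClass("LineGraph",
  representation(
    nNodes = "integer",
    edges = "matrix",
    xi = "matrix",
    xj = "matrix",
    xe = "matrix",
    elemI = "character",
    elemJ = "character",
    bondType = "character",
    dist = "matrix",
    paths = "list",
    maxPathNodes = "integer",
    smiles = "character"
  )
)

setValidity("LineGraph", function(object) {
  n <- object@nNodes
  msg <- character(0)
  if (n < 1L) msg <- c(msg, "line graph must have at least one node")
  if (nrow(object@xi) != n || nrow(object@xj) != n || nrow(object@xe) != n)
    msg <- c(msg, "raw feature triples must have one row per node")
  if (nrow(object@edges) > 0 && (any(object@edges < 1L) || any(object@edges > n)))
    msg <- c(msg, "edge indices out of range")
  if (length(object@dist) > 0) {
    if (!identical(dim(object@dist), c(n, n))) msg <- c(msg, "dist must be nNodes x nNodes")
    else {
      if (any(diag(object@dist) != 0L)) msg <- c(msg, "dist diagonal must be zero")
      if (!identical(object@dist, t(object@dist))) msg <- c(msg, "dist must be symmetric")
    }
  }
  if (length(msg)) msg else TRUE
})

#' KnowledgeVector: descriptor + fingerprint features for the knowledge node
#'
#' @slot descriptors numeric length-200 normalized descriptor block (finite).
#' @slot fingerprint numeric length-512 binary fingerprint block.
#' @slot rawDescriptors numeric length-200 pre-normalization descriptor values
#'   (may contain non-finite entries where a descriptor is undefined).
#' @export
setClass("KnowledgeVector",
  representation(
    descriptors = "numeric",
    fingerprint = "numeric",
    rawDescriptors = "numeric"
  )
)

setValidity("KnowledgeVector", function(object) {
  msg <- character(0)
  if (length(object@descriptors) != 200L) msg <- c(msg, "descriptor block must have length 200")
  if (length(object@fingerprint) != 512L) msg <- c(msg, "fingerprint block must have length 512")
  if (!all(object@fingerprint %in% c(0, 1))) msg <- c(msg, "fingerprint entries must be 0/1")
  if (any(!is.finite(object@descriptors))) msg <- c(msg, "normalized descriptors must be finite")
  if (length(msg)) msg else TRUE
})

#' AugmentedGraph: a LineGraph plus its knowledge node
#'
#' The knowledge node (K node) is appended after the base nodes, connected to
#' every base node, and excluded from the base shortest-path structure. Slots
#' \code{maskFlags}/\code{knowledgeMask} carry the corruption state used
#' during masked-graph pre-training (all zero for clean graphs).
#'
#' @slot base the underlying [LineGraph-class].
#' @slot knowledge the [KnowledgeVector-class] attached to the K node.
#' @slot kIndex integer index of the K node (always \code{nNodes(base) + 1}).
#' @slot maskFlags logical per-base-node flags; TRUE rows are replaced by the
#'   learned mask token at embedding time.
#' @slot knowledgeMask numeric 0/1 vector (length 712) marking masked
#'   knowledge entries (zeroed on input, signalled via an indicator channel).
#' @export
setClass("AugmentedGraph",
  representation(
    base = "LineGraph",
    knowledge = "KnowledgeVector",
    kIndex = "integer",
    maskFlags = "logical",
    knowledgeMask = "numeric"
  )
)

setValidity("AugmentedGraph", function(object) {
  msg <- character(0)
  if (object@kIndex != object@base@nNodes + 1L)
    msg <- c(msg, "kIndex must equal nNodes(base) + 1")
  if (length(object@maskFlags) != object@base@nNodes)
    msg <- c(msg, "maskFlags must have one entry per base node")
  if (length(object@knowledgeMask) != 712L)
    msg <- c(msg, "knowledgeMask must have length 712")
  if (length(msg)) msg else TRUE
})

#' DescriptorNormalizer: robust per-descriptor affine standardization
#'
#' Location is the per-descriptor median over finite corpus entries; scale is
#' a normal-consistent interquartile-range estimate (IQR / 1.349), with
#' degenerate (constant) descriptors assigned scale 1. Transformed values are
#' clipped at \code{clipBound} z-score units and non-finite inputs map to 0.
#'
#' @slot location,scale numeric length-200 statistics.
#' @slot clipBound numeric clip bound in z-score units.
#' @slot nFitted integer number of corpus vectors the normalizer was fit on.
#' @slot descriptorNames character length-200 descriptor registry names.
#' @export
setClass("DescriptorNormalizer",
  representation(
    location = "numeric",
    scale = "numeric",
    clipBound = "numeric",
    nFitted = "integer",
    descriptorNames = "character"
  )
)

setValidity("DescriptorNormalizer", function(object) {
  msg <- character(0)
  if (length(object@location) != length(object@scale))
    msg <- c(msg, "location/scale lengths differ")
  if (any(object@scale <= 0)) msg <- c(msg, "scales must be positive")
  if (object@clipBound <= 0) msg <- c(msg, "clipBound must be positive")
  if (length(msg)) msg else TRUE
})

#' LiGhTModel: parameter bundle for the line-graph transformer
#'
#' Parameters live in a flat named list of numeric arrays (see
#' \code{\link{initLightModel}} for the naming scheme); the configuration is
#' the list produced by \code{\link{lightConfig}}. A model optionally carries
#' the descriptor normalizer and the node-type vocabulary it was pre-trained
#' with, so checkpoints are self-contained.
#'
#' @slot config list from [lightConfig()].
#' @slot params flat named list of numeric arrays.
#' @slot normalizer a [DescriptorNormalizer-class] or NULL.
#' @slot vocab node-type vocabulary list (see [buildNodeTypeVocab()]) or NULL.
#' @export
setClass("LiGhTModel",
  representation(
    config = "list",
    params = "list",
    normalizer = "ANY",
    vocab = "ANY"
  )
)

setValidity("LiGhTModel", function(object) {
  cfg <- object@config
  msg <- character(0)
  if (cfg$hidden %% cfg$nHeads != 0L) msg <- c(msg, "hidden must be divisible by nHeads")
  if (length(object@params) == 0L) msg <- c(msg, "empty parameter list")
  if (length(msg)) msg else TRUE
})

#' MaskPlan: per-node corruption actions for one pre-training example
#'
#' @slot nodeActions integer vector with one code per base node:
#'   0 = not selected, 1 = MASK, 2 = RANDOM, 3 = KEEP.
#' @slot knowledgeMask numeric 0/1 vector of length 712.
#' @slot rate numeric masking rate in \[0, 1\].
#' @slot seed integer seed the plan was drawn with (NA when drawn from the
#'   ambient RNG stream).
#' @export
setClass("MaskPlan",
  representation(
    nodeActions = "integer",
    knowledgeMask = "numeric",
    rate = "numeric",
    seed = "integer"
  )
)

setValidity("MaskPlan", function(object) {
  msg <- character(0)
  if (object@rate < 0 || object@rate > 1) msg <- c(msg, "rate must lie in [0, 1]")
  if (!all(object@nodeActions %in% 0:3)) msg <- c(msg, "invalid action codes")
  if (!all(object@knowledgeMask %in% c(0, 1))) msg <- c(msg, "knowledgeMask must be 0/1")
  if (length(msg)) msg else TRUE
})

#' LabeledSet: SMILES with property labels
#'
#' @slot smiles character vector of molecules.
#' @slot labels numeric matrix (n x nTasks); NA marks missing labels.
#' @slot taskType character per-column task types ("classification" or
#'   "regression").
#' @export
setClass("LabeledSet",
  representation(
    smiles = "character",
    labels = "matrix",
    taskType = "character"
  )
)

setValidity("LabeledSet", function(object) {
  msg <- character(0)
  if (nrow(object@labels) != length(object@smiles))
    msg <- c(msg, "label rows must align with smiles")
  if (ncol(object@labels) != length(object@taskType))
    msg <- c(msg, "one task type per label column")
  if (!all(object@taskType %in% c("classification", "regression")))
    msg <- c(msg, "task types must be classification or regression")
  cls <- object@taskType == "classification"
  if (any(cls)) {
    v <- object@labels[, cls, drop = FALSE]
    if (!all(is.na(v) | v %in% c(0, 1)))
      msg <- c(msg, "classification labels must be 0, 1 or missing")
  }
  if (length(msg)) msg else TRUE
})

#' SplitAssignment: a scaffold-based train/valid/test partition
#'
#' @slot train,valid,test integer index vectors partitioning \code{1:n}.
#' @slot ratios numeric length-3 target ratios.
#' @slot scaffolds character per-molecule scaffold keys.
#' @slot seed integer seed used for the split.
#' @export
setClass("SplitAssignment",
  representation(
    train = "integer",
    valid = "integer",
    test = "integer",
    ratios = "numeric",
    scaffolds = "character",
    seed = "integer"
  )
)

setValidity("SplitAssignment", function(object) {
  idx <- c(object@train, object@valid, object@test)
  n <- length(object@scaffolds)
  msg <- character(0)
  if (length(idx) != n || !setequal(idx, seq_len(n)))
    msg <- c(msg, "train/valid/test must partition 1:n")
  sc <- object@scaffolds
  for (s in unique(sc)) {
    inSplit <- c(any(sc[object@train] == s), any(sc[object@valid] == s),
                 any(sc[object@test] == s))
    if (sum(inSplit) > 1L) { msg <- c(msg, "scaffold appears in multiple splits"); break }
  }
  if (length(msg)) msg else TRUE
})
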