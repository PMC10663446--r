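# Generics and accessors for the core classes. Slot access from user code
# should go through these.

#' Number of atoms / line-graph nodes
#' @param x a MolecularGraph, LineGraph or AugmentedGraph
#' @return integer count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "MolecularGraph", function(x) length(x@elements))

#' Number of nodes
#' @param x a LineGraph or AugmentedGraph
#' @return integer count (for an AugmentedGraph, includes the K node)
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname nNodes
#' @export
setMethod("nNodes", "LineGraph", function(x) x@nNodes)

#' @rdname nNodes
#' @export
setMethod("nNodes", "AugmentedGraph", function(x) x@base@nNodes + 1L)

#' Number of bonds
#' @param x a MolecularGraph
#' @return integer count
#' @export
setGeneric("nBonds", function(x) standardGeneric("nBonds"))

#' @rdname nBonds
#' @export
setMethod("nBonds", "MolecularGraph", function(x) nrow(x@bonds))

#' Canonical SMILES stored in an object
#' @param x a MolecularGraph, LineGraph or AugmentedGraph
#' @return character scalar
#' @export
setGeneric("canonicalSmiles", function(x) standardGeneric("canonicalSmiles"))

#' @rdname canonicalSmiles
#' @export
setMethod("canonicalSmiles", "MolecularGraph", function(x) x@smiles)

#' @rdname canonicalSmiles
#' @export
setMethod("canonicalSmiles", "LineGraph", function(x) x@smiles)

#' @rdname canonicalSmiles
#' @export
setMethod("canonicalSmiles", "AugmentedGraph", function(x) x@base@smiles)

#' Shortest-path hop-count matrix of a line graph
#' @param x a LineGraph or AugmentedGraph
#' @return integer matrix; -1 marks unreachable pairs
#' @export
setGeneric("distMatrix", function(x) standardGeneric("distMatrix"))

#' @rdname distMatrix
#' @export
setMethod("distMatrix", "LineGraph", function(x) x@dist)

#' @rdname distMatrix
#' @export
setMethod("distMatrix", "AugmentedGraph", function(x) x@base@dist)

#' Stored shortest paths of a line graph
#' @param x a LineGraph or AugmentedGraph
#' @return nested list of integer node sequences
#' @export
setGeneric("shortestPaths", function(x) standardGeneric("shortestPaths"))

#' @rdname shortestPaths
#' @export
setMethod("shortestPaths", "LineGraph", function(x) x@paths)

#' @rdname shortestPaths
#' @export
setMethod("shortestPaths", "AugmentedGraph", function(x) x@base@paths)

#' Knowledge vector attached to an augmented graph
#' @param x an AugmentedGraph
#' @return a [KnowledgeVector-class]
#' @export
setGeneric("knowledge", function(x) standardGeneric("knowledge"))

#' @rdname knowledge
#' @export
setMethod("knowledge", "AugmentedGraph", function(x) x@knowledge)

#' Assembled 712-dimensional knowledge-node input
#' @param x a KnowledgeVector
#' @return numeric vector: normalized descriptors (200) then fingerprint (512)
#' @export
setGeneric("assembled", function(x) standardGeneric("assembled"))

#' @rdname assembled
#' @export
setMethod("assembled", "KnowledgeVector",
          function(x) c(x@descriptors, x@fingerprint))

#' Model configuration / parameters
#' @param x a LiGhTModel
#' @return the configuration list
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname modelConfig
#' @export
setMethod("modelConfig", "LiGhTModel", function(x) x@config)

#' @rdname modelConfig
#' @return for `modelParams`, the flat named parameter list
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' @rdname modelConfig
#' @export
setMethod("modelParams", "LiGhTModel", function(x) x@params)

setMethod("show", "MolecularGraph", function(object) {
  cat("MolecularGraph:", object@smiles, "\n")
  cat(" ", nAtoms(object), "atoms,", nBonds(object), "bonds;",
      "Dv =", ncol(object@atomFeatures), ", De =", ncol(object@bondFeatures), "\n")
})

setMethod("show", "LineGraph", function(object) {
  cat("LineGraph of", object@smiles, "\n")
  cat(" ", object@nNodes, "nodes,", nrow(object@edges), "edges;",
      if (length(object@dist)) "distances/paths populated" else "distances not populated", "\n")
})

setMethod("show", "AugmentedGraph", function(object) {
  cat("AugmentedGraph of", object@base@smiles, "\n")
  cat(" ", object@base@nNodes, "base nodes + K node (index", object@kIndex, ")\n")
  if (any(object@maskFlags) || any(object@knowledgeMask > 0))
    cat("  corrupted:", sum(object@maskFlags), "masked nodes,",
        sum(object@knowledgeMask), "masked knowledge entries\n")
})

setMethod("show", "KnowledgeVector", function(object) {
  cat("KnowledgeVector: 200 descriptors + 512 fingerprint bits (",
      sum(object@fingerprint), " bits set)\n", sep = "")
})

setMethod("show", "LiGhTModel", function(object) {
  cfg <- object@config
  cat("LiGhTModel:", cfg$nLayers, "layers,", cfg$hidden, "hidden,",
      cfg$nHeads, "heads;", format(countParameters(object), big.mark = ","),
      "parameters\n")
  if (!is.null(object@vocab)) cat("  node-type vocabulary:", object@vocab$size, "classes\n")
})

setMethod("show", "SplitAssignment", function(object) {
  cat("SplitAssignment:", length(object@train), "train /", length(object@valid),
      "valid /", length(object@test), "test;",
      length(unique(object@scaffolds)), "scaffold groups\n")
})

setMethod("show", "LabeledSet", function(object) {
  cat("LabeledSet:", length(object@smiles), "molecules,",
      ncol(object@labels), "task(s) [", paste(object@taskType, collapse = ", "), "]\n")
})
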