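#' Accessors for stCrosstalk classes
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors raw count matrix of an \linkS4class{STData}.
#' @export
assayCounts <- function(x) {
  stopifnot(is(x, "STData"))
  x@counts
}

#' @describeIn accessors log-normalized matrix (NULL if absent).
#' @export
assayLogcounts <- function(x) {
  stopifnot(is(x, "STData"))
  x@logcounts
}

#' @describeIn accessors unit coordinate data.frame of an STData.
#' @export
spatialCoords <- function(x) {
  stopifnot(is(x, "STData"))
  x@coords
}

#' @describeIn accessors gene symbols of an STData.
#' @export
geneNames <- function(x) {
  stopifnot(is(x, "STData"))
  rownames(x@counts)
}

#' @describeIn accessors unit (cell/spot) ids of an STData.
#' @export
unitNames <- function(x) {
  stopifnot(is(x, "STData"))
  colnames(x@counts)
}

#' @describeIn accessors cell-type proportion matrix (types x units) of a
#'   \linkS4class{Composition}.
#' @export
compositionProps <- function(x) {
  stopifnot(is(x, "Composition"))
  x@props
}

#' @describeIn accessors raw non-negative weight matrix of a Composition.
#' @export
compositionWeights <- function(x) {
  stopifnot(is(x, "Composition"))
  x@weights
}

#' @describeIn accessors per-iteration mean relative-entropy loss trace.
#' @export
lossTrace <- function(x) {
  stopifnot(is(x, "Composition"))
  x@lossTrace
}

#' @describeIn accessors logical mask of units flagged unsure.
#' @export
unsureMask <- function(x) {
  stopifnot(is(x, "Composition"))
  x@unsureMask
}

#' @describeIn accessors edge table of a \linkS4class{CellGraph}.
#' @export
graphEdges <- function(x) {
  stopifnot(is(x, "CellGraph"))
  x@edges
}

#' @describeIn accessors node table of a CellGraph.
#' @export
graphNodes <- function(x) {
  stopifnot(is(x, "CellGraph"))
  x@nodes
}

#' @describeIn accessors placement table of a \linkS4class{CellAtlas}.
#' @export
atlasPlacements <- function(x) {
  stopifnot(is(x, "CellAtlas"))
  x@placements
}

#' @describeIn accessors expression (\linkS4class{STData}) of a CellAtlas.
#' @export
atlasExpression <- function(x) {
  stopifnot(is(x, "CellAtlas"))
  x@expr
}

#' @describeIn accessors ligand-receptor pair table of a
#'   \linkS4class{PriorKnowledge}.
#' @export
lriPairs <- function(x) {
  stopifnot(is(x, "PriorKnowledge"))
  x@lri
}

#' @describeIn accessors directed pathway edge table of a PriorKnowledge.
#' @export
pathwayEdges <- function(x) {
  stopifnot(is(x, "PriorKnowledge"))
  x@pathways
}

#' @describeIn accessors transcription-factor symbols of a PriorKnowledge.
#' @export
tfSet <- function(x) {
  stopifnot(is(x, "PriorKnowledge"))
  x@tfs
}

#' @describeIn accessors named list of pathway membership gene sets.
#' @export
pathwaySets <- function(x) {
  stopifnot(is(x, "PriorKnowledge"))
  x@pathwaySets
}

#' @describeIn accessors underlying igraph of a
#'   \linkS4class{KnowledgeGraph}.
#' @export
kgGraph <- function(x) {
  stopifnot(is(x, "KnowledgeGraph"))
  x@graph
}

#' @describeIn accessors node annotation table of a KnowledgeGraph.
#' @export
kgNodes <- function(x) {
  stopifnot(is(x, "KnowledgeGraph"))
  x@nodeAnno
}

#' @export
setMethod("dim", "STData", function(x) dim(x@counts))

#' @export
setMethod("dimnames", "STData", function(x) dimnames(x@counts))

#' Subset an STData by genes and/or units
#'
#' @param x an \linkS4class{STData}.
#' @param i gene index/names. @param j unit index/names.
#' @param ... ignored. @param drop ignored (never drops).
#' @export
setMethod("[", "STData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@counts))
  if (missing(j)) j <- seq_len(ncol(x@counts))
  cnt <- x@counts[i, j, drop = FALSE]
  lg <- if (is.null(x@logcounts)) NULL else x@logcounts[i, j, drop = FALSE]
  crd <- if (nrow(x@coords)) x@coords[colnames(cnt), , drop = FALSE] else
    x@coords
  new("STData", counts = cnt, logcounts = lg, coords = crd)
})
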