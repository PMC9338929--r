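#' @import methods
#' @importFrom Matrix Matrix sparseMatrix readMM writeMM rowSums colSums t
NULL

#' Spatial expression data container
#'
#' Holds a gene x unit (cell or spot) count matrix, an optional
#' log-normalized layer, and optional 2-D spatial coordinates. Units are
#' cells for single-cell resolution platforms and capture spots for
#' spot-based platforms.
#'
#' @slot counts sparse non-negative gene x unit raw count matrix
#'   (\code{dgCMatrix}); rownames are gene symbols, colnames unit ids.
#' @slot logcounts the log-normalized layer (same shape), or \code{NULL}
#'   before \code{\link{logNormalize}} has been applied.
#' @slot coords \code{data.frame} with columns \code{x}, \code{y} and
#'   rownames matching unit ids; zero rows when no coordinates are attached.
#'
#' @seealso \code{\link{STData}}, \code{\link{readExpression}},
#'   \code{\link{logNormalize}}
#' @export
setClass("STData",
  representation(counts = "ANY", logcounts = "ANY", coords = "data.frame"),
  prototype(counts = NULL, logcounts = NULL,
            coords = data.frame(x = numeric(0), y = numeric(0)))
)

setValidity("STData", function(object) {
  msg <- character(0)
  cnt <- object@counts
  if (!inherits(cnt, "dgCMatrix"))
    msg <- c(msg, "counts must be a dgCMatrix")
  else {
    if (is.null(rownames(cnt)) || is.null(colnames(cnt)))
      msg <- c(msg, "counts must have gene rownames and unit colnames")
    else if (anyDuplicated(rownames(cnt)))
      msg <- c(msg, "duplicate gene symbols in counts")
    else if (anyDuplicated(colnames(cnt)))
      msg <- c(msg, "duplicate unit ids in counts")
    if (length(cnt@x) && min(cnt@x) < 0)
      msg <- c(msg, "negative entries in counts")
  }
  if (!is.null(object@logcounts)) {
    if (!identical(dim(object@logcounts), dim(cnt)))
      msg <- c(msg, "logcounts dimensions differ from counts")
  }
  if (nrow(object@coords) > 0) {
    if (!all(c("x", "y") %in% colnames(object@coords)))
      msg <- c(msg, "coords must have columns x and y")
    else {
      if (!setequal(rownames(object@coords), colnames(cnt)))
        msg <- c(msg, "coords rownames must match unit ids")
      if (!all(is.finite(object@coords$x)) || !all(is.finite(object@coords$y)))
        msg <- c(msg, "coordinates must be finite")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an STData object
#'
#' @param counts gene x unit numeric matrix (dense or sparse) of raw,
#'   non-negative counts with gene rownames and unit colnames.
#' @param coords optional \code{data.frame} of unit coordinates; either
#'   rownames or a first id column must give unit ids, and columns
#'   \code{x}, \code{y} the positions.
#' @param logcounts optional precomputed log-normalized layer.
#' @return an \linkS4class{STData} object.
#' @examples
#' m <- matrix(rpois(12, 4), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("U", 1:4)))
#' STData(m)
#' @export
STData <- function(counts, coords = NULL, logcounts = NULL) {
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(coords)) {
    coords <- data.frame(x = numeric(0), y = numeric(0))
  } else {
    coords <- as.data.frame(coords)
    if (!all(c("x", "y") %in% colnames(coords))) {
      stop("coords must contain columns 'x' and 'y'")
    }
    if (is.null(rownames(coords)) ||
        identical(rownames(coords), as.character(seq_len(nrow(coords))))) {
      idcol <- setdiff(colnames(coords), c("x", "y"))[1]
      if (is.na(idcol)) stop("coords need unit ids (rownames or an id column)")
      rownames(coords) <- as.character(coords[[idcol]])
    }
    coords <- coords[, c("x", "y")]
    missing <- setdiff(colnames(counts), rownames(coords))
    extra <- setdiff(rownames(coords), colnames(counts))
    if (length(missing) || length(extra)) {
      stop("coordinate/expression unit mismatch; missing coords for: ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(extra)) paste0("; coords without expression: ",
                                     paste(utils::head(extra, 5), collapse = ", ")))
    }
    coords <- coords[colnames(counts), , drop = FALSE]
  }
  if (!is.null(logcounts))
    logcounts <- as(as(as(logcounts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  new("STData", counts = counts, logcounts = logcounts, coords = coords)
}

#' Cell-type composition of spatial units
#'
#' Result of \code{\link{fitNNLM}}: per-unit non-negative cell-type
#' weights and the derived proportions, with fit diagnostics.
#'
#' @slot weights raw non-negative coefficient matrix, types x units.
#' @slot props column-normalized weights (proportions summing to 1 per
#'   unit; all-zero units stay zero).
#' @slot converged logical per unit: relative loss change fell below
#'   tolerance before the iteration cap.
#' @slot lossTrace mean relative-entropy loss per outer iteration block,
#'   averaged over active units (non-increasing up to tolerance).
#' @slot unsureMask logical per unit: units whose composition cannot be
#'   trusted (all-zero or below the expressed-gene floor).
#' @export
setClass("Composition",
  representation(weights = "matrix", props = "matrix", converged = "logical",
                 lossTrace = "numeric", unsureMask = "logical")
)

setValidity("Composition", function(object) {
  msg <- character(0)
  if (any(object@weights < 0)) msg <- c(msg, "negative weights")
  if (!identical(dim(object@weights), dim(object@props)))
    msg <- c(msg, "weights/props shape mismatch")
  if (length(object@converged) != ncol(object@weights))
    msg <- c(msg, "converged length != number of units")
  if (length(object@unsureMask) != ncol(object@weights))
    msg <- c(msg, "unsureMask length != number of units")
  if (length(msg)) msg else TRUE
})

#' Directed spatial KNN cell graph
#'
#' @slot edges \code{data.frame} with integer node index columns
#'   \code{from}, \code{to} and \code{dist}, one row per directed edge
#'   from a cell to one of its K nearest neighbors.
#' @slot nodes \code{data.frame} with columns \code{cell}, \code{type},
#'   \code{x}, \code{y}; row order defines node indices.
#' @slot K the requested neighbor count.
#' @export
setClass("CellGraph",
  representation(edges = "data.frame", nodes = "data.frame", K = "integer")
)

setValidity("CellGraph", function(object) {
  msg <- character(0)
  if (!all(c("from", "to", "dist") %in% colnames(object@edges)))
    msg <- c(msg, "edges must have from, to, dist")
  else if (nrow(object@edges) && any(object@edges$from == object@edges$to))
    msg <- c(msg, "self-edges are not allowed")
  if (!all(c("cell", "type", "x", "y") %in% colnames(object@nodes)))
    msg <- c(msg, "nodes must have cell, type, x, y")
  if (length(msg)) msg else TRUE
})

#' Reconstructed single-cell spatial atlas
#'
#' Product of \code{\link{reconstructAtlas}}: each selected reference
#' cell placed at a coordinate inside its source spot's neighborhood.
#'
#' @slot placements \code{data.frame} with columns \code{cell} (new unique
#'   id), \code{type}, \code{x}, \code{y}, \code{spot} (source spot id),
#'   \code{ref_cell} (reference cell the expression profile came from),
#'   \code{alpha}, \code{theta} (the sampled radius weight and angle; NA
#'   in single-cell mode where coordinates are kept as observed).
#' @slot expr \linkS4class{STData} whose units are the placed cells and
#'   whose profiles are the selected reference cells' counts.
#' @export
setClass("CellAtlas",
  representation(placements = "data.frame", expr = "STData")
)

setValidity("CellAtlas", function(object) {
  need <- c("cell", "type", "x", "y", "spot", "ref_cell", "alpha", "theta")
  msg <- character(0)
  if (!all(need %in% colnames(object@placements)))
    msg <- c(msg, paste("placements must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@placements$cell))
      msg <- c(msg, "placed cell ids must be unique")
    if (!setequal(object@placements$cell, colnames(object@expr@counts)))
      msg <- c(msg, "placements and expression units differ")
  }
  if (length(msg)) msg else TRUE
})

#' Prior knowledge: ligand-receptor pairs, pathway edges, TFs
#'
#' @slot lri \code{data.frame} with character columns \code{ligand},
#'   \code{receptor}; one row per curated interaction, no self-pairs.
#' @slot pathways \code{data.frame} with columns \code{src}, \code{dest},
#'   \code{source} giving directed pathway edges and their database label.
#' @slot tfs character vector of transcription-factor symbols.
#' @slot pathwaySets named list of character vectors: pathway membership
#'   gene sets (from GMT input) used for enrichment tests.
#' @export
setClass("PriorKnowledge",
  representation(lri = "data.frame", pathways = "data.frame",
                 tfs = "character", pathwaySets = "list")
)

setValidity("PriorKnowledge", function(object) {
  msg <- character(0)
  if (!all(c("ligand", "receptor") %in% colnames(object@lri)))
    msg <- c(msg, "lri must have ligand and receptor columns")
  else if (nrow(object@lri) &&
           any(object@lri$ligand == object@lri$receptor))
    msg <- c(msg, "self-pairs in lri are not allowed")
  if (!all(c("src", "dest", "source") %in% colnames(object@pathways)))
    msg <- c(msg, "pathways must have src, dest, source columns")
  if (length(msg)) msg else TRUE
})

#' Receiver-side ligand-receptor-TF knowledge graph
#'
#' Directed gene graph whose edges come from the ligand-receptor table and
#' pathway edge list, weighted by the positive co-expression coefficient of
#' the endpoint genes across the receiver cells.
#'
#' @slot graph an \code{igraph} directed graph; vertex attribute
#'   \code{name} is the gene symbol, edge attribute \code{weight} the
#'   co-expression coefficient in (0, 1].
#' @slot nodeAnno \code{data.frame} with columns \code{gene},
#'   \code{is_ligand}, \code{is_receptor}, \code{is_tf}.
#' @slot receiverType cell type the co-expression weights were computed on.
#' @export
setClass("KnowledgeGraph",
  representation(graph = "ANY", nodeAnno = "data.frame",
                 receiverType = "character")
)

#' Run configuration
#'
#' All tunable parameters of the pipeline, with field-standard defaults.
#'
#' @slot K KNN neighbor count for the spatial cell graph (default 10).
#' @slot maxCells maximum cells per spot M (default 30; use 1 for
#'   bead/near-cellular platforms).
#' @slot zPerm label-shuffling permutation count (default 1000).
#' @slot zWalk random-walk count per receptor (default 1000).
#' @slot maxIter multiplicative-update iteration cap (default 10000).
#' @slot lambda1,lambdaAlpha,lambda2 L1 / angle / L2 regularization
#'   weights of the deconvolution objective (defaults 0).
#' @slot maxWalkSteps walk step bound (default 10).
#' @slot pCutoff permutation significance cutoff (default 0.05).
#' @slot minExpr a gene is "expressed" in a cell when its raw count
#'   exceeds this (default 0).
#' @slot minGenes expressed-gene floor below which a unit is "unsure"
#'   (default 50).
#' @slot unsurePropMin maximum-proportion floor for single-cell label
#'   assignment (default 0.3).
#' @slot nRestarts random draws when selecting reference cells per spot
#'   (default 100).
#' @slot minCellsFrac fraction of receiver cells in which a TF/target
#'   must be expressed to count as active (default 0.1).
#' @slot tol relative loss-change convergence tolerance (default 1e-6,
#'   assessed over blocks of 10 iterations).
#' @slot scaleFactor library-size scaling for log normalization
#'   (default 10000).
#' @export
setClass("RunConfig",
  representation(K = "integer", maxCells = "integer", zPerm = "integer",
                 zWalk = "integer", maxIter = "integer",
                 lambda1 = "numeric", lambdaAlpha = "numeric",
                 lambda2 = "numeric", maxWalkSteps = "integer",
                 pCutoff = "numeric", minExpr = "numeric",
                 minGenes = "integer", unsurePropMin = "numeric",
                 nRestarts = "integer", minCellsFrac = "numeric",
                 tol = "numeric", scaleFactor = "numeric"),
  prototype(K = 10L, maxCells = 30L, zPerm = 1000L, zWalk = 1000L,
            maxIter = 10000L, lambda1 = 0, lambdaAlpha = 0, lambda2 = 0,
            maxWalkSteps = 10L, pCutoff = 0.05, minExpr = 0,
            minGenes = 50L, unsurePropMin = 0.3, nRestarts = 100L,
            minCellsFrac = 0.1, tol = 1e-6, scaleFactor = 1e4)
)

setValidity("RunConfig", function(object) {
  msg <- character(0)
  pos <- c("K", "maxCells", "zPerm", "zWalk", "maxIter", "maxWalkSteps",
           "nRestarts")
  for (s in pos) if (slot(object, s) < 1L)
    msg <- c(msg, paste(s, "must be a positive integer"))
  if (object@lambda1 < 0 || object@lambdaAlpha < 0 || object@lambda2 < 0)
    msg <- c(msg, "regularization weights must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param ... named slot overrides, e.g. \code{runConfig(K = 6, zPerm = 500)}.
#' @return a validated \linkS4class{RunConfig}.
#' @examples
#' runConfig(maxCells = 1, zPerm = 500)
#' @rdname RunConfig-class
#' @export
runConfig <- function(...) {
  args <- list(...)
  intSlots <- c("K", "maxCells", "zPerm", "zWalk", "maxIter",
                "maxWalkSteps", "minGenes", "nRestarts")
  for (s in intersect(names(args), intSlots)) args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list("RunConfig"), args))
}

#' Synthetic study scenario
#'
#' Describes a fully synthetic dataset: a labeled scRNA-seq reference, a
#' zoned single-cell spatial atlas with a planted ligand-receptor signal
#' and its downstream receptor-to-TF-to-target chain, and a matching
#' prior-knowledge base with decoys.
#'
#' @slot nTypes number of cell types (zones).
#' @slot nGenes gene universe size.
#' @slot cellsPerType cells per type in both reference and atlas.
#' @slot nMarkers marker genes per type (fold change >= 4).
#' @slot layout spatial zoning: \code{"stripes"} (vertical bands) or
#'   \code{"checkerboard"}.
#' @slot plantedLRI \code{data.frame} with columns \code{ligand},
#'   \code{receptor}, \code{sender}, \code{receiver}, \code{effect}.
#' @slot plantedChains list of lists with elements \code{receptor},
#'   \code{tf}, \code{targets}: the downstream activation chain planted
#'   in the receiver type.
#' @slot nDecoyLRI decoy ligand-receptor pairs with no planted signal.
#' @slot noise \code{"nb"} (negative binomial), \code{"poisson"}, or
#'   \code{"none"} (rounded means).
#' @slot dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @slot baseMu baseline mean count for non-marker genes.
#' @slot markerMu mean count of a marker gene in its own type.
#' @export
setClass("SyntheticScenario",
  representation(nTypes = "integer", nGenes = "integer",
                 cellsPerType = "integer", nMarkers = "integer",
                 layout = "character", plantedLRI = "data.frame",
                 plantedChains = "list", nDecoyLRI = "integer",
                 noise = "character", dispersion = "numeric",
                 baseMu = "numeric", markerMu = "numeric")
)

setValidity("SyntheticScenario", function(object) {
  msg <- character(0)
  if (object@cellsPerType < 3L) msg <- c(msg, "cellsPerType must be >= 3")
  if (!object@layout %in% c("stripes", "checkerboard", "random"))
    msg <- c(msg, "layout must be 'stripes', 'checkerboard' or 'random'")
  if (!object@noise %in% c("nb", "poisson", "none"))
    msg <- c(msg, "noise must be 'nb', 'poisson' or 'none'")
  planted <- unlist(lapply(object@plantedChains,
                           function(ch) c(ch$receptor, ch$tf, ch$targets)))
  if (anyDuplicated(planted))
    msg <- c(msg, "planted genes overlap across chains")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "STData", function(object) {
  cat("STData:", nrow(object@counts), "genes x", ncol(object@counts),
      "units\n")
  cat("  layers: raw", if (!is.null(object@logcounts)) "+ lognorm", "\n")
  cat("  coordinates:", if (nrow(object@coords)) "yes" else "no", "\n")
})

#' @export
setMethod("show", "Composition", function(object) {
  cat("Composition:", nrow(object@weights), "cell types x",
      ncol(object@weights), "units\n")
  cat("  converged:", sum(object@converged), "/", length(object@converged),
      " units; unsure:", sum(object@unsureMask), "\n")
})

#' @export
setMethod("show", "CellGraph", function(object) {
  cat("CellGraph:", nrow(object@nodes), "cells,", nrow(object@edges),
      "directed edges (K =", object@K, ")\n")
})

#' @export
setMethod("show", "CellAtlas", function(object) {
  cat("CellAtlas:", nrow(object@placements), "placed cells from",
      length(unique(object@placements$spot)), "spots\n")
})

#' @export
setMethod("show", "PriorKnowledge", function(object) {
  cat("PriorKnowledge:", nrow(object@lri), "LR pairs,",
      nrow(object@pathways), "pathway edges,", length(object@tfs), "TFs,",
      length(object@pathwaySets), "pathway sets\n")
})

#' @export
setMethod("show", "KnowledgeGraph", function(object) {
  cat("KnowledgeGraph (receiver:", object@receiverType, "):",
      igraph::vcount(object@graph), "genes,",
      igraph::ecount(object@graph), "weighted edges\n")
})

#' @export
setMethod("show", "SyntheticScenario", function(object) {
  cat("SyntheticScenario:", object@nTypes, "types x", object@nGenes,
      "genes,", object@cellsPerType, "cells/type (", object@layout,
      "layout,", object@noise, "noise )\n")
  cat("  planted LRIs:", nrow(object@plantedLRI), "; decoy LRIs:",
      object@nDecoyLRI, "\n")
})
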