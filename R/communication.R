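#' Build the directed spatial KNN cell graph
#'
#' Each cell gets a directed edge to its K nearest cells by Euclidean
#' distance in space. Ties at the K-th distance are broken by cell-id
#' order; self-edges are never created; duplicate coordinates (distance 0)
#' are allowed. When fewer than K other cells exist, all of them are used
#' with a warning.
#'
#' @param atlas a \linkS4class{CellAtlas}, or a data.frame with columns
#'   \code{cell}, \code{type}, \code{x}, \code{y}.
#' @param K neighbor count (default 10).
#' @return a \linkS4class{CellGraph}.
#' @export
buildKNNGraph <- function(atlas, K = 10L) {
  nodes <- if (is(atlas, "CellAtlas")) {
    atlasPlacements(atlas)[, c("cell", "type", "x", "y")]
  } else {
    stopifnot(all(c("cell", "type", "x", "y") %in% colnames(atlas)))
    atlas[, c("cell", "type", "x", "y")]
  }
  rownames(nodes) <- NULL
  n <- nrow(nodes)
  if (n < 2) stop("need at least 2 cells to build a graph")
  K <- as.integer(K)
  if (K > n - 1L) {
    warning("K = ", K, " exceeds n - 1 = ", n - 1, "; clamped")
    K <- n - 1L
  }
  D <- as.matrix(stats::dist(nodes[, c("x", "y")]))
  ids <- nodes$cell
  from <- integer(0); to <- integer(0); dd <- numeric(0)
  fromL <- toL <- vector("list", n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    ord <- order(d, ids)[seq_len(K)]
    fromL[[i]] <- rep.int(i, K)
    toL[[i]] <- ord
  }
  from <- unlist(fromL); to <- unlist(toL)
  edges <- data.frame(from = from, to = to,
                      dist = D[cbind(from, to)])
  new("CellGraph", edges = edges, nodes = nodes, K = K)
}

# Edge subset on which a ligand-receptor pair is co-expressed:
# returns integer edge indices with ligand expressed in the source cell
# and receptor in the target cell (raw count > minExpr).
.lrEdgeSubset <- function(graph, expr, ligand, receptor, minExpr = 0) {
  genes <- geneNames(expr)
  if (!(ligand %in% genes) || !(receptor %in% genes)) {
    warning("gene(s) absent from expression: ",
            paste(setdiff(c(ligand, receptor), genes), collapse = ", "))
    return(integer(0))
  }
  cnt <- assayCounts(expr)
  cellIdx <- match(graphNodes(graph)$cell, unitNames(expr))
  ligPos <- (cnt[ligand, ] > minExpr)[cellIdx]
  recPos <- (cnt[receptor, ] > minExpr)[cellIdx]
  e <- graphEdges(graph)
  which(ligPos[e$from] & recPos[e$to])
}

#' Count co-expressed ligand-receptor sender-receiver pairs
#'
#' The observed statistic of the spatial enrichment test: the number of
#' directed graph edges u -> v with sender type A at u, receiver type B at
#' v, the ligand expressed in u, and the receptor expressed in v
#' (positivity on raw counts).
#'
#' @param graph a \linkS4class{CellGraph}.
#' @param expr \linkS4class{STData} over the graph's cells.
#' @param A sender type. @param B receiver type.
#' @param ligand,receptor gene symbols. A gene absent from the matrix
#'   yields count 0 with a warning so database scans proceed.
#' @param minExpr expression positivity threshold (default 0).
#' @return integer count.
#' @export
countLRPairs <- function(graph, expr, A, B, ligand, receptor, minExpr = 0) {
  sub <- .lrEdgeSubset(graph, expr, ligand, receptor, minExpr)
  if (!length(sub)) return(0L)
  e <- graphEdges(graph)[sub, ]
  ty <- graphNodes(graph)$type
  sum(ty[e$from] == A & ty[e$to] == B)
}

#' Label-shuffling permutation test for one ligand-receptor interaction
#'
#' Recomputes the co-expressed pair count after globally shuffling the
#' cell-type labels over all nodes (graph topology and expression fixed),
#' Z times. The P-value is the fraction of permuted counts at least as
#' large as the observed one; interactions with P below the cutoff carry
#' the inter-cellular score 1 - P (capped at 1 - 1/(Z+1) when P = 0, for
#' ranking stability).
#'
#' @inheritParams countLRPairs
#' @param Z number of permutations (>= 100).
#' @param pCutoff significance cutoff (default 0.05).
#' @return list with \code{C0}, \code{permCounts}, \code{P},
#'   \code{significant}, and \code{S_inter} (NA when not significant).
#' @export
permutationTest <- function(graph, expr, A, B, ligand, receptor,
                            Z = 1000L, pCutoff = 0.05, minExpr = 0) {
  if (Z < 1) stop("Z must be positive")
  sub <- .lrEdgeSubset(graph, expr, ligand, receptor, minExpr)
  ty <- graphNodes(graph)$type
  e <- graphEdges(graph)
  fs <- e$from[sub]; ts <- e$to[sub]
  C0 <- sum(ty[fs] == A & ty[ts] == B)
  perm <- integer(Z)
  n <- length(ty)
  for (z in seq_len(Z)) {
    lp <- ty[sample.int(n)]
    perm[z] <- sum(lp[fs] == A & lp[ts] == B)
  }
  P <- sum(perm >= C0) / Z
  sig <- P < pCutoff
  list(C0 = C0, permCounts = perm, P = P, significant = sig,
       S_inter = if (sig) min(1 - P, 1 - 1 / (Z + 1)) else NA_real_)
}

#' Score all cell-cell communications in an atlas
#'
#' Runs the spatial ligand-receptor permutation test for every ordered
#' sender-receiver type pair (autocrine included) and every database pair
#' whose genes are measured, then computes the intracellular
#' (receptor-to-TF random walk) score for the significant interactions and
#' combines the two as a geometric mean. Interactions failing either stage
#' (permutation P at or above the cutoff, or no activated TF with an
#' expressed target) get combined score 0.
#'
#' @param atlas a labeled \linkS4class{CellAtlas}.
#' @param prior a \linkS4class{PriorKnowledge}.
#' @param config a \linkS4class{RunConfig}.
#' @param verbose print progress (default FALSE).
#' @return \code{data.frame} with one row per (sender, receiver, ligand,
#'   receptor): \code{C0}, \code{P}, \code{S_inter}, \code{S_intra},
#'   \code{score}, \code{significant}. Rows are deterministic under a
#'   fixed RNG seed and invariant to input cell order.
#' @export
scoreCommunications <- function(atlas, prior, config = runConfig(),
                                verbose = FALSE) {
  stopifnot(is(atlas, "CellAtlas"), is(prior, "PriorKnowledge"))
  pl <- atlasPlacements(atlas)
  ord <- order(pl$cell)
  pl <- pl[ord, ]
  expr <- atlasExpression(atlas)[, pl$cell]
  graph <- buildKNNGraph(data.frame(cell = pl$cell, type = pl$type,
                                    x = pl$x, y = pl$y), config@K)
  types <- sort(unique(pl$type))
  k <- length(types)
  code <- match(graphNodes(graph)$type, types)
  lri <- lriPairs(prior)
  genes <- geneNames(expr)
  lri <- lri[lri$ligand %in% genes & lri$receptor %in% genes, , drop = FALSE]
  if (nrow(lri) == 0) {
    return(data.frame(sender = character(0), receiver = character(0),
                      ligand = character(0), receptor = character(0),
                      C0 = integer(0), P = numeric(0), S_inter = numeric(0),
                      S_intra = numeric(0), score = numeric(0),
                      significant = logical(0)))
  }
  Z <- config@zPerm
  n <- nrow(graphNodes(graph))
  e <- graphEdges(graph)
  # one global label shuffle per permutation, shared by every LRI and
  # type pair, mirroring a full recomputation under each shuffle
  permCodes <- matrix(0L, n, Z)
  for (z in seq_len(Z)) permCodes[, z] <- code[sample.int(n)]

  cnt <- assayCounts(expr)
  cellIdx <- match(graphNodes(graph)$cell, unitNames(expr))
  rows <- vector("list", nrow(lri))
  for (i in seq_len(nrow(lri))) {
    lg <- lri$ligand[i]; rc <- lri$receptor[i]
    ligPos <- (cnt[lg, ] > config@minExpr)[cellIdx]
    recPos <- (cnt[rc, ] > config@minExpr)[cellIdx]
    sub <- which(ligPos[e$from] & recPos[e$to])
    fs <- e$from[sub]; ts <- e$to[sub]
    obs <- tabulate(code[fs] + k * (code[ts] - 1L), k * k)
    ge <- integer(k * k)
    for (z in seq_len(Z)) {
      pc <- permCodes[, z]
      pcnt <- tabulate(pc[fs] + k * (pc[ts] - 1L), k * k)
      ge <- ge + (pcnt >= obs)
    }
    P <- ge / Z
    rows[[i]] <- data.frame(
      sender = rep(types, times = k), receiver = rep(types, each = k),
      ligand = lg, receptor = rc, C0 = obs, P = P,
      stringsAsFactors = FALSE)
    if (verbose) message("LRI ", i, "/", nrow(lri), ": ", lg, "-", rc)
  }
  tab <- do.call(rbind, rows)
  tab$significant <- tab$P < config@pCutoff
  tab$S_inter <- ifelse(tab$significant,
                        pmin(1 - tab$P, 1 - 1 / (Z + 1)), NA_real_)
  tab$S_intra <- NA_real_

  # intracellular stage: one knowledge graph per receiver type, one walk
  # per (receiver, receptor)
  need <- unique(tab[tab$significant, c("receiver", "receptor")])
  kgCache <- list(); intraCache <- list()
  for (j in seq_len(nrow(need))) {
    B <- need$receiver[j]; rc <- need$receptor[j]
    key <- paste(B, rc, sep = "\r")
    if (is.null(kgCache[[B]])) {
      recvCells <- pl$cell[pl$type == B]
      kgCache[[B]] <- if (length(recvCells) >= 3) {
        buildLRTKG(prior, expr[, recvCells], config)
      } else NA
    }
    kg <- kgCache[[B]]
    intraCache[[key]] <- if (identical(kg, NA)) 0 else {
      acts <- randomWalkTF(kg, rc, config)
      recvCells <- pl$cell[pl$type == B]
      intracellularScore(acts, expr[, recvCells], kg, config)$S_intra
    }
  }
  sigIdx <- which(tab$significant)
  if (length(sigIdx)) {
    keys <- paste(tab$receiver[sigIdx], tab$receptor[sigIdx], sep = "\r")
    tab$S_intra[sigIdx] <- vapply(keys, function(kk)
      intraCache[[kk]], numeric(1))
  }
  tab$score <- combinedScore(tab$S_inter, tab$S_intra)
  rownames(tab) <- NULL
  tab[, c("sender", "receiver", "ligand", "receptor", "C0", "P",
          "S_inter", "S_intra", "score", "significant")]
}

#' Significant, ranked communications
#'
#' @param tab table from \code{\link{scoreCommunications}}.
#' @return rows with positive combined score, ranked by score.
#' @export
significantCommunications <- function(tab) {
  out <- tab[!is.na(tab$score) & tab$score > 0, , drop = FALSE]
  out[order(-out$score, out$sender, out$receiver, out$ligand,
            out$receptor), , drop = FALSE]
}
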