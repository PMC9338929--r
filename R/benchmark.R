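#' Merge single-cell ST data into simulated spots
#'
#' Splits the plane into a square grid of side \code{binSize} anchored at
#' the minimum coordinate (configurable offset) and merges the cells of
#' each bin into one simulated spot: spot counts are the exact column sums
#' of the member cells, spot coordinates the bin centers. Empty bins are
#' dropped. The per-spot ground-truth composition is recorded.
#'
#' @param atlas a \linkS4class{CellAtlas} (single-cell data with labels).
#' @param binSize grid side length (> 0), in coordinate units.
#' @param origin grid anchor c(x, y); default the minimum coordinate.
#' @return list with \code{spots} (\linkS4class{STData} with coordinates),
#'   \code{truth} (types x spots proportion matrix), \code{members}
#'   (named list spot -> member cell ids).
#' @export
simulateSpots <- function(atlas, binSize, origin = NULL) {
  stopifnot(is(atlas, "CellAtlas"))
  if (binSize <= 0) stop("binSize must be positive")
  pl <- atlasPlacements(atlas)
  if (is.null(origin)) origin <- c(min(pl$x), min(pl$y))
  bx <- floor((pl$x - origin[1]) / binSize)
  by <- floor((pl$y - origin[2]) / binSize)
  spotId <- paste0("spot_", bx, "_", by)
  members <- split(pl$cell, spotId)
  types <- sort(unique(pl$type))
  typeBySpot <- split(pl$type, spotId)
  spots <- names(members)
  cnt <- assayCounts(atlasExpression(atlas))
  # spot counts = exact member column sums, via a sparse indicator
  memIdx <- match(pl$cell, colnames(cnt))
  agg <- Matrix::sparseMatrix(i = memIdx,
                              j = match(spotId, spots),
                              x = 1, dims = c(ncol(cnt), length(spots)))
  sc <- cnt %*% agg
  colnames(sc) <- spots
  ctr <- data.frame(
    x = origin[1] + (vapply(split(bx, spotId), function(v) v[1],
                            numeric(1)) + 0.5) * binSize,
    y = origin[2] + (vapply(split(by, spotId), function(v) v[1],
                            numeric(1)) + 0.5) * binSize,
    row.names = spots)
  truth <- vapply(typeBySpot, function(tv) {
    tab <- table(factor(tv, levels = types))
    as.numeric(tab) / length(tv)
  }, numeric(length(types)))
  rownames(truth) <- types
  list(spots = STData(sc, coords = ctr), truth = truth, members = members)
}

#' Composition recovery metrics
#'
#' Per-spot Pearson correlation (across cell types) and RMSE between
#' predicted and true composition, plus their means over spots. Spots
#' whose true composition is constant across types have an undefined
#' correlation and are skipped from the correlation mean with a warning.
#'
#' @param pred a \linkS4class{Composition} or a types x spots proportion
#'   matrix.
#' @param truth types x spots proportion matrix with matching dimnames.
#' @return list with \code{perSpot} (data.frame spot, pearson, rmse),
#'   \code{meanPearson}, \code{meanRMSE}.
#' @export
evaluateComposition <- function(pred, truth) {
  if (is(pred, "Composition")) pred <- compositionProps(pred)
  types <- intersect(rownames(pred), rownames(truth))
  spots <- intersect(colnames(pred), colnames(truth))
  if (length(types) < 2 || length(spots) < 1) {
    stop("prediction and truth share too few types or spots")
  }
  P <- pred[types, spots, drop = FALSE]
  Tm <- truth[types, spots, drop = FALSE]
  rmse <- sqrt(colMeans((P - Tm)^2))
  const <- apply(Tm, 2, function(v) stats::sd(v) == 0) |
    apply(P, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning(sum(const), " spot(s) with constant composition vector ",
            "skipped in the correlation")
  }
  pear <- rep(NA_real_, length(spots))
  ok <- which(!const)
  pear[ok] <- vapply(ok, function(j)
    stats::cor(P[, j], Tm[, j]), numeric(1))
  list(perSpot = data.frame(spot = spots, pearson = pear,
                            rmse = unname(rmse), row.names = NULL),
       meanPearson = mean(pear, na.rm = TRUE),
       meanRMSE = mean(rmse))
}

#' Spatial proximity significance of an inferred interaction
#'
#' One-sided Wilcoxon rank-sum test asking whether the distances from
#' ligand-expressing sender cells to receptor-expressing receiver cells
#' are stochastically smaller than the distances between all ordered
#' cell-cell pairs.
#'
#' @param atlas a \linkS4class{CellAtlas}.
#' @param ligand,receptor gene symbols.
#' @param A sender type. @param B receiver type.
#' @param minExpr positivity threshold on raw counts.
#' @param maxPairs background ordered pairs are subsampled to this bound
#'   (seeded by the caller) for tractability; flagged in the result.
#' @return list with \code{P}, \code{nPairs}, \code{nBackground},
#'   \code{subsampled}, \code{flag} ("ok", "no-expressing-pairs", or
#'   "low-n").
#' @export
spatialProximityTest <- function(atlas, ligand, receptor, A, B,
                                 minExpr = 0, maxPairs = 1e6) {
  pl <- atlasPlacements(atlas)
  cnt <- assayCounts(atlasExpression(atlas))
  genes <- rownames(cnt)
  if (!(ligand %in% genes) || !(receptor %in% genes)) {
    return(list(P = 1, nPairs = 0L, nBackground = 0L, subsampled = FALSE,
                flag = "no-expressing-pairs"))
  }
  idx <- match(pl$cell, colnames(cnt))
  send <- which(pl$type == A & (cnt[ligand, ] > minExpr)[idx])
  recv <- which(pl$type == B & (cnt[receptor, ] > minExpr)[idx])
  pairIdx <- expand.grid(s = send, r = recv)
  pairIdx <- pairIdx[pairIdx$s != pairIdx$r, , drop = FALSE]
  if (nrow(pairIdx) == 0) {
    return(list(P = 1, nPairs = 0L, nBackground = 0L, subsampled = FALSE,
                flag = "no-expressing-pairs"))
  }
  dLR <- sqrt((pl$x[pairIdx$s] - pl$x[pairIdx$r])^2 +
              (pl$y[pairIdx$s] - pl$y[pairIdx$r])^2)
  n <- nrow(pl)
  nbg <- n * (n - 1)
  subsampled <- nbg > maxPairs
  if (subsampled) {
    si <- sample.int(n, maxPairs, replace = TRUE)
    ri <- sample.int(n, maxPairs, replace = TRUE)
    keep <- si != ri
    si <- si[keep]; ri <- ri[keep]
  } else {
    g <- expand.grid(s = seq_len(n), r = seq_len(n))
    g <- g[g$s != g$r, ]
    si <- g$s; ri <- g$r
  }
  dBG <- sqrt((pl$x[si] - pl$x[ri])^2 + (pl$y[si] - pl$y[ri])^2)
  P <- stats::wilcox.test(dLR, dBG, alternative = "less")$p.value
  list(P = P, nPairs = nrow(pairIdx), nBackground = length(dBG),
       subsampled = subsampled,
       flag = if (nrow(pairIdx) < 3) "low-n" else "ok")
}

#' Co-expressed percent of an interaction over the cell graph
#'
#' 100 times the co-expressed pair count divided by the number of
#' sender-to-receiver edges in the graph; 0 when no such edges exist.
#'
#' @inheritParams countLRPairs
#' @return percent in [0, 100].
#' @export
coexpressionPercent <- function(graph, expr, A, B, ligand, receptor,
                                minExpr = 0) {
  ty <- graphNodes(graph)$type
  e <- graphEdges(graph)
  nAB <- sum(ty[e$from] == A & ty[e$to] == B)
  if (nAB == 0) return(0)
  100 * countLRPairs(graph, expr, A, B, ligand, receptor, minExpr) / nAB
}

#' Fisher exact pathway enrichment of inferred target genes
#'
#' For each pathway membership set, forms the 2x2 table (inferred targets
#' vs rest of the universe, in vs out of the pathway) and reports the
#' one-sided upper-tail hypergeometric P-value. A Benjamini-Hochberg
#' adjusted column is emitted alongside for convenience.
#'
#' @param targetGenes character vector of inferred target genes.
#' @param sets named list of pathway gene sets.
#' @param universe all assayable genes (the 2x2 total n).
#' @return data.frame with columns \code{pathway}, \code{a}, \code{b},
#'   \code{c}, \code{d}, \code{P}, \code{padj}; all P = 1 when the target
#'   set is empty.
#' @export
fisherPathwayEnrichment <- function(targetGenes, sets, universe) {
  stopifnot(length(sets) > 0, length(universe) > 0)
  universe <- unique(universe)
  targets <- intersect(unique(targetGenes), universe)
  n <- length(universe)
  rows <- lapply(names(sets), function(nm) {
    pw <- intersect(sets[[nm]], universe)
    a <- length(intersect(targets, pw))
    b <- length(pw) - a
    cc <- length(targets) - a
    d <- n - a - b - cc
    P <- if (length(targets) == 0) 1 else
      stats::phyper(a - 1, a + b, cc + d, a + cc, lower.tail = FALSE)
    data.frame(pathway = nm, a = a, b = b, c = cc, d = d, P = P,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$P, method = "BH")
  rownames(out) <- NULL
  out
}
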