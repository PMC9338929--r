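#' Build the receiver-side ligand-receptor-TF knowledge graph
#'
#' Directed gene graph wiring the ligand-receptor pairs and the pathway
#' edge list, restricted to genes measured and expressed in the receiver
#' cells, with each edge weighted by the co-expression coefficient
#' (Pearson correlation of log-normalized expression across the receiver
#' cells) of its endpoint genes. Edges with non-positive or undefined
#' coefficients are pruned, so remaining weights lie in (0, 1].
#'
#' @param prior a \linkS4class{PriorKnowledge}.
#' @param receiverExpr \linkS4class{STData} restricted to the receiver
#'   type's cells (at least 3, otherwise the correlation is meaningless).
#' @param config a \linkS4class{RunConfig} (\code{minExpr},
#'   \code{scaleFactor}).
#' @param method correlation flavor: \code{"pearson"} (default) or
#'   \code{"spearman"}.
#' @return a \linkS4class{KnowledgeGraph}.
#' @export
buildLRTKG <- function(prior, receiverExpr, config = runConfig(),
                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is(prior, "PriorKnowledge"), is(receiverExpr, "STData"))
  if (dim(receiverExpr)[2] < 3)
    stop("receiver needs at least 3 cells for co-expression weights")
  if (is.null(assayLogcounts(receiverExpr))) {
    receiverExpr <- logNormalize(receiverExpr, config@scaleFactor)
  }
  lri <- lriPairs(prior)
  pe <- pathwayEdges(prior)
  cand <- rbind(
    if (nrow(lri)) data.frame(src = lri$ligand, dest = lri$receptor,
                              source = "LRI", stringsAsFactors = FALSE),
    if (nrow(pe)) data.frame(src = pe$src, dest = pe$dest,
                             source = pe$source, stringsAsFactors = FALSE))
  if (is.null(cand) || nrow(cand) == 0) stop("no candidate edges in prior")
  genes <- geneNames(receiverExpr)
  cnt <- assayCounts(receiverExpr)
  expressed <- genes[Matrix::rowSums(cnt > config@minExpr) > 0]
  cand <- cand[cand$src %in% expressed & cand$dest %in% expressed, ,
               drop = FALSE]
  cand <- unique(cand)
  if (nrow(cand) == 0) {
    g <- igraph::make_empty_graph(directed = TRUE)
  } else {
    used <- unique(c(cand$src, cand$dest))
    lg <- t(as.matrix(assayLogcounts(receiverExpr)[used, , drop = FALSE]))
    w <- vapply(seq_len(nrow(cand)), function(i) {
      suppressWarnings(stats::cor(lg[, cand$src[i]], lg[, cand$dest[i]],
                                  method = method))
    }, numeric(1))
    keep <- !is.na(w) & w > 0
    cand <- cand[keep, , drop = FALSE]
    w <- w[keep]
    verts <- unique(c(cand$src, cand$dest))
    g <- igraph::graph_from_data_frame(
      data.frame(from = cand$src, to = cand$dest, weight = w,
                 source = cand$source, stringsAsFactors = FALSE),
      directed = TRUE, vertices = verts)
  }
  vn <- igraph::V(g)$name
  anno <- data.frame(gene = vn,
                     is_ligand = vn %in% lri$ligand,
                     is_receptor = vn %in% lri$receptor,
                     is_tf = vn %in% tfSet(prior),
                     stringsAsFactors = FALSE)
  new("KnowledgeGraph", graph = g, nodeAnno = anno,
      receiverType = if (length(unitNames(receiverExpr)))
        "receiver" else character(0))
}

#' Random-walk TF activation probabilities
#'
#' Runs \code{zWalk} bounded random walks on the knowledge graph starting
#' at the receptor. Each step moves to an out-neighbor with probability
#' proportional to the edge weight; a walk terminates on first hitting a
#' TF (TFs are absorbing) or after \code{maxWalkSteps} steps (or at a dead
#' end). For each TF, the hit probability p is the fraction of walks that
#' ended there, and the step count eta is the mean first-hit step over
#' those walks, rounded to the nearest integer (at least 1).
#'
#' Ligand-only nodes (annotated ligand but neither receptor nor TF) do not
#' belong to the receiver-side signaling cascade and are removed from the
#' walk graph.
#'
#' @param kg a \linkS4class{KnowledgeGraph}.
#' @param receptor the query receptor gene.
#' @param config a \linkS4class{RunConfig} (\code{zWalk},
#'   \code{maxWalkSteps}).
#' @return data.frame with columns \code{tf}, \code{p}, \code{eta},
#'   \code{hits}; zero rows when the receptor is absent or isolated.
#' @export
randomWalkTF <- function(kg, receptor, config = runConfig()) {
  stopifnot(is(kg, "KnowledgeGraph"))
  g <- kgGraph(kg)
  anno <- kgNodes(kg)
  drop <- anno$gene[anno$is_ligand & !anno$is_receptor & !anno$is_tf]
  drop <- setdiff(drop, receptor)
  if (length(drop)) g <- igraph::delete_vertices(g, drop)
  vn <- igraph::V(g)$name
  if (!(receptor %in% vn)) return(.emptyTFActivation())
  n <- length(vn)
  tfFlag <- vn %in% anno$gene[anno$is_tf]
  el <- igraph::as_data_frame(g, what = "edges")
  if (nrow(el) == 0) return(.emptyTFActivation())
  adj <- split(seq_len(nrow(el)), match(el$from, vn))
  nbr <- lapply(seq_len(n), function(i) {
    eidx <- adj[[as.character(i)]]
    if (is.null(eidx)) return(NULL)
    list(to = match(el$to[eidx], vn), w = el$weight[eidx])
  })
  start <- match(receptor, vn)
  if (is.null(nbr[[start]])) return(.emptyTFActivation())
  Z <- config@zWalk
  cur <- rep.int(start, Z)
  alive <- rep(TRUE, Z)
  hitNode <- integer(Z)
  hitStep <- integer(Z)
  for (step in seq_len(config@maxWalkSteps)) {
    idxAlive <- which(alive)
    if (!length(idxAlive)) break
    for (u in unique(cur[idxAlive])) {
      at <- idxAlive[cur[idxAlive] == u]
      nb <- nbr[[u]]
      if (is.null(nb)) {
        alive[at] <- FALSE
      } else if (length(nb$to) == 1L) {
        cur[at] <- nb$to
      } else {
        cur[at] <- nb$to[sample.int(length(nb$to), length(at),
                                    replace = TRUE, prob = nb$w)]
      }
    }
    hit <- alive & tfFlag[cur]
    if (any(hit)) {
      hitNode[hit] <- cur[hit]
      hitStep[hit] <- step
      alive[hit] <- FALSE
    }
  }
  hits <- which(hitNode > 0)
  if (!length(hits)) return(.emptyTFActivation())
  bytf <- split(hitStep[hits], vn[hitNode[hits]])
  data.frame(tf = names(bytf),
             p = lengths(bytf) / Z,
             eta = pmax(1, round(vapply(bytf, mean, numeric(1)))),
             hits = lengths(bytf),
             row.names = NULL, stringsAsFactors = FALSE)
}

.emptyTFActivation <- function() {
  data.frame(tf = character(0), p = numeric(0), eta = numeric(0),
             hits = integer(0), stringsAsFactors = FALSE)
}

#' Intracellular activation score
#'
#' Sums, over the TFs reached by the random walk, the number of expressed
#' target genes times the hit probability divided by the step count
#' (theta * p / eta), then squashes through the logistic sigmoid. A TF is
#' retained only if it is itself expressed in enough receiver cells and
#' has at least one expressed target; with no retained TF the interaction
#' is considered not to activate downstream signaling and the score is 0
#' (not logistic(0) = 0.5, which would leak a nonzero combined score).
#'
#' Target genes of a TF are its non-TF out-neighbors in the knowledge
#' graph; a gene counts as expressed when its raw count exceeds
#' \code{minExpr} in at least \code{minCellsFrac} of the receiver cells.
#'
#' @param tfActivations data.frame from \code{\link{randomWalkTF}}.
#' @param receiverExpr \linkS4class{STData} of the receiver cells.
#' @param kg the \linkS4class{KnowledgeGraph} the walk ran on.
#' @param config a \linkS4class{RunConfig}.
#' @return list with \code{S_intra_raw}, \code{S_intra}, and
#'   \code{activations} (the retained TFs with their theta).
#' @export
intracellularScore <- function(tfActivations, receiverExpr, kg,
                               config = runConfig()) {
  stopifnot(is(kg, "KnowledgeGraph"), is(receiverExpr, "STData"))
  if (nrow(tfActivations) == 0) {
    return(list(S_intra_raw = 0, S_intra = 0,
                activations = cbind(tfActivations, theta = integer(0))))
  }
  g <- kgGraph(kg)
  anno <- kgNodes(kg)
  cnt <- assayCounts(receiverExpr)
  nc <- ncol(cnt)
  exprFrac <- Matrix::rowSums(cnt > config@minExpr) / nc
  isExpr <- function(gene) {
    gene %in% rownames(cnt) && exprFrac[gene] >= config@minCellsFrac
  }
  tfs <- anno$gene[anno$is_tf]
  theta <- integer(nrow(tfActivations))
  keep <- logical(nrow(tfActivations))
  vn <- igraph::V(g)$name
  for (i in seq_len(nrow(tfActivations))) {
    tf <- tfActivations$tf[i]
    if (!(tf %in% vn) || !isExpr(tf)) next
    targ <- setdiff(names(igraph::neighbors(g, tf, mode = "out")), tfs)
    targ <- targ[vapply(targ, isExpr, logical(1))]
    theta[i] <- length(targ)
    keep[i] <- length(targ) >= 1
  }
  acts <- cbind(tfActivations, theta = theta)[keep, , drop = FALSE]
  if (nrow(acts) == 0) {
    return(list(S_intra_raw = 0, S_intra = 0, activations = acts))
  }
  raw <- sum(acts$theta * acts$p / acts$eta)
  list(S_intra_raw = raw, S_intra = stats::plogis(raw), activations = acts)
}

#' Combined communication score
#'
#' Geometric mean of the inter-cellular (spatial permutation) and
#' intracellular (downstream activation) scores. An interaction failing
#' either stage (NA or zero on either side) scores 0.
#'
#' @param sInter,sIntra numeric vectors in [0, 1] (NAs allowed).
#' @return numeric vector in [0, 1].
#' @examples
#' combinedScore(0.96, 0.25)  # sqrt(0.24)
#' @export
combinedScore <- function(sInter, sIntra) {
  out <- sqrt(pmax(sInter, 0) * pmax(sIntra, 0))
  out[is.na(sInter) | is.na(sIntra)] <- 0
  out
}

#' Export a knowledge graph as a weighted edge list
#'
#' @param kg a \linkS4class{KnowledgeGraph}.
#' @param path output TSV path (from, to, weight, source).
#' @export
writeKnowledgeGraph <- function(kg, path) {
  el <- igraph::as_data_frame(kgGraph(kg), what = "edges")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
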