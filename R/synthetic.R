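#' Default synthetic study scenario
#'
#' A four-type, 200-gene, 800-cell design on the unit square: each type
#' occupies a vertical stripe, ten marker genes per type (mean fold change
#' well above 4), one planted ligand-receptor interaction from the first
#' (sender) to the second (receiver) stripe with a downstream
#' receptor -> TF -> targets chain planted in the receiver, ten decoy
#' ligand-receptor pairs, and negative-binomial counts (dispersion 0.5),
#' matching the overdispersion of real spatial count data.
#'
#' @param nTypes,nGenes,cellsPerType,nMarkers design sizes.
#' @param layout \code{"stripes"}, \code{"checkerboard"}, or
#'   \code{"random"} (positions and labels independent -- the null
#'   construction).
#' @param planted plant the ligand-receptor signal and its chain
#'   (default TRUE; FALSE gives a decoy-only null prior).
#' @param nDecoyLRI decoy pair count.
#' @param noise \code{"nb"}, \code{"poisson"}, or \code{"none"}.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param baseMu,markerMu baseline and marker mean counts.
#' @return a \linkS4class{SyntheticScenario}.
#' @export
syntheticScenario <- function(nTypes = 4L, nGenes = 200L,
                              cellsPerType = 200L, nMarkers = 10L,
                              layout = "stripes", planted = TRUE,
                              nDecoyLRI = 10L, noise = "nb",
                              dispersion = 0.5, baseMu = 0.5,
                              markerMu = 4) {
  plantedLRI <- if (planted) {
    data.frame(ligand = "LIG1", receptor = "REC1", sender = "T1",
               receiver = "T2", effect = markerMu * 2,
               stringsAsFactors = FALSE)
  } else {
    data.frame(ligand = character(0), receptor = character(0),
               sender = character(0), receiver = character(0),
               effect = numeric(0), stringsAsFactors = FALSE)
  }
  chains <- if (planted) {
    list(list(receptor = "REC1", tf = "TF1", targets = c("TGT1", "TGT2")))
  } else list()
  new("SyntheticScenario", nTypes = as.integer(nTypes),
      nGenes = as.integer(nGenes), cellsPerType = as.integer(cellsPerType),
      nMarkers = as.integer(nMarkers), layout = layout,
      plantedLRI = plantedLRI, plantedChains = chains,
      nDecoyLRI = as.integer(nDecoyLRI), noise = noise,
      dispersion = dispersion, baseMu = baseMu, markerMu = markerMu)
}

# Gene universe and per-type mean matrix (genes x types) of a scenario.
.scenarioMeans <- function(scenario) {
  k <- scenario@nTypes
  types <- paste0("T", seq_len(k))
  plantedGenes <- unique(c(scenario@plantedLRI$ligand,
                           unlist(lapply(scenario@plantedChains, function(ch)
                             c(ch$receptor, ch$tf, ch$targets)))))
  nMark <- scenario@nMarkers * k
  markers <- if (scenario@nMarkers > 0) {
    as.vector(vapply(seq_len(k), function(t)
      sprintf("MK%d_%02d", t, seq_len(scenario@nMarkers)),
      character(scenario@nMarkers)))
  } else character(0)
  nFill <- scenario@nGenes - length(plantedGenes) - nMark
  if (nFill < 0) stop("nGenes too small for markers and planted genes")
  fillers <- sprintf("FL%03d", seq_len(nFill))
  genes <- c(markers, plantedGenes, fillers)
  mu <- matrix(scenario@baseMu, length(genes), k,
               dimnames = list(genes, types))
  lowMu <- scenario@baseMu / 5
  for (t in seq_len(k)) {
    if (scenario@nMarkers > 0) {
      mk <- sprintf("MK%d_%02d", t, seq_len(scenario@nMarkers))
      mu[mk, ] <- lowMu
      mu[mk, t] <- scenario@markerMu
    }
  }
  if (nrow(scenario@plantedLRI)) {
    for (i in seq_len(nrow(scenario@plantedLRI))) {
      pr <- scenario@plantedLRI[i, ]
      # planted genes are strictly type-specific so the planted signal is
      # unambiguous: ligand only in the sender, receptor and chain only in
      # the receiver
      mu[pr$ligand, ] <- 0
      mu[pr$ligand, pr$sender] <- pr$effect
      downstream <- pr$receptor
      for (ch in scenario@plantedChains) {
        if (ch$receptor == pr$receptor) {
          downstream <- c(downstream, ch$tf, ch$targets)
        }
      }
      mu[downstream, ] <- 0
      mu[downstream, pr$receiver] <- pr$effect
    }
  }
  list(mu = mu, genes = genes, types = types, fillers = fillers,
       markers = markers)
}

# Pathway co-activation: cells of a chain's receiver type get a shared
# per-cell activity factor (gamma, mean 1) scaling the whole
# receptor -> TF -> targets chain, inducing the positive co-expression
# real signaling cascades show (and the knowledge-graph weights assume).
.applyChainActivity <- function(muCells, labels, scenario) {
  if (!nrow(scenario@plantedLRI)) return(muCells)
  for (i in seq_len(nrow(scenario@plantedLRI))) {
    pr <- scenario@plantedLRI[i, ]
    for (ch in scenario@plantedChains) {
      if (ch$receptor != pr$receptor) next
      genes <- c(ch$receptor, ch$tf, ch$targets)
      cells <- which(labels == pr$receiver)
      if (!length(cells)) next
      act <- stats::rgamma(length(cells), shape = 2, rate = 2)
      muCells[genes, cells] <- muCells[genes, cells] *
        rep(act, each = length(genes))
    }
  }
  muCells
}

# Draw a count matrix (genes x cells) from per-cell mean columns.
.drawCounts <- function(muCells, scenario) {
  n <- nrow(muCells); m <- ncol(muCells)
  x <- switch(scenario@noise,
    none = round(muCells),
    poisson = matrix(stats::rpois(n * m, muCells), n, m),
    nb = matrix(stats::rnbinom(n * m, mu = muCells,
                               size = 1 / scenario@dispersion), n, m))
  dimnames(x) <- dimnames(muCells)
  x
}

#' Generate a labeled synthetic scRNA-seq reference
#'
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @param seed RNG seed (set when non-NULL).
#' @return list with \code{expr} (\linkS4class{STData}) and \code{labels}
#'   (named character vector cell -> type).
#' @export
generateReference <- function(scenario, seed = NULL) {
  if (scenario@cellsPerType < 3L) stop("cellsPerType must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  sm <- .scenarioMeans(scenario)
  cells <- paste0("ref", seq_len(scenario@nTypes * scenario@cellsPerType))
  labels <- rep(sm$types, each = scenario@cellsPerType)
  muCells <- sm$mu[, labels, drop = FALSE]
  colnames(muCells) <- cells
  muCells <- .applyChainActivity(muCells, labels, scenario)
  cnt <- .drawCounts(muCells, scenario)
  list(expr = STData(cnt), labels = stats::setNames(labels, cells))
}

#' Generate a synthetic single-cell spatial atlas
#'
#' Cells of each type are placed in their zone of the unit square
#' (vertical stripes by default, a checkerboard to stress the quadrant
#' sampler, or uniformly with random labels for the null construction) and
#' counts are drawn from the same per-type means as the reference, so the
#' planted ligand-receptor pair is spatially proximal between adjacent
#' sender/receiver zones.
#'
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @param seed RNG seed.
#' @param binSize when non-NULL, additionally aggregates the atlas into
#'   simulated spots of this size via \code{\link{simulateSpots}}.
#' @return list with \code{atlas} (\linkS4class{CellAtlas}) and, when
#'   requested, \code{spots} (the \code{\link{simulateSpots}} output).
#' @export
generateSpatial <- function(scenario, seed = NULL, binSize = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sm <- .scenarioMeans(scenario)
  k <- scenario@nTypes
  nCells <- k * scenario@cellsPerType
  cells <- paste0("sc", seq_len(nCells))
  if (scenario@layout == "random") {
    labels <- sample(sm$types, nCells, replace = TRUE)
    x <- stats::runif(nCells)
    y <- stats::runif(nCells)
  } else if (scenario@layout == "stripes") {
    labels <- rep(sm$types, each = scenario@cellsPerType)
    t <- match(labels, sm$types)
    x <- (t - 1 + stats::runif(nCells)) / k
    y <- stats::runif(nCells)
  } else { # checkerboard
    labels <- rep(sm$types, each = scenario@cellsPerType)
    t <- match(labels, sm$types)
    g <- 2L * ceiling(sqrt(k) / 2) + 2L  # grid side
    cellBlock <- vapply(t, function(tt) {
      blocks <- which((outer(seq_len(g), seq_len(g),
                             function(i, j) (i + j) %% k)) == (tt %% k))
      sample(blocks, 1)
    }, numeric(1))
    bi <- (cellBlock - 1) %% g
    bj <- (cellBlock - 1) %/% g
    x <- (bi + stats::runif(nCells)) / g
    y <- (bj + stats::runif(nCells)) / g
  }
  muCells <- sm$mu[, labels, drop = FALSE]
  colnames(muCells) <- cells
  muCells <- .applyChainActivity(muCells, labels, scenario)
  cnt <- .drawCounts(muCells, scenario)
  coords <- data.frame(x = x, y = y, row.names = cells)
  expr <- STData(cnt, coords = coords)
  placements <- data.frame(cell = cells, type = labels, x = x, y = y,
                           spot = cells, ref_cell = cells,
                           alpha = NA_real_, theta = NA_real_,
                           stringsAsFactors = FALSE)
  atlas <- new("CellAtlas", placements = placements, expr = expr)
  out <- list(atlas = atlas)
  if (!is.null(binSize)) out$spots <- simulateSpots(atlas, binSize)
  out
}

#' Generate the matching synthetic prior knowledge
#'
#' The ligand-receptor table holds the planted pair(s) plus decoys drawn
#' from filler genes; the pathway edge list wires each planted chain
#' (receptor -> TF -> targets) plus random decoy edges among fillers; the
#' TF list holds the chain TFs plus decoy TFs; pathway membership sets
#' include one set per chain and random decoy sets.
#'
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @param seed RNG seed.
#' @param nDecoyEdges random decoy pathway edges (default 20).
#' @param nDecoySets random decoy pathway membership sets (default 3).
#' @return a \linkS4class{PriorKnowledge}.
#' @export
generatePrior <- function(scenario, seed = NULL, nDecoyEdges = 20L,
                          nDecoySets = 3L) {
  if (!is.null(seed)) set.seed(seed)
  sm <- .scenarioMeans(scenario)
  pool <- sm$fillers
  if (length(pool) < 4) stop("scenario has too few filler genes for decoys")
  lri <- scenario@plantedLRI[, c("ligand", "receptor")]
  nd <- scenario@nDecoyLRI
  while (nd > 0) {
    cand <- data.frame(ligand = sample(pool, nd, replace = TRUE),
                       receptor = sample(pool, nd, replace = TRUE),
                       stringsAsFactors = FALSE)
    cand <- cand[cand$ligand != cand$receptor, , drop = FALSE]
    lri <- unique(rbind(lri, cand))
    nd <- scenario@nDecoyLRI + nrow(scenario@plantedLRI) - nrow(lri)
  }
  rownames(lri) <- NULL
  pw <- data.frame(src = character(0), dest = character(0),
                   source = character(0), stringsAsFactors = FALSE)
  tfs <- character(0)
  psets <- list()
  ci <- 0L
  for (ch in scenario@plantedChains) {
    ci <- ci + 1L
    pw <- rbind(pw, data.frame(
      src = c(ch$receptor, rep(ch$tf, length(ch$targets))),
      dest = c(ch$tf, ch$targets),
      source = paste0("CHAIN", ci), stringsAsFactors = FALSE))
    tfs <- c(tfs, ch$tf)
    psets[[paste0("CHAIN", ci)]] <- unique(c(ch$receptor, ch$tf,
                                             ch$targets))
  }
  if (nDecoyEdges > 0) {
    de <- data.frame(src = sample(pool, nDecoyEdges, replace = TRUE),
                     dest = sample(pool, nDecoyEdges, replace = TRUE),
                     source = "DECOY", stringsAsFactors = FALSE)
    de <- de[de$src != de$dest, , drop = FALSE]
    pw <- unique(rbind(pw, de))
  }
  tfs <- unique(c(tfs, sample(pool, min(3L, length(pool)))))
  for (i in seq_len(nDecoySets)) {
    psets[[paste0("DECOYSET", i)]] <-
      sample(sm$genes, min(8L, length(sm$genes)))
  }
  rownames(pw) <- NULL
  new("PriorKnowledge", lri = lri, pathways = pw, tfs = tfs,
      pathwaySets = psets)
}

#' Write all scenario inputs in the formats the readers accept
#'
#' Emits the reference matrix and labels, the spatial expression matrix
#' and coordinates, the ligand-receptor table, the pathway edge list, the
#' GMT membership sets, and the TF list into a directory.
#'
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @param dir output directory (created if needed).
#' @param seed RNG seed driving all draws.
#' @return invisible named character vector of file paths.
#' @export
writeScenarioFiles <- function(scenario, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  ref <- generateReference(scenario)
  sp <- generateSpatial(scenario)
  prior <- generatePrior(scenario)
  paths <- c(
    ref = file.path(dir, "reference.tsv"),
    ref_labels = file.path(dir, "reference_labels.tsv"),
    st = file.path(dir, "st.tsv"),
    coords = file.path(dir, "coords.tsv"),
    lri = file.path(dir, "lri.tsv"),
    pathways = file.path(dir, "pathways.tsv"),
    gmt = file.path(dir, "pathways.gmt"),
    tfs = file.path(dir, "tfs.txt"))
  writeExpression(ref$expr, paths["ref"])
  utils::write.table(
    data.frame(cell = names(ref$labels), type = unname(ref$labels)),
    paths["ref_labels"], sep = "\t", quote = FALSE, row.names = FALSE)
  writeExpression(atlasExpression(sp$atlas), paths["st"])
  pl <- atlasPlacements(sp$atlas)
  utils::write.table(data.frame(unit = pl$cell, x = pl$x, y = pl$y),
                     paths["coords"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(lriPairs(prior), paths["lri"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(pathwayEdges(prior), paths["pathways"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeGMT(pathwaySets(prior), paths["gmt"])
  writeLines(tfSet(prior), paths["tfs"])
  invisible(paths)
}
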