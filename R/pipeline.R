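#' Deconvolve an ST dataset against a labeled reference
#'
#' Reads the ST matrix, coordinates, reference matrix and labels, log
#' normalizes both sides, builds the per-type reference profile, and fits
#' the non-negative linear model. In \code{"cell"} mode a label is
#' assigned to every unit; in \code{"spot"} mode the per-spot proportions
#' are the product.
#'
#' @param stPath,coordsPath,refPath,refLabelsPath input files (delimited;
#'   see \code{\link{readExpression}}, \code{\link{readCoordinates}}).
#' @param mode \code{"cell"} (single-cell resolution) or \code{"spot"}.
#' @param config a \linkS4class{RunConfig}.
#' @return list with \code{st} (\linkS4class{STData}), \code{ref},
#'   \code{refLabels}, \code{profile}, \code{composition}, and in cell
#'   mode \code{labels} (from \code{\link{assignCellLabels}}).
#' @export
decomposePipeline <- function(stPath, coordsPath, refPath, refLabelsPath,
                              mode = c("cell", "spot"),
                              config = runConfig()) {
  mode <- match.arg(mode)
  st <- readExpression(stPath)
  st <- attachCoordinates(st, readCoordinates(coordsPath))
  st <- logNormalize(st, config@scaleFactor)
  ref <- logNormalize(readExpression(refPath), config@scaleFactor)
  labTab <- utils::read.table(refLabelsPath, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  refLabels <- stats::setNames(labTab[[2]], labTab[[1]])
  prof <- buildReferenceProfile(ref, refLabels, stGenes = geneNames(st),
                                scaleFactor = config@scaleFactor)
  genes <- rownames(referenceProfile(prof))
  comp <- fitNNLM(linearLayer(st, config@scaleFactor)[genes, ,
                                                      drop = FALSE],
                  prof, config,
                  rawCounts = assayCounts(st)[genes, , drop = FALSE])
  out <- list(st = st, ref = ref, refLabels = refLabels, profile = prof,
              composition = comp)
  if (mode == "cell") out$labels <- assignCellLabels(comp, config)
  out
}

#' Reconstruct a single-cell atlas from spot data
#'
#' Chains \code{\link{decomposePipeline}} (spot mode),
#' \code{\link{spotCellCombination}}, \code{\link{selectSpotCells}}, and
#' \code{\link{reconstructAtlas}}.
#'
#' @inheritParams decomposePipeline
#' @return list with the decomposition pieces plus \code{combinations}
#'   and \code{atlas}.
#' @export
reconstructPipeline <- function(stPath, coordsPath, refPath, refLabelsPath,
                                config = runConfig()) {
  dec <- decomposePipeline(stPath, coordsPath, refPath, refLabelsPath,
                           mode = "spot", config = config)
  P <- compositionProps(dec$composition)
  unsure <- unsureMask(dec$composition)
  lg <- assayLogcounts(dec$st)
  genes <- rownames(referenceProfile(dec$profile))
  combos <- list()
  for (j in seq_len(ncol(P))) {
    spot <- colnames(P)[j]
    if (unsure[j]) next
    om <- spotCellCombination(P[, j], config@maxCells,
                              spotNonzero = sum(P[, j]) > 0)
    y <- as.numeric(lg[genes, spot])
    names(y) <- genes
    combos[[spot]] <- selectSpotCells(y, om, dec$ref, dec$refLabels,
                                      config)
  }
  atlas <- reconstructAtlas(dec$st, dec$composition, combos, dec$ref,
                            config)
  c(dec, list(combinations = combos, atlas = atlas))
}

#' Score communications from files
#'
#' @param atlasPath atlas placement TSV (columns cell, type, x, y, ...).
#' @param exprPath expression matrix over the atlas cells.
#' @param lriPath,pathwaysPath,tfsPath prior knowledge files
#'   (\code{\link{readPriorKnowledge}}).
#' @param config a \linkS4class{RunConfig}.
#' @return the \code{\link{scoreCommunications}} table.
#' @export
communicatePipeline <- function(atlasPath, exprPath, lriPath,
                                pathwaysPath = NULL, tfsPath = NULL,
                                config = runConfig()) {
  atlas <- .readAtlasFiles(atlasPath, exprPath)
  prior <- readPriorKnowledge(lriPath, pathwaysPath, tfsPath)
  scoreCommunications(atlas, prior, config)
}

#' Write an atlas as delimited tables
#'
#' @param atlas a \linkS4class{CellAtlas}.
#' @param dir output directory; writes \code{atlas.tsv} (placements) and
#'   \code{atlas_expr.tsv} (raw counts).
#' @return invisible paths.
#' @export
writeAtlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "atlas.tsv")
  p2 <- file.path(dir, "atlas_expr.tsv")
  utils::write.table(atlasPlacements(atlas), p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeExpression(atlasExpression(atlas), p2)
  invisible(c(atlas = p1, expr = p2))
}

# Rebuild a CellAtlas from the atlas.tsv / atlas_expr.tsv pair.
.readAtlasFiles <- function(atlasPath, exprPath) {
  pl <- utils::read.table(atlasPath, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (col in c("spot", "ref_cell")) if (is.null(pl[[col]]))
    pl[[col]] <- pl$cell
  for (col in c("alpha", "theta")) if (is.null(pl[[col]]))
    pl[[col]] <- NA_real_
  expr <- readExpression(exprPath)[, pl$cell]
  expr <- STData(assayCounts(expr),
                 coords = data.frame(x = pl$x, y = pl$y,
                                     row.names = pl$cell))
  new("CellAtlas",
      placements = pl[, c("cell", "type", "x", "y", "spot", "ref_cell",
                          "alpha", "theta")],
      expr = expr)
}

# ---- command-line dispatch (used by inst/scripts/stcrosstalk) ----------

.cliOption <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 0) return(default)
  if (i[1] == length(args)) stop("missing value for ", flag)
  args[i[1] + 1]
}

#' Command-line entry point
#'
#' Thin dispatcher behind the \code{stcrosstalk} script. Subcommands:
#' \code{simulate}, \code{decompose}, \code{reconstruct},
#' \code{communicate}, \code{benchmark}. Every subcommand honors
#' \code{--seed} and writes plain TSV tables, byte-identical across runs
#' at a fixed seed.
#'
#' @param argv character vector of command-line arguments (subcommand
#'   first).
#' @return invisibly, the output paths written.
#' @export
cliMain <- function(argv) {
  if (length(argv) < 1) stop("usage: stcrosstalk <subcommand> [options]")
  sub <- argv[1]
  args <- argv[-1]
  seed <- as.integer(.cliOption(args, "--seed", "1"))
  set.seed(seed)
  out <- .cliOption(args, "--out", ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg <- runConfig(
    K = as.integer(.cliOption(args, "--K", 10)),
    maxCells = as.integer(.cliOption(args, "--max-cells", 30)),
    zPerm = as.integer(.cliOption(args, "--zperm", 1000)),
    zWalk = as.integer(.cliOption(args, "--zwalk", 1000)))
  paths <- character(0)
  if (sub == "simulate") {
    scn <- syntheticScenario(
      nTypes = as.integer(.cliOption(args, "--types", 4)),
      nGenes = as.integer(.cliOption(args, "--genes", 200)),
      cellsPerType = as.integer(.cliOption(args, "--cells-per-type", 200)),
      layout = .cliOption(args, "--layout", "stripes"),
      noise = .cliOption(args, "--noise", "nb"))
    paths <- writeScenarioFiles(scn, out, seed = seed)
  } else if (sub == "decompose") {
    mode <- .cliOption(args, "--mode", "cell")
    dec <- decomposePipeline(.cliOption(args, "--st"),
                             .cliOption(args, "--coords"),
                             .cliOption(args, "--ref"),
                             .cliOption(args, "--ref-labels"),
                             mode = mode, config = cfg)
    p1 <- file.path(out, "composition.tsv")
    utils::write.table(t(compositionProps(dec$composition)), p1,
                       sep = "\t", quote = FALSE, col.names = NA)
    paths <- p1
    if (mode == "cell") {
      p2 <- file.path(out, "labels.tsv")
      utils::write.table(dec$labels, p2, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      # labeled single-cell atlas, ready for `communicate`
      atlas <- atlasFromLabels(dec$st, dec$labels)
      p3 <- file.path(out, "atlas.tsv")
      utils::write.table(atlasPlacements(atlas), p3, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      paths <- c(paths, p2, p3)
    }
  } else if (sub == "reconstruct") {
    rec <- reconstructPipeline(.cliOption(args, "--st"),
                               .cliOption(args, "--coords"),
                               .cliOption(args, "--ref"),
                               .cliOption(args, "--ref-labels"),
                               config = cfg)
    paths <- writeAtlas(rec$atlas, out)
  } else if (sub == "communicate") {
    tab <- communicatePipeline(.cliOption(args, "--atlas"),
                               .cliOption(args, "--expr"),
                               .cliOption(args, "--lri"),
                               .cliOption(args, "--pathways"),
                               .cliOption(args, "--tfs"),
                               config = cfg)
    p1 <- file.path(out, "communication.tsv")
    utils::write.table(tab, p1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- p1
  } else if (sub == "benchmark") {
    mode <- .cliOption(args, "--mode", "pathway")
    if (mode == "pathway") {
      targets <- readLines(.cliOption(args, "--targets"))
      sets <- readGMT(.cliOption(args, "--gmt"))
      universe <- readLines(.cliOption(args, "--universe"))
      tab <- fisherPathwayEnrichment(targets, sets, universe)
      p1 <- file.path(out, "enrichment.tsv")
      utils::write.table(tab, p1, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- p1
    } else if (mode == "decon") {
      atl <- .readAtlasFiles(.cliOption(args, "--atlas"),
                             .cliOption(args, "--expr"))
      sim <- simulateSpots(atl,
                           as.numeric(.cliOption(args, "--bin-size", 0.1)))
      ref <- logNormalize(readExpression(.cliOption(args, "--ref")),
                          cfg@scaleFactor)
      labTab <- utils::read.table(.cliOption(args, "--ref-labels"),
                                  header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
      refLabels <- stats::setNames(labTab[[2]], labTab[[1]])
      prof <- buildReferenceProfile(ref, refLabels,
                                    stGenes = geneNames(sim$spots))
      genes <- rownames(referenceProfile(prof))
      comp <- fitNNLM(linearLayer(sim$spots,
                                  cfg@scaleFactor)[genes, , drop = FALSE],
                      prof, cfg)
      met <- evaluateComposition(comp, sim$truth)
      p1 <- file.path(out, "decon_metrics.tsv")
      utils::write.table(met$perSpot, p1, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      message("mean Pearson r = ", round(met$meanPearson, 4),
              "; mean RMSE = ", round(met$meanRMSE, 4))
      paths <- p1
    } else if (mode == "lri") {
      atl <- .readAtlasFiles(.cliOption(args, "--atlas"),
                             .cliOption(args, "--expr"))
      comm <- utils::read.table(.cliOption(args, "--communication"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
      comm <- comm[!is.na(comm$score) & comm$score > 0, , drop = FALSE]
      graph <- buildKNNGraph(atl, cfg@K)
      expr <- atlasExpression(atl)
      res <- lapply(seq_len(nrow(comm)), function(i) {
        r <- comm[i, ]
        prox <- spatialProximityTest(atl, r$ligand, r$receptor,
                                     r$sender, r$receiver)
        data.frame(sender = r$sender, receiver = r$receiver,
                   ligand = r$ligand, receptor = r$receptor,
                   proximity_P = prox$P, proximity_flag = prox$flag,
                   coexpr_percent = coexpressionPercent(
                     graph, expr, r$sender, r$receiver, r$ligand,
                     r$receptor))
      })
      tab <- if (length(res)) do.call(rbind, res) else
        data.frame(sender = character(0))
      p1 <- file.path(out, "lri_metrics.tsv")
      utils::write.table(tab, p1, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- p1
    } else {
      stop("benchmark --mode must be one of decon, lri, pathway")
    }
  } else {
    stop("unknown subcommand: ", sub)
  }
  invisible(paths)
}
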