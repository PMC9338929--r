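# Shared fixtures and independent oracles, built in code at test time.

# Tiny STData with deterministic counts and optional coordinates.
tinySTData <- function(nGenes = 5, nUnits = 4, coords = FALSE, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(nGenes * nUnits, 3), nGenes, nUnits,
              dimnames = list(sprintf("G%02d", seq_len(nGenes)),
                              sprintf("U%02d", seq_len(nUnits))))
  crd <- if (coords) {
    data.frame(x = runif(nUnits), y = runif(nUnits),
               row.names = colnames(m))
  } else NULL
  STData(m, coords = crd)
}

# A labeled atlas with cells at given coordinates and a raw count matrix.
makeAtlas <- function(counts, types, x, y) {
  cells <- colnames(counts)
  placements <- data.frame(cell = cells, type = types, x = x, y = y,
                           spot = cells, ref_cell = cells,
                           alpha = NA_real_, theta = NA_real_,
                           stringsAsFactors = FALSE)
  expr <- STData(counts, coords = data.frame(x = x, y = y,
                                             row.names = cells))
  new("CellAtlas", placements = placements, expr = expr)
}

# Brute-force O(n^2) oracle for the co-expressed pair count: loops over
# every ordered cell pair restricted to graph edges.
bruteForceLRCount <- function(graph, expr, A, B, ligand, receptor,
                              minExpr = 0) {
  nodes <- graphNodes(graph)
  e <- graphEdges(graph)
  cnt <- as.matrix(assayCounts(expr))
  total <- 0L
  for (i in seq_len(nrow(nodes))) {
    for (j in seq_len(nrow(nodes))) {
      if (i == j) next
      isEdge <- any(e$from == i & e$to == j)
      if (!isEdge) next
      ci <- nodes$cell[i]; cj <- nodes$cell[j]
      if (nodes$type[i] == A && nodes$type[j] == B &&
          cnt[ligand, ci] > minExpr && cnt[receptor, cj] > minExpr) {
        total <- total + 1L
      }
    }
  }
  total
}

# Truncated-absorption oracle for the bounded random walk: propagates the
# full probability vector step by step, TFs absorbing, walks dying at
# dead ends, truncated at maxSteps. Returns named absorption
# probabilities (per TF) and the expected first-hit step.
walkAbsorptionOracle <- function(edges, start, tfs, maxSteps = 10) {
  nodes <- sort(unique(c(edges$from, edges$to, start)))
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    W[edges$from[r], edges$to[r]] <- edges$weight[r]
  }
  rs <- rowSums(W)
  P <- W
  P[rs > 0, ] <- W[rs > 0, ] / rs[rs > 0]
  tfs <- intersect(tfs, nodes)
  p <- numeric(n); p[match(start, nodes)] <- 1
  absorbed <- setNames(numeric(length(tfs)), tfs)
  stepMass <- matrix(0, maxSteps, length(tfs),
                     dimnames = list(NULL, tfs))
  for (s in seq_len(maxSteps)) {
    p <- as.numeric(p %*% P)
    hit <- p[match(tfs, nodes)]
    absorbed <- absorbed + hit
    stepMass[s, ] <- hit
    p[match(tfs, nodes)] <- 0  # absorbing
  }
  eta <- vapply(tfs, function(tf) {
    if (absorbed[tf] == 0) return(NA_real_)
    sum(seq_len(maxSteps) * stepMass[, tf]) / absorbed[tf]
  }, numeric(1))
  list(p = absorbed, eta = eta)
}

# Exhaustive hypergeometric upper-tail oracle for a 2x2 table with fixed
# margins: sums the point probabilities of every table with the first
# cell at least a (log-factorial arithmetic, independent of phyper).
fisherUpperTailOracle <- function(a, b, cc, d) {
  n <- a + b + cc + d
  k <- a + cc  # interested genes drawn
  m <- a + b   # pathway genes
  lo <- max(0, k - (n - m))
  hi <- min(k, m)
  if (a > hi) return(0)
  terms <- vapply(max(a, lo):hi, function(i) {
    exp(lchoose(m, i) + lchoose(n - m, k - i) - lchoose(n, k))
  }, numeric(1))
  sum(terms)
}

# Run the full pipeline (generate -> label -> communicate) on the default
# scenario at one seed; returns the scored table.
runPlantedPipeline <- function(seed, config = runConfig()) {
  set.seed(seed)
  scn <- syntheticScenario()
  sp <- generateSpatial(scn)
  prior <- generatePrior(scn)
  scoreCommunications(sp$atlas, prior, config)
}
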