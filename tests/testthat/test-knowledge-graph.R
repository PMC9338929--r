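# A receiver-side expression fixture whose gene pairs have controlled
# correlation structure: G1/G2 identical, G3 anti-correlated with G1.
corFixture <- function() {
  v <- c(5, 1, 4, 0, 3, 2, 6, 1, 2, 4)
  m <- rbind(G1 = v, G2 = v, G3 = max(v) - v, G4 = v + 1,
             G5 = c(4, 2, 3, 1, 3, 2, 5, 1, 2, 4))  # G4/G5 track G1
  colnames(m) <- paste0("c", 1:10)
  STData(m)
}

priorFromEdges <- function(edges, tfs = character(0),
                           lri = data.frame(ligand = character(0),
                                            receptor = character(0))) {
  new("PriorKnowledge", lri = lri,
      pathways = data.frame(src = edges$from, dest = edges$to,
                            source = "FIX", stringsAsFactors = FALSE),
      tfs = tfs, pathwaySets = list())
}

test_that("knowledge-graph weights equal the receiver co-expression and
           non-positive edges are pruned", {
  expr <- corFixture()
  prior <- priorFromEdges(data.frame(from = c("G1", "G1", "G1"),
                                     to = c("G2", "G3", "G5")))
  kg <- buildLRTKG(prior, expr)
  el <- igraph::as_data_frame(kgGraph(kg))
  # identical expression vectors give weight 1
  expect_equal(el$weight[el$to == "G2"], 1)
  # anti-correlated pair is pruned
  expect_false(any(el$to == "G3"))
  # remaining weight equals an independently computed correlation
  lg <- as.matrix(assayLogcounts(logNormalize(expr)))
  expect_equal(el$weight[el$to == "G5"],
               cor(lg["G1", ], lg["G5", ]))
  expect_error(buildLRTKG(prior, expr[, 1:2]), "3 cells")
})

test_that("chain and branch walks hit TFs with the expected
           probabilities", {
  set.seed(40)
  expr <- corFixture()
  # forced path: receptor -> TF in one step
  kgChain <- buildLRTKG(priorFromEdges(
    data.frame(from = "G1", to = "G2"), tfs = "G2"), expr)
  act <- randomWalkTF(kgChain, "G1", runConfig(zWalk = 200L))
  expect_equal(act$tf, "G2")
  expect_equal(act$p, 1)
  expect_equal(act$eta, 1)

  # two equal-weight absorbing branches split ~50/50
  # R/T1/T2 identical (weight 1 edges); OTH breaks the proportionality
  # that per-cell normalization would otherwise flatten to constants
  v <- c(5, 1, 4, 1, 3, 2, 6, 1, 2, 4)
  expr2 <- STData(rbind(R = v, T1 = v, T2 = v, OTH = rev(v))
                  |> `colnames<-`(paste0("c", 1:10)))
  kg2 <- buildLRTKG(priorFromEdges(
    data.frame(from = c("R", "R"), to = c("T1", "T2")),
    tfs = c("T1", "T2")), expr2)
  Z <- 2000L
  act2 <- randomWalkTF(kg2, "R", runConfig(zWalk = Z))
  expect_setequal(act2$tf, c("T1", "T2"))
  expect_lt(max(abs(act2$p - 0.5)), 3 * sqrt(0.25 / Z))
  expect_equal(sum(act2$p), 1)

  # isolated receptor: empty activation table
  expect_equal(nrow(randomWalkTF(kg2, "T1", runConfig())), 0)
})

test_that("walk probabilities match the truncated-absorption oracle on a
           weighted 6-node graph", {
  # hand-specified weighted directed graph; walks only see these weights
  edges <- data.frame(
    from = c("R", "R", "A", "A", "B", "B", "C"),
    to = c("A", "B", "TF1", "C", "TF2", "A", "TF1"),
    weight = c(0.8, 0.4, 0.5, 0.7, 0.6, 0.3, 0.9))
  tfs <- c("TF1", "TF2")
  g <- igraph::graph_from_data_frame(edges)
  kg <- new("KnowledgeGraph", graph = g,
            nodeAnno = data.frame(gene = igraph::V(g)$name,
                                  is_ligand = FALSE, is_receptor =
                                    igraph::V(g)$name == "R",
                                  is_tf = igraph::V(g)$name %in% tfs),
            receiverType = "fix")
  Z <- 4000L
  set.seed(41)
  act <- randomWalkTF(kg, "R", runConfig(zWalk = Z, maxWalkSteps = 10L))
  oracle <- walkAbsorptionOracle(edges, "R", tfs, maxSteps = 10)
  for (tf in act$tf) {
    p <- oracle$p[tf]
    expect_lt(abs(act$p[act$tf == tf] - p),
              4 * sqrt(p * (1 - p) / Z))
    expect_lt(abs(act$eta[act$tf == tf] - oracle$eta[tf]), 0.6)
  }
  expect_lte(sum(act$p), 1)
})

test_that("ligand-only nodes are excluded from the walk graph", {
  expr <- corFixture()
  # G5 is a ligand wired back to the receptor: without exclusion a walk
  # could escape through it
  prior <- new("PriorKnowledge",
               lri = data.frame(ligand = "G5", receptor = "G1"),
               pathways = data.frame(src = c("G1", "G1"),
                                     to = c("G2", "G5"),
                                     source = "FIX") |>
                 `colnames<-`(c("src", "dest", "source")),
               tfs = "G2", pathwaySets = list())
  kg <- buildLRTKG(prior, expr)
  set.seed(42)
  act <- randomWalkTF(kg, "G1", runConfig(zWalk = 500L))
  # the only remaining out-edge is to the TF
  expect_equal(act$p[act$tf == "G2"], 1)
})

test_that("intracellular score follows the theta * p / eta sum with the
           activation filter", {
  expr <- corFixture()
  prior <- priorFromEdges(
    data.frame(from = c("G1", "G2", "G2"), to = c("G2", "G4", "G5")),
    tfs = "G2")
  kg <- buildLRTKG(prior, expr)
  acts <- data.frame(tf = "G2", p = 1, eta = 1, hits = 100L)
  res <- intracellularScore(acts, expr, kg, runConfig())
  # theta = 2 expressed targets, p = 1, eta = 1
  expect_equal(res$S_intra_raw, 2)
  expect_equal(res$S_intra, 1 / (1 + exp(-2)))
  # no retained TF zeroes the score outright (not logistic(0) = 0.5)
  resEmpty <- intracellularScore(acts[0, ], expr, kg, runConfig())
  expect_equal(resEmpty$S_intra, 0)
  # a TF whose targets are all unexpressed is dropped
  exprOff <- STData(rbind(G1 = rep(3, 10), G2 = rep(2, 10),
                          G4 = rep(0, 10), G5 = rep(0, 10))
                    |> `colnames<-`(paste0("c", 1:10)))
  kgOff <- buildLRTKG(priorFromEdges(
    data.frame(from = c("G1", "G2"), to = c("G2", "G4")), tfs = "G2"),
    exprOff)
  resOff <- intracellularScore(acts, exprOff, kgOff, runConfig())
  expect_equal(resOff$S_intra, 0)
})

test_that("a three-TF activation table reproduces the hand-computed sum", {
  acts <- data.frame(tf = c("TFA", "TFB", "TFC"),
                     p = c(0.5, 0.25, 0.1),
                     eta = c(1, 2, 5), hits = c(50L, 25L, 10L))
  # build a KG where each TF has known expressed targets:
  # TFA -> 2 targets, TFB -> 1, TFC -> 3
  edges <- data.frame(
    from = c("R", rep("TFA", 2), "TFB", rep("TFC", 3)),
    to = c("TFA", "X1", "X2", "X3", "X4", "X5", "X6"))
  # intracellular scoring uses only the graph wiring and expression
  # fractions, so wire the KG directly and express every gene
  m <- matrix(3, 10, 8,
              dimnames = list(c("R", "TFA", "TFB", "TFC",
                                paste0("X", 1:6)), paste0("c", 1:8)))
  expr <- STData(m)
  g <- igraph::graph_from_data_frame(edges)
  kg <- new("KnowledgeGraph", graph = g,
            nodeAnno = data.frame(
              gene = igraph::V(g)$name, is_ligand = FALSE,
              is_receptor = igraph::V(g)$name == "R",
              is_tf = igraph::V(g)$name %in% c("TFA", "TFB", "TFC")),
            receiverType = "fix")
  res <- intracellularScore(acts, expr, kg, runConfig())
  manual <- 2 * 0.5 / 1 + 1 * 0.25 / 2 + 3 * 0.1 / 5
  expect_equal(res$S_intra_raw, manual)
  expect_equal(res$S_intra, stats::plogis(manual))
})

test_that("combined score is the geometric mean with hard zeroes", {
  expect_equal(combinedScore(1, 1), 1)
  expect_equal(combinedScore(0.96, 0.25), sqrt(0.24))
  expect_equal(combinedScore(NA, 0.9), 0)
  expect_equal(combinedScore(0.9, 0), 0)
  # monotone in both arguments over a grid
  g <- seq(0, 1, by = 0.1)
  for (s2 in g) {
    expect_true(all(diff(combinedScore(g, s2)) >= 0))
    expect_true(all(diff(combinedScore(s2, g)) >= 0))
  }
  expect_true(all(combinedScore(runif(50), runif(50)) <= 1))
})
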