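test_that("spot simulation bins cells and conserves counts exactly", {
  m <- matrix(1:16, 4, 4,
              dimnames = list(paste0("G", 1:4), paste0("c", 1:4)))
  atl <- makeAtlas(m, c("A", "A", "B", "B"),
                   x = c(0, 0, 1, 1), y = c(0, 1, 0, 1))
  one <- simulateSpots(atl, binSize = 2)
  expect_equal(ncol(assayCounts(one$spots)), 1)
  expect_equal(as.numeric(assayCounts(one$spots)), unname(rowSums(m)))
  expect_equal(as.numeric(one$truth), c(0.5, 0.5))

  four <- simulateSpots(atl, binSize = 1)
  expect_equal(ncol(assayCounts(four$spots)), 4)
  expect_true(all(lengths(four$members) == 1))
  expect_error(simulateSpots(atl, 0), "positive")
})

test_that("spot simulation conserves totals and truth on a random atlas", {
  set.seed(50)
  scn <- syntheticScenario(nTypes = 3L, nGenes = 40L, cellsPerType = 60L)
  sp <- generateSpatial(scn, binSize = 0.25)
  sim <- sp$spots
  cellCnt <- assayCounts(atlasExpression(sp$atlas))
  expect_equal(sum(assayCounts(sim$spots)), sum(cellCnt))
  expect_equal(sum(lengths(sim$members)), ncol(cellCnt))
  pl <- atlasPlacements(sp$atlas)
  for (s in sample(colnames(assayCounts(sim$spots)), 5)) {
    mem <- sim$members[[s]]
    expect_equal(as.numeric(assayCounts(sim$spots)[, s]),
                 unname(Matrix::rowSums(cellCnt[, mem, drop = FALSE])))
    tv <- table(factor(pl$type[match(mem, pl$cell)],
                       levels = rownames(sim$truth)))
    expect_equal(unname(sim$truth[, s]),
                 as.numeric(tv) / length(mem))
  }
})

test_that("composition metrics match their closed forms", {
  truth <- cbind(s1 = c(1, 0, 0), s2 = c(0.5, 0.25, 0.25))
  rownames(truth) <- c("A", "B", "C")
  perfect <- evaluateComposition(truth, truth)
  expect_equal(perfect$meanPearson, 1)
  expect_equal(perfect$meanRMSE, 0)

  pred <- cbind(s1 = rep(1 / 3, 3), s2 = c(0.5, 0.25, 0.25))
  rownames(pred) <- rownames(truth)
  # a uniform prediction has no correlation but a closed-form RMSE
  expect_warning(met <- evaluateComposition(pred, truth), "constant")
  expect_equal(met$perSpot$rmse[1], sqrt(2 / 9))

  # constant truth spots are skipped with a warning
  truth2 <- cbind(s1 = rep(1 / 3, 3), s2 = c(0.5, 0.25, 0.25))
  rownames(truth2) <- rownames(truth)
  expect_warning(met2 <- evaluateComposition(pred, truth2), "constant")
  expect_true(is.na(met2$perSpot$pearson[1]))
  expect_equal(met2$meanPearson, 1)
})

test_that("composition metrics agree with an independent recomputation", {
  set.seed(51)
  k <- 4; s <- 12
  truth <- matrix(rgamma(k * s, 1), k, s,
                  dimnames = list(paste0("T", 1:k), paste0("s", 1:s)))
  truth <- sweep(truth, 2, colSums(truth), "/")
  pred <- truth + matrix(runif(k * s, 0, 0.2), k, s)
  pred <- sweep(pred, 2, colSums(pred), "/")
  met <- evaluateComposition(pred, truth)
  manual_r <- sapply(1:s, function(j) cor(pred[, j], truth[, j]))
  manual_rmse <- sapply(1:s, function(j)
    sqrt(mean((pred[, j] - truth[, j])^2)))
  expect_equal(met$perSpot$pearson, manual_r)
  expect_equal(met$perSpot$rmse, manual_rmse)
  expect_equal(met$meanPearson, mean(manual_r))
  expect_equal(met$meanRMSE, mean(manual_rmse))
})

test_that("proximity test flags planted adjacency and degenerate input", {
  set.seed(52)
  # senders and receivers interleaved in a tight cluster, others far away
  n <- 40
  types <- c(rep(c("A", "B"), 10), rep("C", 20))
  x <- c(runif(20, 0, 0.1), runif(20, 5, 10))
  y <- c(runif(20, 0, 0.1), runif(20, 5, 10))
  m <- rbind(LIG = ifelse(types == "A", 4, 0),
             REC = ifelse(types == "B", 4, 0),
             OTH = rpois(n, 2))
  colnames(m) <- paste0("c", 1:n)
  atl <- makeAtlas(m, types, x, y)
  res <- spatialProximityTest(atl, "LIG", "REC", "A", "B")
  expect_lt(res$P, 1e-6)
  expect_identical(res$flag, "ok")

  # no expressing pairs
  res0 <- spatialProximityTest(atl, "LIG", "REC", "C", "C")
  expect_equal(res0$P, 1)
  expect_identical(res0$flag, "no-expressing-pairs")

  # a single sender-receiver pair cannot reach significance
  m1 <- rbind(LIG = c(4, rep(0, n - 1)), REC = c(0, 4, rep(0, n - 2)),
              OTH = rpois(n, 2))
  colnames(m1) <- paste0("c", 1:n)
  atl1 <- makeAtlas(m1, types, x, y)
  res1 <- spatialProximityTest(atl1, "LIG", "REC", "A", "B")
  expect_identical(res1$flag, "low-n")
  expect_gt(res1$P, 0.001)
})

test_that("proximity P-values are roughly uniform when labels carry no
           spatial information", {
  set.seed(53)
  pv <- replicate(40, {
    n <- 30
    types <- sample(c("A", "B"), n, TRUE)
    m <- rbind(LIG = rpois(n, 2), REC = rpois(n, 2))
    colnames(m) <- paste0("c", 1:n)
    atl <- makeAtlas(m, types, runif(n), runif(n))
    spatialProximityTest(atl, "LIG", "REC", "A", "B")$P
  })
  expect_gt(mean(pv), 0.25)
  expect_gt(ks.test(pv, "punif")$p.value, 0.001)
})

test_that("co-expression percent matches the brute-force ratio", {
  set.seed(54)
  n <- 30
  m <- matrix(rpois(2 * n, 1), 2, n,
              dimnames = list(c("LIG", "REC"), paste0("c", 1:n)))
  types <- sample(c("A", "B"), n, TRUE)
  atl <- makeAtlas(m, types, runif(n), runif(n))
  g <- buildKNNGraph(atl, K = 5)
  expr <- atlasExpression(atl)
  e <- graphEdges(g)
  ty <- graphNodes(g)$type
  nAB <- sum(ty[e$from] == "A" & ty[e$to] == "B")
  c0 <- bruteForceLRCount(g, expr, "A", "B", "LIG", "REC")
  expect_equal(coexpressionPercent(g, expr, "A", "B", "LIG", "REC"),
               100 * c0 / nAB)

  # all co-expressing / none
  m2 <- matrix(3, 2, n, dimnames = dimnames(m))
  atl2 <- makeAtlas(m2, types, atlasPlacements(atl)$x,
                    atlasPlacements(atl)$y)
  expect_equal(coexpressionPercent(buildKNNGraph(atl2, 5),
                                   atlasExpression(atl2),
                                   "A", "B", "LIG", "REC"), 100)
  m3 <- m2; m3["REC", ] <- 0
  atl3 <- makeAtlas(m3, types, atlasPlacements(atl)$x,
                    atlasPlacements(atl)$y)
  expect_equal(coexpressionPercent(buildKNNGraph(atl3, 5),
                                   atlasExpression(atl3),
                                   "A", "B", "LIG", "REC"), 0)
})

test_that("pathway enrichment matches closed forms and the enumeration
           oracle", {
  universe <- paste0("G", 1:20)
  sets <- list(P1 = paste0("G", 1:5))
  res <- fisherPathwayEnrichment(paste0("G", 1:5), sets, universe)
  expect_equal(res$P, 1 / choose(20, 5))
  expect_equal(res$a, 5)

  # disjoint targets: upper tail at a = 0 is 1
  res0 <- fisherPathwayEnrichment(paste0("G", 10:12), sets, universe)
  expect_equal(res0$P, 1)
  # empty target set: all P = 1
  resE <- fisherPathwayEnrichment(character(0), sets, universe)
  expect_equal(resE$P, 1)

  set.seed(55)
  for (i in 1:300) {
    a <- sample(0:6, 1); b <- sample(0:8, 1)
    cc <- sample(0:6, 1); d <- sample(0:12, 1)
    n <- a + b + cc + d
    if (n == 0 || (a + cc) == 0) next
    universe <- paste0("g", seq_len(n))
    targets <- universe[seq_len(a + cc)]
    pw <- c(universe[seq_len(a)],
            universe[a + cc + seq_len(b)])
    res <- fisherPathwayEnrichment(targets, list(S = pw), universe)
    expect_equal(res$P, fisherUpperTailOracle(a, b, cc, d),
                 tolerance = 1e-12)
  }
})

test_that("pathway enrichment is invariant to gene order and monotone in
           the overlap", {
  set.seed(56)
  universe <- paste0("G", 1:30)
  sets <- list(S = paste0("G", 1:10))
  targets <- paste0("G", c(1:4, 15:20))
  p1 <- fisherPathwayEnrichment(targets, sets, universe)$P
  p2 <- fisherPathwayEnrichment(sample(targets), lapply(sets, sample),
                                sample(universe))$P
  expect_equal(p1, p2)
  # larger overlap at fixed margins decreases the upper-tail P
  ps <- sapply(0:8, function(a) fisherUpperTailOracle(a, 10 - a,
                                                      8 - a, 12 + a))
  expect_true(all(diff(ps) < 0))
})
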