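test_that("reference profile equals independently computed group means", {
  set.seed(10)
  scn <- syntheticScenario(nTypes = 5L, nGenes = 80L, cellsPerType = 12L,
                           nMarkers = 4L)
  ref <- generateReference(scn)
  prof <- buildReferenceProfile(ref$expr, ref$labels)
  X <- referenceProfile(prof)
  lin <- linearLayer(ref$expr)
  for (tp in colnames(X)) {
    cells <- names(ref$labels)[ref$labels == tp]
    expect_equal(unname(X[, tp]), unname(rowMeans(lin[, cells])))
  }
  # arithmetic-mean example: cells [0,2] and [2,0] average to [1,1]
  m <- cbind(c1 = c(0, 2), c2 = c(2, 0), c3 = c(1, 1), c4 = c(1, 1))
  rownames(m) <- c("G1", "G2")
  pr <- buildReferenceProfile(STData(m), c(c1 = "A", c2 = "A",
                                           c3 = "B", c4 = "B"),
                              scaleFactor = 2)
  expect_equal(unname(referenceProfile(pr)[, "A"]), c(1, 1))
})

test_that("reference profile validates labels and shared genes", {
  x <- tinySTData(5, 4)
  expect_error(buildReferenceProfile(x, c(U01 = "A", U02 = "B")),
               "unlabeled")
  lab <- setNames(rep("A", 4), unitNames(x))
  expect_error(buildReferenceProfile(x, lab), "2 cell types")
  lab[3:4] <- "B"
  expect_error(buildReferenceProfile(x, lab, stGenes = "G01"),
               "2 genes")
})

test_that("noiseless mixtures are recovered within 1e-3", {
  set.seed(21)
  for (k in c(2, 4, 6)) {
    X <- matrix(runif(100 * k, 0, 10), 100, k,
                dimnames = list(sprintf("G%03d", 1:100), LETTERS[1:k]))
    beta <- as.numeric(stats::rgamma(k, 1))
    beta <- beta / sum(beta)
    y <- X %*% beta
    comp <- fitNNLM(y, X)
    expect_lt(max(abs(compositionProps(comp)[, 1] - beta)), 1e-3)
  }
  # vertex case: the unit is exactly one type's profile
  X <- matrix(runif(60 * 3, 0, 5), 60, 3,
              dimnames = list(sprintf("G%02d", 1:60), c("A", "B", "C")))
  comp <- fitNNLM(X[, "A"], X)
  expect_equal(unname(compositionProps(comp)[, 1]), c(1, 0, 0),
               tolerance = 1e-3)
})

test_that("multiplicative updates keep weights non-negative and the loss
           non-increasing", {
  set.seed(31)
  X <- matrix(runif(50 * 4, 0, 4), 50, 4)
  rownames(X) <- sprintf("G%02d", 1:50)
  Y <- matrix(rpois(50 * 8, 5), 50, 8, dimnames = list(rownames(X), NULL))
  comp <- fitNNLM(Y, X)
  expect_true(all(compositionWeights(comp) >= 0))
  tr <- lossTrace(comp)
  expect_true(all(diff(tr) <= 1e-8))
})

test_that("degenerate units and genes are handled", {
  X <- cbind(A = c(2, 1, 0), B = c(0, 1, 2))
  rownames(X) <- c("G1", "G2", "G3")
  Y <- cbind(u1 = c(2, 1, 0), u2 = c(0, 0, 0))
  rownames(Y) <- rownames(X)
  comp <- fitNNLM(Y, X, runConfig(minGenes = 1L))
  expect_equal(unname(compositionProps(comp)[, "u2"]), c(0, 0))
  expect_true(unsureMask(comp)[2])
  expect_false(unsureMask(comp)[1])
  # gene the reference cannot explain is dropped with a warning
  X2 <- rbind(X, G4 = c(0, 0))
  Y2 <- rbind(Y, G4 = c(5, 0))
  expect_warning(fitNNLM(Y2, X2, runConfig(minGenes = 1L)),
                 "all-zero reference")
})

test_that("single-cell labels use argmax with tie and unsure rules", {
  P <- cbind(u1 = c(0.9, 0.1), u2 = c(0.5, 0.5), u3 = c(0.28, 0.72),
             u4 = c(0, 0))
  rownames(P) <- c("A", "B")
  comp <- new("Composition", weights = P, props = P,
              converged = rep(TRUE, 4), lossTrace = c(1, 0.5),
              unsureMask = c(FALSE, FALSE, FALSE, TRUE))
  lab <- assignCellLabels(comp, runConfig(unsurePropMin = 0.3))
  expect_identical(lab$type, c("A", "A", "B", "unsure"))
  expect_identical(lab$ambiguous, c(FALSE, TRUE, FALSE, FALSE))
  # max proportion below the floor is unsure too
  lab2 <- assignCellLabels(comp, runConfig(unsurePropMin = 0.95))
  expect_identical(lab2$type, c("unsure", "unsure", "unsure", "unsure"))
})

test_that("spot cell combination follows the rounding and cap rules", {
  expect_identical(spotCellCombination(c(A = 0.52, B = 0.48), 30),
                   c(A = 16L, B = 14L))
  expect_identical(spotCellCombination(c(A = 0.9, B = 0.1), 1),
                   c(A = 1L, B = 0L))
  # uniform over 4 types: raw rounding gives 8 each (sum 32), the two
  # lexicographically first types are decremented to reach 30
  om <- spotCellCombination(rep(0.25, 4) |> setNames(LETTERS[1:4]), 30)
  expect_identical(om, c(A = 7L, B = 7L, C = 8L, D = 8L))
  # overflow with distinct fractional parts: smallest fractions go first
  om2 <- spotCellCombination(c(A = 0.3, B = 0.3, C = 0.2, D = 0.2), 5)
  expect_identical(om2, c(A = 2L, B = 2L, C = 0L, D = 1L))
  # all-zero rounding on a nonzero spot floors the argmax type at 1
  om3 <- spotCellCombination(c(A = 0.4, B = 0.3, C = 0.3), 1)
  expect_identical(om3, c(A = 1L, B = 0L, C = 0L))
})

test_that("spot cell combination conserves its bounds on random inputs", {
  set.seed(5)
  for (i in 1:200) {
    k <- sample(2:8, 1)
    M <- sample(c(1, 5, 10, 30), 1)
    beta <- as.numeric(rgamma(k, 1))
    beta <- beta / sum(beta)
    names(beta) <- paste0("T", seq_len(k))
    om <- spotCellCombination(beta, M)
    expect_true(all(om >= 0))
    expect_lte(sum(om), M)
    expect_gte(sum(om), 1)
  }
})

test_that("spot cell selection matches the exhaustive oracle", {
  # 3 type-A cells, 2 type-B cells, omega = (1, 1): 6 possible draws
  set.seed(8)
  m <- matrix(rpois(10 * 5, 4), 10, 5,
              dimnames = list(sprintf("G%02d", 1:10), paste0("c", 1:5)))
  ref <- logNormalize(STData(m))
  labels <- setNames(c("A", "A", "A", "B", "B"), paste0("c", 1:5))
  lg <- as.matrix(assayLogcounts(ref))
  y <- lg[, 1] * 0.8 + lg[, 5] * 1.1  # near one specific combo
  names(y) <- rownames(lg)
  combos <- expand.grid(a = 1:3, b = 4:5)
  sse <- apply(combos, 1, function(cc)
    sum((y - (lg[, cc[1]] + lg[, cc[2]]))^2))
  best <- combos[which.min(sse), ]
  sel <- selectSpotCells(y, c(A = 1L, B = 1L), ref, labels,
                         runConfig(nRestarts = 300L))
  expect_setequal(sel$cells,
                  paste0("c", c(best$a, best$b)))
  expect_equal(sel$fitError, min(sse))
})

test_that("spot cell selection handles exact matches, empty draws and
           missing types", {
  m <- matrix(rpois(8 * 4, 5), 8, 4,
              dimnames = list(sprintf("G%02d", 1:8), paste0("c", 1:4)))
  ref <- logNormalize(STData(m))
  labels <- setNames(c("A", "A", "B", "B"), paste0("c", 1:4))
  lg <- as.matrix(assayLogcounts(ref))
  y <- lg[, "c1"]
  sel <- selectSpotCells(y, c(A = 1L), ref, labels, runConfig())
  expect_identical(sel$cells, "c1")
  expect_equal(sel$fitError, 0)
  empty <- selectSpotCells(y, c(A = 0L, B = 0L), ref, labels, runConfig())
  expect_length(empty$cells, 0)
  expect_equal(empty$fitError, sum(y^2))
  expect_error(selectSpotCells(y, c(Z = 1L), ref, labels, runConfig()),
               "absent")
})

test_that("selection is reproducible under a fixed seed", {
  set.seed(99)
  m <- matrix(rpois(12 * 10, 4), 12, 10,
              dimnames = list(sprintf("G%02d", 1:12), paste0("c", 1:10)))
  ref <- logNormalize(STData(m))
  labels <- setNames(rep(c("A", "B"), each = 5), paste0("c", 1:10))
  y <- as.matrix(assayLogcounts(ref))[, 2]
  set.seed(7)
  s1 <- selectSpotCells(y, c(A = 2L, B = 1L), ref, labels, runConfig())
  set.seed(7)
  s2 <- selectSpotCells(y, c(A = 2L, B = 1L), ref, labels, runConfig())
  expect_identical(s1, s2)
})
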