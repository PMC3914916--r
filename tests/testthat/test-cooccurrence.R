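test_that("binarize-and-filter stacks tables and applies the >=3 filter", {
  logs <- sprintf("L%02d", 1:5)
  fung <- matrix(0, 5, 2, dimnames = list(logs, c("F1", "F2")))
  fung[1:1, 1] <- 3; fung[1:2, 2] <- 1          # occupancies 1, 2
  motu <- matrix(0, 5, 3, dimnames = list(logs, c("M1", "M2", "M3")))
  motu[1:3, 1] <- 7; motu[1:4, 2] <- 1; motu[1:5, 3] <- 2  # 3, 4, 5
  bm <- binarizeAndFilter(fung, motu, minOccurrence = 3)
  expect_equal(nrow(binaryMatrix(bm)), 3)
  expect_true(all(binaryMatrix(bm) %in% 0:1))
  expect_equal(unname(kingdom(bm)), rep("nifH", 3))
  all <- binarizeAndFilter(fung, motu, applyTo = "matrix")
  expect_equal(nrow(binaryMatrix(all)), 5)
  bad <- motu; rownames(bad) <- sprintf("X%02d", 1:5)
  expect_error(binarizeAndFilter(fung, bad), "disjoint")
})

test_that("a study-sized fixture retains 23 nifH and 27 fungal species", {
  set.seed(20)
  logs <- sprintf("L%02d", 1:45)
  occupancy <- function(n, kmin, kmax) sample(kmin:kmax, n, TRUE)
  fill <- function(n, occ) {
    m <- matrix(0L, 45, n)
    for (j in seq_len(n)) m[sample(45, occ[j]), j] <- 1L
    m
  }
  fung <- fill(40, c(occupancy(27, 3, 20), occupancy(13, 1, 2)))
  motu <- fill(30, c(occupancy(23, 3, 20), occupancy(7, 1, 2)))
  dimnames(fung) <- list(logs, sprintf("F%02d", 1:40))
  dimnames(motu) <- list(logs, sprintf("M%02d", 1:30))
  bm <- binarizeAndFilter(fung, motu, minOccurrence = 3)
  expect_equal(sum(kingdom(bm) == "nifH"), 23)
  expect_equal(sum(kingdom(bm) == "fungus"), 27)
  expect_equal(nrow(binaryMatrix(bm)), 50)
})

test_that("C-score and checkerboard statistics match hand enumeration", {
  bm <- makeBinary(list(c(1, 1, 0, 0), c(0, 1, 1, 0), c(0, 0, 1, 1)))
  # pairs: CU = 1, 4, 1 -> mean 2; one never-co-occurring pair; units 6
  expect_equal(cscore(bm), 2)
  cb <- checkerboardStats(bm)
  expect_equal(cb$neverCooccurPairs, 1)
  expect_equal(cb$checkerboardUnits, 6)

  ident <- makeBinary(list(c(1, 0, 1, 0), c(1, 0, 1, 0)))
  expect_equal(cscore(ident), 0)
  expect_equal(checkerboardStats(ident)$neverCooccurPairs, 0)

  compl <- makeBinary(list(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  expect_equal(cscore(compl), 4)    # r1*r2 for a disjoint pair

  disj <- makeBinary(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  expect_equal(checkerboardStats(disj)$neverCooccurPairs, 3)
  expect_error(cscore(makeBinary(list(c(1, 0, 1)))), "two species")
})

test_that("statistics equal brute-force enumeration on random matrices", {
  set.seed(21)
  for (rep in 1:50) {
    m <- randomBinary(sample(3:8, 1), sample(4:10, 1), runif(1, 0.2, 0.7))
    ref <- brutePairStats(m)
    expect_equal(cscore(m), ref$cscore)
    cb <- checkerboardStats(m)
    expect_equal(cb$neverCooccurPairs, ref$neverPairs)
    expect_equal(cb$checkerboardUnits, ref$units)
  }
})

test_that("checkerboard swaps preserve margins and are reversible", {
  id2 <- matrix(c(1L, 0L, 0L, 1L), 2,
                dimnames = list(c("a", "b"), c("x", "y")))
  once <- swapRandomize(id2, 1, seed = 1)
  expect_equal(unname(once), matrix(c(0L, 1L, 1L, 0L), 2))
  expect_equal(unname(swapRandomize(once, 1, seed = 2)), unname(id2))

  nested <- makeBinary(list(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0)))
  after <- swapRandomize(nested, 500, seed = 3)
  expect_equal(binaryMatrix(after), binaryMatrix(nested))

  set.seed(22)
  for (rep in 1:10) {
    m <- randomBinary(6, 8, 0.4)
    r <- swapRandomize(m, 2000, seed = rep)
    expect_equal(rowSums(r), rowSums(m))
    expect_equal(colSums(r), colSums(m))
  }
})

test_that("null ensembles conserve margins and internal CU identities", {
  set.seed(23)
  bm <- makeBinary(lapply(1:7, function(i) rbinom(9, 1, 0.45)))
  ens <- nullEnsemble(bm, N = 40, seed = 5)
  m0 <- binaryMatrix(bm)
  for (i in seq_len(nullCount(ens))) {
    mi <- nullMatrix(ens, i)
    expect_equal(rowSums(mi), rowSums(m0))
    expect_equal(colSums(mi), colSums(m0))
    # per-matrix consistency: mean CU = C-score, sum CU = units
    expect_equal(mean(ens@pairCU[, i]), ens@cscores[i])
    expect_equal(sum(ens@pairCU[, i]), ens@checkerUnits[i])
    expect_equal(unname(ens@cscores[i]), cscore(mi))
  }
})

test_that("degenerate nested matrices give a warning and a flat null", {
  nested <- makeBinary(list(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0)))
  expect_warning(ens <- nullEnsemble(nested, N = 20, seed = 1),
                 "degenerate")
  expect_true(all(ens@cscores == cscore(nested)))
  pz <- pairwiseZ(ens)
  expect_true(all(pz$z == 0))
  expect_true(all(pz$classification == "none"))
})

test_that("ensemble C-score means agree across seeds and with vegan", {
  set.seed(24)
  m <- randomBinary(8, 10, 0.45)
  bm <- BinaryMatrix(m, rep(c("nifH", "fungus"), 4))
  e1 <- nullEnsemble(bm, N = 150, seed = 1)
  e2 <- nullEnsemble(bm, N = 150, seed = 99)
  se <- sqrt(var(nullCscores(e1)) / 150 + var(nullCscores(e2)) / 150)
  expect_lt(abs(mean(nullCscores(e1)) - mean(nullCscores(e2))), 4 * se)

  # independent route: vegan's sequential swap null model
  nm <- vegan::nullmodel(m, "swap")
  sim <- stats::simulate(nm, nsim = 150, burnin = 2000, thin = 100,
                         seed = 7)
  veganC <- mean(apply(sim, 3, cscore))
  seV <- sqrt(var(apply(sim, 3, cscore)) / 150 +
                var(nullCscores(e1)) / 150)
  expect_lt(abs(mean(nullCscores(e1)) - veganC), 4 * seV)
})

test_that("exact enumeration of a small state space matches the sampler", {
  set.seed(25)
  m <- rbind(c(1L, 1L, 0L, 0L, 1L), c(0L, 1L, 1L, 0L, 0L),
             c(1L, 0L, 1L, 1L, 0L), c(0L, 1L, 0L, 1L, 0L))
  dimnames(m) <- list(sprintf("S%d", 1:4), sprintf("L%d", 1:5))
  states <- enumerateMarginMatrices(rowSums(m), colSums(m))
  exact <- mean(vapply(states, cscore, numeric(1)))
  ens <- nullEnsemble(BinaryMatrix(m, rep(c("nifH", "fungus"), 2)),
                      N = 400, spacing = 50, seed = 9)
  mc <- mean(nullCscores(ens))
  se <- sd(nullCscores(ens)) / sqrt(400)
  expect_lt(abs(mc - exact), 5 * se + 0.02)
})

test_that("matrix-level tests use the add-one tail convention", {
  expect_equal(matrixTest(10, rep(1, 99)), 1 / 100)
  expect_equal(matrixTest(5, rep(5, 99)), 1)
  expect_equal(matrixTest(1, rep(5, 99), tail = "lesser"), 1 / 100)
  expect_error(matrixTest(1, numeric()), "empty")
})

test_that("pairwise Z recovers a planted strength-1 association", {
  logs <- generateLogs(studyDesign(seed = 31))
  occ <- generateOccurrences(
    logs, nFungi = 15, nMotus = 15,
    planted = list(plantedAssociation("M002", "F002", "positive", 1)),
    speciesEffect = 0, decayEffect = 0, richnessRange = NULL, seed = 31)
  bm <- binarizeAndFilter(occ$fungal, occ$motu)
  ens <- nullEnsemble(bm, N = 100, seed = 31)
  pz <- pairwiseZ(ens)
  hit <- pz[(pz$a == "F002" & pz$b == "M002") |
              (pz$a == "M002" & pz$b == "F002"), ]
  expect_equal(nrow(hit), 1)
  expect_lt(hit$z, -1.96)
  expect_equal(hit$classification, "co-occurrence")
  expect_true(all(pz$p > 0 & pz$p <= 1))
})
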