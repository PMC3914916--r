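test_that("Bray-Curtis matches the defining formula", {
  m <- rbind(a = c(2, 0), b = c(1, 1), c = c(2, 0), d = c(0, 3))
  d <- as.matrix(brayCurtis(m))
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "d"], 1)       # disjoint supports
  expect_true(all(d >= 0 & d <= 1))
  expect_error(brayCurtis(rbind(x = c(0, 0), y = c(1, 1))), "x")
  expect_error(brayCurtis(rbind(a = c(-1, 2), b = c(1, 1))),
               "non-negative")
})

test_that("k-means decay classes order by descending mass center", {
  x <- c(90, 91, 70, 71, 50, 51, 30, 31)
  names(x) <- sprintf("L%02d", 1:8)
  k <- kmeansDecayClasses(x, k = 4, seed = 1)
  expect_equal(unname(k$classes), rep(1:4, each = 2))
  expect_equal(k$centers, sort(k$centers, decreasing = TRUE))
  expect_error(kmeansDecayClasses(rep(50, 10), k = 4), "distinct")
})

test_that("1-D k-means attains the exhaustive ordered-partition optimum", {
  set.seed(4)
  for (rep in 1:8) {
    n <- sample(8:12, 1)
    x <- runif(n, 0, 100)
    km <- kmeansDecayClasses(x, k = 4, seed = rep, nstart = 100)
    expect_equal(km$withinss, bruteKmeans1d(x, 4), tolerance = 1e-8)
    # classes form contiguous intervals of remaining mass
    ord <- order(x, decreasing = TRUE)
    expect_true(all(diff(km$classes[ord]) >= 0))
  }
})

test_that("perMANOVA bookkeeping holds on random designs", {
  set.seed(5)
  for (rep in 1:4) {
    n <- 24
    Y <- matrix(rpois(n * 6, 4), n)
    rownames(Y) <- sprintf("L%02d", 1:n)
    meta <- data.frame(g = factor(rep_len(c("x", "y"), n)),
                       h = factor(rep_len(c("a", "b", "c"), n)),
                       z = runif(n))
    pm <- permanova(brayCurtis(Y), ~ g * z + h, meta, nPerm = 99,
                    seed = rep)
    tot <- pm[pm$term == "Total", ]
    expect_equal(tot$Df, n - 1)
    expect_equal(sum(pm$Df[pm$term != "Total"]), tot$Df)
    expect_equal(sum(pm$SS[pm$term != "Total"]), tot$SS,
                 tolerance = 1e-8)
    expect_equal(pm$R2, pm$SS / tot$SS, tolerance = 1e-8)
    ps <- pm$p[!is.na(pm$p)]
    expect_true(all(ps >= 1 / 100 & ps <= 1))
  }
})

test_that("perMANOVA flags strong separation at the permutation floor", {
  n <- 45
  g <- factor(rep_len(c("A", "B"), n))
  Y <- matrix(0, n, 6, dimnames = list(sprintf("L%02d", 1:n), NULL))
  Y[g == "A", 1:3] <- matrix(rpois(sum(g == "A") * 3, 8) + 1, ncol = 3)
  Y[g == "B", 4:6] <- matrix(rpois(sum(g == "B") * 3, 8) + 1, ncol = 3)
  pm <- permanova(brayCurtis(Y), ~ g, data.frame(g = g), nPerm = 999,
                  seed = 1)
  expect_equal(pm$p[pm$term == "g"], 0.001)
})

test_that("perMANOVA rejects rank-deficient designs naming the alias", {
  meta <- data.frame(g = factor(rep(c("x", "y"), each = 6)),
                     gg = factor(rep(c("u", "v"), each = 6)))
  Y <- matrix(rpois(12 * 4, 3) + 1, 12)
  rownames(Y) <- sprintf("L%02d", 1:12)
  expect_error(permanova(brayCurtis(Y), ~ g + gg, meta, nPerm = 49),
               "aliased")
})

test_that("MRT recovers planted structure and obeys SS bookkeeping", {
  set.seed(6)
  n <- 30
  species <- rep(c("Fagus", "Picea"), each = n / 2)
  Y <- matrix(rnorm(n * 5, 0, 0.1), n)
  Y[species == "Fagus", 1] <- Y[species == "Fagus", 1] + 5
  pred <- data.frame(species = species,
                     noise = sample(c("a", "b"), n, TRUE))
  tree <- mrt(Y, pred)
  nodes <- mrtNodes(tree)
  expect_equal(nodes$var[1], "species")
  # child SS never exceeds parent SS along any path
  for (k in which(!is.na(nodes$parent))) {
    expect_lte(nodes$ss[k], nodes$ss[nodes$id == nodes$parent[k]] + 1e-9)
  }
  # leaves partition the samples; leaf SS sums to root SS minus reductions
  expect_equal(sort(unique(mrtGroups(tree))),
               seq_len(sum(nodes$isLeaf)))
  leafSS <- sum(nodes$ss[nodes$isLeaf])
  internal <- nodes[!nodes$isLeaf, ]
  reductions <- sum(vapply(internal$id, function(id) {
    ch <- nodes[!is.na(nodes$parent) & nodes$parent == id, ]
    nodes$ss[nodes$id == id] - sum(ch$ss)
  }, numeric(1)))
  expect_equal(leafSS, tree@rootSS - reductions, tolerance = 1e-8)
})

test_that("single samples and exhaustive splits behave as specified", {
  Y1 <- matrix(rnorm(4), 1)
  t1 <- mrt(Y1, data.frame(g = "a"))
  expect_equal(nrow(mrtNodes(t1)), 1)
  expect_true(mrtNodes(t1)$isLeaf)

  set.seed(8)
  for (rep in 1:6) {
    n <- sample(6:10, 1)
    Y <- matrix(rnorm(n * 3), n)
    pred <- data.frame(f = sample(c("a", "b", "c"), n, TRUE),
                       o = sample(1:4, n, TRUE))
    tree <- mrt(Y, pred, minSplit = 2, maxDepth = 1, minImprove = 0)
    nodes <- mrtNodes(tree)
    if (sum(!nodes$isLeaf) == 1) {
      got <- nodes$ss[1] - sum(nodes$ss[nodes$isLeaf])
      expect_equal(got, bruteBestSplitReduction(Y, pred),
                   tolerance = 1e-8)
    }
  }
})

test_that("group-mean PCA matches eigen oracle and flags strong axes", {
  # two groups: a single informative axis carrying all between-group variance
  set.seed(9)
  Y <- rbind(matrix(rnorm(20, 0, 0.05), 10),
             matrix(rnorm(20, 3, 0.05), 10))
  g <- rep(1:2, each = 10)
  p <- pcaGroupMeans(Y, g)
  expect_equal(length(p$explained), 1)
  expect_equal(p$explained, 1)
  expect_true(p$flagged[1])           # separation => correlation > 0.8

  # eigenvalues match a brute-force eigen decomposition on 3 groups
  gm <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0))
  Y3 <- gm[rep(1:3, each = 4), ] + matrix(rnorm(36, 0, 1e-6), 12)
  p3 <- pcaGroupMeans(Y3, rep(1:3, each = 4))
  ev <- eigen(cov(sweep(gm, 2, colMeans(gm))))$values
  ev <- ev[ev > 1e-8]
  expect_equal(p3$explained, ev / sum(ev), tolerance = 1e-3)
  expect_error(pcaGroupMeans(Y, rep(1, 20)), "two groups")

  # uninformative grouping on noise must not flag
  Yn <- matrix(rnorm(40 * 3), 40)
  pn <- pcaGroupMeans(Yn, sample(rep(1:2, 20)))
  expect_true(all(pn$intersectCorrelation < 0.8))
})

test_that("richness regressions report the printed structure and signs", {
  logs <- generateLogs(studyDesign(seed = 10))
  occ <- generateOccurrences(logs, seed = 10)
  km <- kmeansDecayClasses(setNames(logs$remainingMass, logs$log),
                           seed = 10)
  tab <- data.frame(sporocarpRichness = rowSums(occ$fungal),
                    species = logs$species,
                    nPerDensity = logs$nPerDensity,
                    cPerDensity = logs$cPerDensity,
                    decayClass = as.numeric(km$classes),
                    nifhRichness = rowSums(occ$motu > 0),
                    remainingMass = logs$remainingMass)
  rm <- richnessModels(tab)
  expect_equal(rm$anova["Residuals", "Df"], 39)   # 45 - 5 - 1
  expect_equal(nrow(rm$anova), 6)
  expect_true(all(rm$summaryStats[c("R2")] >= 0))

  # exactly linear response: R^2 = 1 on the linear relationship fit
  # (lm warns about the deliberately perfect fit)
  tab2 <- tab
  tab2$sporocarpRichness <- 2 * tab2$nifhRichness + 1
  rm2 <- suppressWarnings(richnessModels(tab2))
  for (f in rm2$relationshipFits)
    expect_equal(f$nifh_R2, 1, tolerance = 1e-8)

  # symmetric hump in remaining mass: negative quadratic coefficient
  tab3 <- tab
  tab3$sporocarpRichness <- 20 - ((tab3$remainingMass - 55) / 10)^2 +
    rnorm(45, 0, 0.01)
  rm3 <- richnessModels(tab3)
  for (f in rm3$relationshipFits)
    expect_lt(f$massQuadCoef, 0)

  tab4 <- tab; tab4$nPerDensity[1] <- 0
  expect_error(richnessModels(tab4), "non-positive")
})

test_that("backward elimination retains only significant predictors", {
  set.seed(12)
  n <- 60
  d <- data.frame(species = sample(c("Fagus", "Picea"), n, TRUE),
                  nPerDensity = rlnorm(n), cPerDensity = rlnorm(n),
                  decayClass = sample(1:4, n, TRUE),
                  nifhRichness = rpois(n, 8),
                  remainingMass = runif(n, 10, 95))
  d$sporocarpRichness <- 3 + 2 * d$nifhRichness + rnorm(n, 0, 1)
  rm <- richnessModels(d)
  expect_true("nifhRichness" %in% rm$backward$terms)
  expect_false("cPerDensity" %in% rm$backward$terms)
})
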