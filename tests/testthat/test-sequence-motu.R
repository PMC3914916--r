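test_that("primer trimming removes matched degenerate sites and flags the rest", {
  core <- "ACGTACGTACGTACGTACGT"
  fwd <- "TGCGACCCGAAGGCGGACTC"                 # one PolF instance
  revSite <- "TCCGGCGAGATGATGGCGAT"             # revcomp of one PolR instance
  r <- Biostrings::DNAStringSet(c(paste0(fwd, core, revSite),
                                  core,
                                  "ACGT"))
  names(r) <- c("ok", "nosites", "short")
  out <- trimPrimers(r)
  expect_equal(out$trimmed, c(TRUE, FALSE, FALSE))
  expect_equal(as.character(out$reads[[1]]), core)
  expect_equal(as.character(out$reads[[2]]), core)   # unchanged
  expect_equal(as.character(out$reads[[3]]), "ACGT")
})

test_that("every random IUPAC instance of both primers is trimmed", {
  set.seed(42)
  pr <- polPrimers()
  for (i in 1:40) {
    fwd <- nifhnet:::sampleIupac(pr$forward)
    rev <- nifhnet:::sampleIupac(pr$reverse)
    read <- Biostrings::DNAStringSet(paste0(
      fwd, randomDna(100), nifhnet:::revcompIupac(rev)))
    # oracle: the instance matches the regex expansion of the IUPAC codes
    expand <- function(p) paste0(vapply(strsplit(p, "")[[1]], function(b)
      paste0("[", paste(nifhnet:::IUPAC[[b]], collapse = ""), "]"), ""),
      collapse = "")
    expect_true(grepl(paste0("^", expand(pr$forward)), fwd))
    expect_true(trimPrimers(read)$trimmed)
  }
})

test_that("pairwise identity follows the shorter-length global convention", {
  expect_equal(pairwiseIdentity("ACGTACGT", "ACGTACGT"), 1)
  expect_equal(pairwiseIdentity("AAAA", "AAAT"), 0.75)
  expect_equal(pairwiseIdentity("AAAA", "AAAAAA"), 1)
  expect_equal(pairwiseIdentity("ACGTTT", "TTTACG"),
               pairwiseIdentity("TTTACG", "ACGTTT"))
  expect_error(pairwiseIdentity("", "ACGT"), "empty")
})

test_that("greedy clustering partitions reads and honours the threshold", {
  r <- Biostrings::DNAStringSet(rep(randomDna(100), 10))
  names(r) <- paste0("r", 1:10)
  m <- clusterGreedy(r)
  expect_equal(unname(motuSizes(m)), 10L)
  expect_false(any(isSingleton(m)))

  set.seed(7)
  a <- randomDna(100)
  b <- mutateSeq(a, 10)      # 90% identity
  r2 <- Biostrings::DNAStringSet(c(a, b)); names(r2) <- c("a", "b")
  m2 <- clusterGreedy(r2, threshold = 0.97)
  expect_equal(length(motuSizes(m2)), 2L)
  expect_true(all(isSingleton(m2)))
})

test_that("clustering partition and threshold monotonicity hold on families", {
  set.seed(11)
  for (rep in 1:5) {
    anc <- replicate(4, randomDna(120))
    sq <- unlist(lapply(anc, function(a)
      replicate(5, mutateSeq(a, sample(0:2, 1)))))
    reads <- Biostrings::DNAStringSet(sq)
    names(reads) <- sprintf("r%02d", seq_along(reads))
    m <- clusterGreedy(reads, threshold = 0.97)
    expect_equal(sum(motuSizes(m)), length(reads))
    expect_false(anyDuplicated(unlist(m@members)) > 0)
    n90 <- length(motuSizes(clusterGreedy(reads, threshold = 0.90)))
    n99 <- length(motuSizes(clusterGreedy(reads, threshold = 0.99)))
    expect_lte(n90, length(motuSizes(m)))
    expect_lte(length(motuSizes(m)), n99)
  }
})

test_that("greedy clusters refine the brute-force identity-graph components", {
  set.seed(13)
  for (rep in 1:4) {
    anc <- replicate(3, randomDna(100))
    sq <- unlist(lapply(anc, function(a)
      replicate(sample(2:5, 1), mutateSeq(a, sample(0:1, 1)))))
    reads <- Biostrings::DNAStringSet(sq)
    names(reads) <- sprintf("r%02d", seq_along(reads))
    thr <- 0.97
    n <- length(sq)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      adj[i, j] <- pairwiseIdentity(sq[i], sq[j]) >= thr
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
    comp <- igraph::components(g)$membership
    names(comp) <- names(reads)
    m <- clusterGreedy(reads, threshold = thr)
    for (mem in m@members)
      expect_length(unique(comp[mem]), 1)   # cluster within one component
  }
})

test_that("reading-frame selection finds the stop-free frame", {
  stopFree <- function(s, f) {
    p <- nifhnet:::translateFrame(s, f)
    !grepl("[*]", substr(p, 1, nchar(p) - 1))
  }
  # search for sequences whose stop-free frame pattern is known exactly
  set.seed(3)
  onlyFrame1 <- NULL; noFrame <- NULL
  while (is.null(onlyFrame1) || is.null(noFrame)) {
    s <- randomDna(27)
    ok <- vapply(0:2, function(f) stopFree(s, f), logical(1))
    if (identical(ok, c(FALSE, TRUE, FALSE))) onlyFrame1 <- s
    if (!any(ok)) noFrame <- s
  }
  expect_equal(selectReadingFrame(onlyFrame1), 1L)
  expect_true(is.na(selectReadingFrame(noFrame)))
  expect_error(selectReadingFrame("AC"), "codon")
})

test_that("generator amplicons are in frame 0 after trimming", {
  logs <- generateLogs(studyDesign(nLogs = 5, seed = 8))
  occ <- generateOccurrences(logs, nFungi = 4, nMotus = 4,
                             richnessRange = c(1, 4), seed = 8)
  reads <- generateAmplicons(occ$motu, seed = 8)
  tr <- trimPrimers(reads)
  frames <- vapply(as.character(tr$reads), selectReadingFrame, integer(1))
  expect_true(all(frames == 0L))
})

test_that("consensus protein takes column majorities with documented ties", {
  expect_equal(consensusProtein(c("MAAC", "MAAC"))$consensus, "MAAC")
  expect_equal(consensusProtein(c("MAVC", "MAVC", "MVVC"))$consensus, "MAVC")
  # tie {A,V} in column 2 resolved to the representative's residue
  expect_equal(consensusProtein(c("MVC", "MAC"),
                                representative = "MAC")$consensus, "MAC")
  expect_error(consensusProtein(c("MAC", "MACC")), "length")
  cp <- consensusProtein(c("MCC"), cysPositions = c(2, 3))
  expect_true(cp$cysteineConserved)
  expect_false(consensusProtein(c("MAC"),
                                cysPositions = c(2, 3))$cysteineConserved)
})

test_that("MOTU consensus pipeline keeps conserved cysteines", {
  logs <- generateLogs(studyDesign(nLogs = 6, seed = 15))
  occ <- generateOccurrences(logs, nFungi = 4, nMotus = 5,
                             richnessRange = c(1, 5), seed = 15)
  reads <- generateAmplicons(occ$motu, seed = 15)
  tr <- trimPrimers(reads)
  m <- clusterGreedy(tr$reads)
  cp <- consensusProteins(m, tr$reads)
  expect_true(all(cp$frame == 0L))
  expect_true(all(cp$cysteineConserved))
  expect_false(any(grepl("[*]", cp$consensus)))
  expect_true(all(nchar(cp$consensus) == 106))
})

test_that("rank-abundance and singleton summaries match fixtures", {
  s <- motuSummaries(makeMotuFixture(c(5, 3, 1)))
  expect_equal(s$rankAbundance$size, c(5, 3, 1))
  expect_equal(s$rankAbundance$rank, 1:3)
  expect_equal(s$singletonFraction, 1 / 3)

  big <- makeMotuFixture(c(rep(2, 106), rep(1, 70)))
  expect_equal(motuSummaries(big)$singletonFraction, 70 / 176)
})

test_that("per-species exclusivity counts split as only/only/shared", {
  sizes <- rep(2, 176)
  sc <- matrix(0L, 176, 2,
               dimnames = list(sprintf("MOTU%03d", 1:176),
                               c("Fagus", "Picea")))
  sc[1:87, 1] <- 2L                       # Fagus only
  sc[88:150, 2] <- 2L                     # Picea only
  sc[151:176, ] <- 1L                     # shared
  s <- motuSummaries(makeMotuFixture(sizes, sc))
  expect_equal(unname(s$exclusivity["only_Fagus"]), 87)
  expect_equal(unname(s$exclusivity["only_Picea"]), 63)
  expect_equal(unname(s$exclusivity["shared"]), 26)
})
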