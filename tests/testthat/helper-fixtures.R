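# Shared fixtures and brute-force oracles, all built in code.

# binary matrix with generated dimnames and kingdom split
makeBinary <- function(rows, kingdom = NULL) {
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("S%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("L%02d", seq_len(ncol(m)))
  if (is.null(kingdom))
    kingdom <- rep(c("nifH", "fungus"), length.out = nrow(m))
  BinaryMatrix(m, kingdom)
}

randomBinary <- function(R, C, fill = 0.4) {
  m <- matrix(rbinom(R * C, 1L, fill), R, C,
              dimnames = list(sprintf("S%02d", seq_len(R)),
                              sprintf("L%02d", seq_len(C))))
  m
}

# brute-force pair statistics by explicit enumeration
brutePairStats <- function(m) {
  R <- nrow(m)
  r <- rowSums(m)
  cu <- c(); never <- 0L
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    S <- sum(m[i, ] == 1 & m[j, ] == 1)
    cu <- c(cu, (r[i] - S) * (r[j] - S))
    if (S == 0) never <- never + 1L
  }
  list(cscore = mean(cu), units = sum(cu), neverPairs = never, cu = cu)
}

# enumerate every binary matrix with the given row/column sums
enumerateMarginMatrices <- function(rs, cs) {
  R <- length(rs); C <- length(cs)
  out <- list()
  rec <- function(rowIdx, mat, colRemain) {
    if (rowIdx > R) {
      if (all(colRemain == 0)) out[[length(out) + 1L]] <<- mat
      return(invisible())
    }
    cols <- which(colRemain > 0)
    if (length(cols) < rs[rowIdx]) return(invisible())
    sets <- if (rs[rowIdx] == 0) list(integer())
            else combn(cols, rs[rowIdx], simplify = FALSE)
    for (cc in sets) {
      cr <- colRemain
      cr[cc] <- cr[cc] - 1L
      if (all(cr <= R - rowIdx)) {
        m2 <- mat; m2[rowIdx, cc] <- 1L
        rec(rowIdx + 1L, m2, cr)
      }
    }
  }
  rec(1L, matrix(0L, R, C), as.integer(cs))
  out
}

matKey <- function(m) paste(as.integer(m), collapse = "")

# family of sequences derived from one ancestor by substitutions only
mutateSeq <- function(s, nmut) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), nmut)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

randomDna <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                      replace = TRUE), collapse = "")

# MotuSet fixture from sizes (and optional per-species read counts)
makeMotuFixture <- function(sizes, speciesCounts = NULL) {
  ids <- sprintf("MOTU%03d", seq_along(sizes))
  members <- lapply(seq_along(sizes), function(k)
    sprintf("r%03d_%03d", k, seq_len(sizes[k])))
  reps <- Biostrings::DNAStringSet(rep("ACGT", length(sizes)))
  names(reps) <- ids
  ab <- matrix(as.integer(sizes), nrow = 1,
               dimnames = list("all", ids))
  sc <- if (is.null(speciesCounts))
    matrix(integer(), nrow = length(ids), ncol = 0,
           dimnames = list(ids, NULL))
  else speciesCounts
  new("MotuSet", ids = ids, members = members, representatives = reps,
      abundance = ab, speciesCounts = sc)
}

# exhaustive 1-D k-means oracle: minimum within-SS over contiguous ordered
# partitions into k non-empty blocks
bruteKmeans1d <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  best <- Inf
  cuts <- combn(n - 1, k - 1, simplify = FALSE)
  for (cc in cuts) {
    bounds <- c(0, cc, n)
    ss <- 0
    for (b in seq_len(k)) {
      blk <- xs[(bounds[b] + 1):bounds[b + 1]]
      ss <- ss + sum((blk - mean(blk))^2)
    }
    best <- min(best, ss)
  }
  best
}

# exhaustive best first split for a multivariate response
bruteBestSplitReduction <- function(Y, predictors) {
  ssq <- function(M) if (nrow(M) == 0) 0 else
    sum(sweep(M, 2, colMeans(M))^2)
  parent <- ssq(Y)
  best <- -Inf
  for (v in colnames(predictors)) {
    x <- predictors[[v]]
    if (is.numeric(x) || is.ordered(x)) {
      xv <- if (is.ordered(x)) as.integer(x) else x
      for (thr in sort(unique(xv))[-length(unique(xv))]) {
        l <- xv <= thr
        red <- parent - ssq(Y[l, , drop = FALSE]) -
          ssq(Y[!l, , drop = FALSE])
        best <- max(best, red)
      }
    } else {
      lev <- sort(unique(as.character(x)))
      for (sz in seq_len(length(lev) - 1)) {
        for (cc in combn(lev, sz, simplify = FALSE)) {
          l <- as.character(x) %in% cc
          if (!any(l) || all(l)) next
          red <- parent - ssq(Y[l, , drop = FALSE]) -
            ssq(Y[!l, , drop = FALSE])
          best <- max(best, red)
        }
      }
    }
  }
  best
}
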