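#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i) between the abundance rows of a
#' community matrix (logs x taxa). Rows with zero total abundance have no
#' defined dissimilarity and are rejected by name.
#'
#' @param mat non-negative abundance matrix, rows = samples.
#' @return a \code{dist} object with values in [0, 1].
#' @examples
#' brayCurtis(rbind(a = c(2, 0), b = c(1, 1)))  # 0.5
#' @export
brayCurtis <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("abundances must be non-negative")
  zero <- rowSums(mat) == 0
  if (any(zero))
    stop("all-zero row(s): ",
         paste(rownames(mat)[zero], collapse = ", "))
  vegan::vegdist(mat, method = "bray")
}

#' Assign decay classes by 1-D k-means on remaining mass
#'
#' Standard k-means with multiple random restarts on the remaining-mass
#' values; the resulting clusters are relabelled 1..k by descending center,
#' so class 1 is the least decayed. In one dimension the classes are
#' contiguous intervals of remaining mass.
#'
#' @param remainingMass numeric vector (percent), optionally named by log.
#' @param k number of decay classes (default 4).
#' @param seed integer seed (restarts are stochastic).
#' @param nstart random restarts (default 50).
#' @return list with \code{classes} (integer vector, ordered labels) and
#'   \code{centers} (descending remaining-mass centers).
#' @export
kmeansDecayClasses <- function(remainingMass, k = 4L, seed = 1L,
                               nstart = 50L) {
  x <- as.numeric(remainingMass)
  if (length(unique(x)) < k)
    stop("fewer than k distinct remaining-mass values")
  km <- withSeed(seed, kmeans(x, centers = k, nstart = nstart))
  ord <- order(km$centers, decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  classes <- relabel[km$cluster]
  names(classes) <- names(remainingMass)
  list(classes = classes, centers = as.numeric(km$centers)[ord],
       withinss = sum(km$withinss))
}

# detect aliased (rank-deficient) columns of a model matrix
checkFullRank <- function(formula, data) {
  mm <- stats::model.matrix(formula, data = data)
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    aliased <- colnames(mm)[q$pivot[(q$rank + 1L):ncol(mm)]]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  invisible(TRUE)
}

#' Distance-based permutational MANOVA
#'
#' Partitions a dissimilarity matrix by sequential (order-of-entry) term
#' sums of squares via the Gower-centered inner-product matrix, with
#' pseudo-F per term against the residual mean square and p-values from
#' free permutation of the rows: p = (permuted F >= observed + 1) /
#' (permutations + 1), so the smallest attainable p at 999 permutations is
#' 0.001. Computation is delegated to \code{vegan::adonis2(by = "terms")};
#' the wrapper adds mean squares, checks Df/SS bookkeeping and rejects
#' rank-deficient designs with the aliased terms named.
#'
#' @param d a \code{dist} (e.g. from \code{\link{brayCurtis}}).
#' @param formula right-hand-side model formula, e.g.
#'   \code{~ species * decayClass * management}. Enter decay class as a
#'   numeric covariate for a single-df row.
#' @param data data.frame of row metadata, complete for every sample.
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return data.frame with rows per term plus Residual and Total and columns
#'   \code{Df}, \code{SS}, \code{MS}, \code{pseudoF}, \code{R2}, \code{p}.
#' @export
permanova <- function(d, formula, data, nPerm = 999L, seed = 1L) {
  if (!inherits(d, "dist")) d <- as.dist(d)
  n <- attr(d, "Size")
  if (nrow(data) != n) stop("metadata rows must match distance entries")
  if (anyNA(data)) stop("factors must be complete for every sample")
  checkFullRank(formula, data)
  .d <- d   # adonis2 resolves the response in the calling frame
  f <- stats::as.formula(paste(".d ~", as.character(formula)[2]),
                         env = environment())
  tab <- withSeed(seed,
    vegan::adonis2(f, data = data, permutations = nPerm, by = "terms"))
  out <- data.frame(term = rownames(tab), Df = tab$Df, SS = tab$SumOfSqs,
                    MS = tab$SumOfSqs / tab$Df, pseudoF = tab$F,
                    R2 = tab$R2, p = tab[["Pr(>F)"]],
                    row.names = NULL)
  out$term[out$term == "Residual"] <- "Residuals"
  res <- out$term == "Residuals"; tot <- out$term == "Total"
  stopifnot(sum(out$Df[!tot]) == out$Df[tot],
            out$Df[tot] == n - 1L,
            abs(sum(out$SS[!tot]) - out$SS[tot]) < 1e-8 * out$SS[tot])
  out$MS[tot] <- NA_real_
  out
}

nodeSS <- function(Y) {
  if (nrow(Y) == 0L) return(0)
  sum(sweep(Y, 2, colMeans(Y))^2)
}

# enumerate candidate binary splits of one predictor on given samples:
# numeric/ordered -> thresholds; factor -> all binary level partitions
splitCandidates <- function(x) {
  if (is.numeric(x) || is.ordered(x)) {
    xv <- if (is.ordered(x)) as.integer(x) else x
    u <- sort(unique(xv))
    if (length(u) < 2L) return(list())
    lapply(u[-length(u)], function(thr)
      list(rule = paste0("<= ", signif(thr, 6)), left = xv <= thr))
  } else {
    lev <- unique(as.character(x))
    if (length(lev) < 2L) return(list())
    out <- list()
    for (sz in seq_len(floor(length(lev) / 2))) {
      combs <- combn(sort(lev), sz, simplify = FALSE)
      for (cc in combs) {
        if (sz == length(lev) / 2 && !(sort(lev)[1] %in% cc)) next
        out[[length(out) + 1L]] <-
          list(rule = paste0("in {", paste(cc, collapse = ","), "}"),
               left = as.character(x) %in% cc)
      }
    }
    out
  }
}

bestSplit <- function(Y, predictors, idx) {
  parent <- nodeSS(Y[idx, , drop = FALSE])
  best <- NULL
  for (v in colnames(predictors)) {
    for (cand in splitCandidates(predictors[idx, v])) {
      l <- idx[cand$left]; r <- idx[!cand$left]
      if (!length(l) || !length(r)) next
      red <- parent - nodeSS(Y[l, , drop = FALSE]) -
        nodeSS(Y[r, , drop = FALSE])
      if (is.null(best) || red > best$reduction + 1e-12)
        best <- list(var = v, rule = cand$rule, left = l, right = r,
                     reduction = red)
    }
  }
  best
}

#' Multivariate regression tree on Euclidean distances
#'
#' Greedy binary recursive partitioning of a multivariate abundance response:
#' each split maximizes the reduction in within-node sum of squared
#' Euclidean distances to the node mean. Splitting stops when a node is
#' smaller than \code{minSplit}, at \code{maxDepth}, or when the best
#' split's reduction falls below \code{minImprove} of the root SS. No
#' cross-validated pruning is applied.
#'
#' @param mat samples x taxa abundance matrix.
#' @param predictors data.frame of categorical or ordinal predictors (same
#'   rows as \code{mat}).
#' @param minSplit smallest node that may be split (default 5).
#' @param maxDepth maximum tree depth, root = 0 (default 4).
#' @param minImprove minimum relative SS improvement (default 0.01).
#' @return an \linkS4class{MrtTree}; a single sample gives a lone leaf.
#' @export
mrt <- function(mat, predictors, minSplit = 5L, maxDepth = 4L,
                minImprove = 0.01) {
  Y <- as.matrix(mat)
  if (nrow(Y) < 1L) stop("at least one sample required")
  stopifnot(nrow(predictors) == nrow(Y))
  rootSS <- nodeSS(Y)
  nodes <- data.frame(id = 1L, parent = NA_integer_, depth = 0L,
                      n = nrow(Y), ss = rootSS, var = NA_character_,
                      rule = NA_character_, isLeaf = TRUE,
                      group = NA_integer_)
  assign <- rep(1L, nrow(Y))
  queue <- list(list(id = 1L, idx = seq_len(nrow(Y)), depth = 0L))
  while (length(queue)) {
    nd <- queue[[1]]; queue <- queue[-1]
    if (length(nd$idx) < minSplit || nd$depth >= maxDepth) next
    bs <- bestSplit(Y, predictors, nd$idx)
    if (is.null(bs)) next
    if (rootSS > 0 && bs$reduction / rootSS < minImprove) next
    idL <- nrow(nodes) + 1L; idR <- nrow(nodes) + 2L
    nodes$isLeaf[nodes$id == nd$id] <- FALSE
    nodes$var[nodes$id == nd$id] <- bs$var
    nodes$rule[nodes$id == nd$id] <- bs$rule
    nodes <- rbind(nodes,
      data.frame(id = c(idL, idR), parent = nd$id, depth = nd$depth + 1L,
                 n = c(length(bs$left), length(bs$right)),
                 ss = c(nodeSS(Y[bs$left, , drop = FALSE]),
                        nodeSS(Y[bs$right, , drop = FALSE])),
                 var = NA_character_, rule = NA_character_, isLeaf = TRUE,
                 group = NA_integer_))
    assign[bs$left] <- idL; assign[bs$right] <- idR
    queue <- c(queue,
               list(list(id = idL, idx = bs$left, depth = nd$depth + 1L),
                    list(id = idR, idx = bs$right, depth = nd$depth + 1L)))
  }
  leaves <- nodes$id[nodes$isLeaf]
  nodes$group[nodes$isLeaf] <- seq_along(leaves)
  groups <- nodes$group[match(assign, nodes$id)]
  names(groups) <- rownames(mat)
  new("MrtTree", nodes = nodes, leafAssign = as.integer(groups) |>
        setNames(rownames(mat)), rootSS = rootSS)
}

#' PCA of multivariate group means
#'
#' Eigendecomposition of the covariance of the leaf-group mean vectors of a
#' regression tree (or any grouping); samples are projected onto the same
#' axes. The intersect correlation of an axis is the correlation between the
#' sample scores and the scores of their group means; axes exceeding
#' \code{corFlag} potentially account for significant between-group
#' variation and are flagged.
#'
#' @param mat samples x taxa abundance matrix.
#' @param groups factor/integer grouping with >= 2 groups.
#' @param corFlag intersect-correlation flag threshold (default 0.8).
#' @return list with \code{groupScores}, \code{sampleScores},
#'   \code{explained} (variance fractions, summing to 1 over retained
#'   axes), \code{intersectCorrelation}, \code{flagged}.
#' @export
pcaGroupMeans <- function(mat, groups, corFlag = 0.8) {
  Y <- as.matrix(mat)
  g <- as.factor(groups)
  if (nlevels(g) < 2L) stop("at least two groups required")
  gm <- apply(Y, 2, function(col) tapply(col, g, mean))
  center <- colMeans(gm)
  gmc <- sweep(gm, 2, center)
  eg <- eigen(cov(gmc), symmetric = TRUE)
  keep <- which(eg$values > max(eg$values) * 1e-10)
  vec <- eg$vectors[, keep, drop = FALSE]
  gs <- gmc %*% vec
  ss <- sweep(Y, 2, center) %*% vec
  colnames(gs) <- colnames(ss) <- paste0("PC", seq_along(keep))
  expl <- eg$values[keep] / sum(eg$values[keep])
  ic <- vapply(seq_along(keep), function(a)
    suppressWarnings(cor(ss[, a], gs[as.integer(g), a])), numeric(1))
  list(groupScores = gs, sampleScores = ss, explained = expl,
       intersectCorrelation = ic, flagged = !is.na(ic) & ic > corFlag)
}

#' Sporocarp-richness regressions
#'
#' Ordinary least squares of fungal sporocarp richness on tree species,
#' log N and log C per density unit, decay class (numeric) and nifH MOTU
#' richness: the full-model sequential ANOVA is reported alongside a
#' backward-eliminated model (drop the largest-p term until every retained
#' term's p is below \code{alpha}). Degree-2 polynomial and linear fits for
#' the richness relationships (vs remaining mass, log N, nifH richness) are
#' returned per tree species.
#'
#' @param table data.frame with columns \code{sporocarpRichness},
#'   \code{species}, \code{nPerDensity}, \code{cPerDensity},
#'   \code{decayClass}, \code{nifhRichness}, \code{remainingMass}.
#' @param alpha retention threshold for backward elimination (default 0.05).
#' @return list with \code{anova} (full-model table, Table-2 structure),
#'   \code{fullModel} (\code{lm}), \code{summaryStats} (R2, F, p),
#'   \code{backward} (retained term names and final \code{lm}),
#'   \code{relationshipFits} (per-species R2 and coefficients).
#' @export
richnessModels <- function(table, alpha = 0.05) {
  req <- c("sporocarpRichness", "species", "nPerDensity", "cPerDensity",
           "decayClass", "nifhRichness", "remainingMass")
  miss <- setdiff(req, colnames(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(table[req])) stop("complete cases required")
  if (any(table$nPerDensity <= 0) || any(table$cPerDensity <= 0))
    stop("non-positive values under log transform")
  d <- data.frame(richness = table$sporocarpRichness,
                  species = factor(table$species),
                  logN = log(table$nPerDensity),
                  logC = log(table$cPerDensity),
                  decayClass = as.numeric(table$decayClass),
                  nifhRichness = table$nifhRichness,
                  remainingMass = table$remainingMass)
  full <- lm(richness ~ species + logN + logC + decayClass + nifhRichness,
             data = d)
  atab <- anova(full)
  sm <- summary(full)
  stats <- c(R2 = unname(sm$r.squared),
             F = unname(sm$fstatistic[1]),
             p = unname(pf(sm$fstatistic[1], sm$fstatistic[2],
                           sm$fstatistic[3], lower.tail = FALSE)))
  # backward elimination on marginal (drop1) F-test p-values
  terms <- c("species", "logN", "logC", "decayClass", "nifhRichness")
  repeat {
    f <- stats::as.formula(paste("richness ~",
                                 if (length(terms)) paste(terms, collapse = " + ")
                                 else "1"))
    fit <- lm(f, data = d)
    if (!length(terms)) break
    dr <- stats::drop1(fit, test = "F")
    pv <- dr[["Pr(>F)"]][-1]
    names(pv) <- rownames(dr)[-1]
    if (all(pv < alpha, na.rm = TRUE)) break
    terms <- setdiff(terms, names(pv)[which.max(pv)])
  }
  fits <- lapply(split(d, d$species), function(dd) {
    polyMass <- lm(richness ~ remainingMass + I(remainingMass^2), data = dd)
    linN <- lm(richness ~ logN, data = dd)
    linNifh <- lm(richness ~ nifhRichness, data = dd)
    list(massPolyR2 = summary(polyMass)$r.squared,
         massQuadCoef = unname(coef(polyMass)[3]),
         logN_R2 = summary(linN)$r.squared,
         logN_slope = unname(coef(linN)[2]),
         nifh_R2 = summary(linNifh)$r.squared,
         nifh_slope = unname(coef(linNifh)[2]))
  })
  list(anova = atab, fullModel = full, summaryStats = stats,
       backward = list(terms = terms, model = fit),
       relationshipFits = fits)
}
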