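#' @useDynLib nifhnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Stack abundance tables into a binary species-by-sites matrix
#'
#' Fungal and nifH abundance tables over the same logs are binarized
#' (abundance > 0), transposed to species x sites and stacked. For pairwise
#' analyses, species present in fewer than \code{minOccurrence} sites are
#' dropped; the matrix-level analysis keeps all species by default.
#'
#' @param fungal logs x fungal-species table (abundance or 0/1).
#' @param motu logs x nifH-MOTU table.
#' @param minOccurrence minimum sites a species must occupy to be retained
#'   (default 3).
#' @param applyTo \code{"pairwise"} applies the occurrence filter,
#'   \code{"matrix"} keeps every species.
#' @return a \linkS4class{BinaryMatrix}.
#' @export
binarizeAndFilter <- function(fungal, motu, minOccurrence = 3L,
                              applyTo = c("pairwise", "matrix")) {
  applyTo <- match.arg(applyTo)
  fungal <- as.matrix(fungal); motu <- as.matrix(motu)
  sitesF <- rownames(fungal); sitesM <- rownames(motu)
  if (!length(intersect(sitesF, sitesM)))
    stop("fungal and nifH tables have disjoint site sets")
  if (!setequal(sitesF, sitesM))
    stop("site sets differ: ",
         paste(c(setdiff(sitesF, sitesM), setdiff(sitesM, sitesF)),
               collapse = ", "))
  motu <- motu[sitesF, , drop = FALSE]
  m <- rbind(t(fungal > 0) + 0L, t(motu > 0) + 0L)
  king <- c(rep("fungus", ncol(fungal)), rep("nifH", ncol(motu)))
  if (applyTo == "pairwise") {
    keep <- rowSums(m) >= minOccurrence
    m <- m[keep, , drop = FALSE]
    king <- king[keep]
  }
  BinaryMatrix(m, king)
}

pairIndex <- function(mat) {
  R <- nrow(mat)
  if (R < 2L) stop("at least two species required")
  rn <- rownames(mat)
  if (is.null(rn)) rn <- sprintf("S%02d", seq_len(R))
  ij <- which(upper.tri(diag(R)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  data.frame(i = ij[, 1], j = ij[, 2], a = rn[ij[, 1]], b = rn[ij[, 2]])
}

# checkerboard units CU_ij = (r_i - S)(r_j - S) for all pairs, in the
# (i, j) i<j row-major order used by pairIndex() and the C++ chain
pairCU <- function(mat) {
  r <- rowSums(mat)
  S <- mat %*% t(mat)
  A <- (r - S) * t(r - S)
  pr <- pairIndex(mat)
  unname(A[cbind(pr$i, pr$j)])
}

#' C-score of a binary matrix
#'
#' Mean checkerboard units CU_ij = (r_i - S_ij)(r_j - S_ij) over all
#' R(R-1)/2 species pairs; larger values indicate segregation (a tendency of
#' species not to co-occur).
#'
#' @param x a \linkS4class{BinaryMatrix} or 0/1 matrix (rows = species).
#' @return the mean checkerboard-unit count.
#' @export
cscore <- function(x) {
  m <- if (is(x, "BinaryMatrix")) binaryMatrix(x) else as.matrix(x)
  if (nrow(m) < 2L) stop("at least two species required")
  mean(pairCU(m))
}

#' Checkerboard statistics of a binary matrix
#'
#' Two complementary quantities: the number of species pairs that never
#' co-occur (the default "checkerboard index") and the total checkerboard
#' units over all pairs (the classical segregation count).
#'
#' @param x a \linkS4class{BinaryMatrix} or 0/1 matrix (rows = species).
#' @return list with \code{neverCooccurPairs} and \code{checkerboardUnits}.
#' @export
checkerboardStats <- function(x) {
  m <- if (is(x, "BinaryMatrix")) binaryMatrix(x) else as.matrix(x)
  if (nrow(m) < 2L) stop("at least two species required")
  S <- m %*% t(m)
  list(neverCooccurPairs = sum(S[upper.tri(S)] == 0),
       checkerboardUnits = sum(pairCU(m)))
}

#' Fixed-fixed sequential swap randomization
#'
#' Repeats \code{nSwaps} times: sample a random 2x2 submatrix uniformly;
#' if it is a checkerboard ([[1,0],[0,1]] or [[0,1],[1,0]]), flip it.
#' Attempts on non-checkerboard submatrices are no-ops, so row and column
#' margins are preserved exactly. Randomness comes from R's RNG
#' (\code{set.seed} upstream, or pass \code{seed}).
#'
#' @param x a \linkS4class{BinaryMatrix} or 0/1 matrix.
#' @param nSwaps number of swap attempts.
#' @param seed optional integer seed.
#' @return randomized matrix of the same class as the input.
#' @export
swapRandomize <- function(x, nSwaps, seed = NULL) {
  m <- if (is(x, "BinaryMatrix")) binaryMatrix(x) else as.matrix(x)
  storage.mode(m) <- "integer"
  out <- withSeed(seed, cpp_swap(m, as.integer(nSwaps)))
  dimnames(out) <- dimnames(m)
  if (is(x, "BinaryMatrix")) BinaryMatrix(out, x@kingdom) else out
}

#' Null ensemble of margin-preserving randomized matrices
#'
#' Runs the sequential-swap chain for \code{burnIn} attempts (default 10x
#' the number of presences), then records one matrix every \code{spacing}
#' attempts (default 5x the presences) until \code{N} matrices are stored,
#' along with per-matrix C-score and checkerboard statistics and per-pair
#' checkerboard-unit samples. A matrix with zero checkerboard submatrices
#' cannot move, and a warning marks the degenerate null distribution.
#'
#' @param x a \linkS4class{BinaryMatrix}.
#' @param N ensemble size (default 100).
#' @param burnIn,spacing swap-attempt counts (defaults above).
#' @param seed integer seed.
#' @return a \linkS4class{NullEnsemble}.
#' @export
nullEnsemble <- function(x, N = 100L, burnIn = NULL, spacing = NULL,
                         seed = 1L) {
  stopifnot(is(x, "BinaryMatrix"), N >= 1L)
  m <- binaryMatrix(x)
  ones <- sum(m)
  if (is.null(burnIn)) burnIn <- 10 * ones
  if (is.null(spacing)) spacing <- 5 * ones
  if (checkerboardStats(x)$checkerboardUnits == 0)
    warning("matrix has no checkerboard submatrix: the null distribution ",
            "is degenerate (all randomized matrices equal the observed)")
  res <- withSeed(seed,
    cpp_null_ensemble(m, as.integer(N), burnIn, spacing))
  arr <- array(res$matrices, dim = c(nrow(m), ncol(m), N))
  new("NullEnsemble", observed = x, matrices = arr,
      pairCU = res$pairCU, pairs = pairIndex(m),
      cscores = as.numeric(res$cscores),
      checkerPairs = as.numeric(res$checkerPairs),
      checkerUnits = as.numeric(res$checkerUnits),
      burnIn = burnIn, spacing = spacing,
      acceptanceRate = res$acceptanceRate)
}

#' Matrix-level permutation test against a null ensemble
#'
#' Empirical tail probability with the add-one convention, so p can never be
#' 0: p = (#(null >= observed) + 1) / (N + 1) for \code{tail = "greater"}
#' (with <= for \code{"lesser"}).
#'
#' @param observed observed statistic.
#' @param nullValues numeric vector of the statistic over the ensemble.
#' @param tail \code{"greater"} (default) or \code{"lesser"}.
#' @return the p-value.
#' @export
matrixTest <- function(observed, nullValues, tail = c("greater", "lesser")) {
  tail <- match.arg(tail)
  if (!length(nullValues)) stop("ensemble is empty")
  hits <- if (tail == "greater") sum(nullValues >= observed)
          else sum(nullValues <= observed)
  (hits + 1) / (length(nullValues) + 1)
}

#' Pairwise Z-scores against the null ensemble
#'
#' For every species pair, Z = (CU_obs - mean(CU_null)) / sd(CU_null).
#' Z < -1.96 marks significant co-occurrence (aggregation), Z > 1.96
#' avoidance. A degenerate null (sd = 0) gives Z = 0 and classification
#' "none" when the observed value equals the null mean, and is otherwise
#' flagged indeterminate. A two-sided empirical tail probability
#' (add-one convention) accompanies each pair for edge-width mapping.
#'
#' @param ensemble a \linkS4class{NullEnsemble}.
#' @param zThreshold significance threshold on |Z| (default 1.96, the 5%
#'   normal quantile).
#' @return data.frame with one row per pair: taxon ids, kingdoms, shared
#'   sites, observed CU, null mean/sd, \code{z}, \code{p} (two-sided
#'   empirical), \code{classification} in {co-occurrence, avoidance, none,
#'   indeterminate}.
#' @export
pairwiseZ <- function(ensemble, zThreshold = 1.96) {
  stopifnot(is(ensemble, "NullEnsemble"))
  obs <- ensemble@observed
  m <- binaryMatrix(obs)
  cuObs <- pairCU(m)
  pr <- ensemble@pairs
  mu <- rowMeans(ensemble@pairCU)
  sdv <- apply(ensemble@pairCU, 1, sd)
  N <- nullCount(ensemble)
  z <- ifelse(sdv > 0, (cuObs - mu) / sdv, ifelse(cuObs == mu, 0, NA_real_))
  cls <- ifelse(is.na(z), "indeterminate",
         ifelse(z < -zThreshold, "co-occurrence",
         ifelse(z > zThreshold, "avoidance", "none")))
  ge <- rowSums(ensemble@pairCU >= cuObs)
  le <- rowSums(ensemble@pairCU <= cuObs)
  p2 <- pmin(1, 2 * (pmin(ge, le) + 1) / (N + 1))
  king <- kingdom(obs)
  S <- m %*% t(m)
  data.frame(a = pr$a, b = pr$b,
             kingdomA = unname(king[pr$a]), kingdomB = unname(king[pr$b]),
             shared = S[cbind(pr$i, pr$j)], cu = cuObs,
             nullMean = mu, nullSd = sdv, z = z, p = p2,
             classification = cls, stringsAsFactors = FALSE)
}
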