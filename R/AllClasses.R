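#' @import methods
#' @importFrom stats anova aov as.dist chisq.test coef cor cov cutree dist
#'   kmeans lm pf rbinom rlnorm rnorm rpois runif sd setNames var
#' @importFrom utils combn read.delim write.table head
NULL

#' Species-by-site presence/absence matrix
#'
#' Container for a binary (0/1) species x sites matrix, the substrate of all
#' null-model statistics. Rows are taxa (fungal species or nifH MOTUs),
#' columns are dead-wood logs. Each row carries a kingdom label so that
#' cross-kingdom edges can be distinguished downstream.
#'
#' @slot mat integer matrix with values in {0, 1}; rownames are taxon ids,
#'   colnames are site (log) ids.
#' @slot kingdom character vector, one of \code{"fungus"} or \code{"nifH"}
#'   per row of \code{mat}.
#' @export
setClass("BinaryMatrix",
  representation(mat = "matrix", kingdom = "character"))

setValidity("BinaryMatrix", function(object) {
  m <- object@mat
  msg <- character()
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "matrix must have row and column names")
  if (!all(m %in% c(0L, 1L)))
    msg <- c(msg, "cells must be 0 or 1")
  if (anyDuplicated(rownames(m)))
    msg <- c(msg, "duplicate taxon ids")
  if (length(object@kingdom) != nrow(m))
    msg <- c(msg, "kingdom must have one entry per row")
  if (!all(object@kingdom %in% c("fungus", "nifH")))
    msg <- c(msg, "kingdom labels must be 'fungus' or 'nifH'")
  if (length(msg)) msg else TRUE
})

#' Construct a BinaryMatrix
#'
#' @param mat numeric/integer matrix of 0/1 cells with dimnames.
#' @param kingdom per-row kingdom labels (\code{"fungus"} or \code{"nifH"}).
#' @return a \linkS4class{BinaryMatrix}.
#' @export
BinaryMatrix <- function(mat, kingdom) {
  storage.mode(mat) <- "integer"
  new("BinaryMatrix", mat = mat, kingdom = as.character(kingdom))
}

#' @describeIn BinaryMatrix underlying integer matrix
#' @param x a BinaryMatrix
#' @export
binaryMatrix <- function(x) x@mat

#' @describeIn BinaryMatrix per-row kingdom labels
#' @export
kingdom <- function(x) setNames(x@kingdom, rownames(x@mat))

#' @describeIn BinaryMatrix row (species) occupancy margins
#' @export
rowMargins <- function(x) rowSums(x@mat)

#' @describeIn BinaryMatrix column (site) richness margins
#' @export
colMargins <- function(x) colSums(x@mat)

setMethod("show", "BinaryMatrix", function(object) {
  cat("BinaryMatrix:", nrow(object@mat), "taxa x", ncol(object@mat), "sites\n")
  tab <- table(factor(object@kingdom, levels = c("fungus", "nifH")))
  cat("  fungi:", tab[["fungus"]], " nifH MOTUs:", tab[["nifH"]],
      " fill:", round(mean(object@mat), 3), "\n")
})

#' Null-model ensemble of margin-preserving randomized matrices
#'
#' Holds the output of the fixed-fixed sequential-swap sampler: N randomized
#' matrices sharing the observed row and column margins, together with
#' per-matrix C-score and checkerboard statistics and per-species-pair
#' checkerboard-unit samples.
#'
#' @slot observed the observed \linkS4class{BinaryMatrix}.
#' @slot matrices integer array (rows x cols x N) of randomized matrices.
#' @slot pairCU numeric matrix (pairs x N) of checkerboard units per pair.
#' @slot pairs data.frame with columns \code{i}, \code{j} (row indices) and
#'   \code{a}, \code{b} (taxon ids) indexing \code{pairCU}.
#' @slot cscores,checkerPairs,checkerUnits per-matrix statistics (length N).
#' @slot burnIn,spacing swap-attempt counts used by the chain.
#' @slot acceptanceRate fraction of swap attempts that flipped a checkerboard.
#' @export
setClass("NullEnsemble",
  representation(observed = "BinaryMatrix", matrices = "array",
                 pairCU = "matrix", pairs = "data.frame",
                 cscores = "numeric", checkerPairs = "numeric",
                 checkerUnits = "numeric",
                 burnIn = "numeric", spacing = "numeric",
                 acceptanceRate = "numeric"))

setValidity("NullEnsemble", function(object) {
  msg <- character()
  N <- length(object@cscores)
  if (dim(object@matrices)[3] != N)
    msg <- c(msg, "matrix count must equal length of statistic vectors")
  if (ncol(object@pairCU) != N)
    msg <- c(msg, "pairCU must have one column per null matrix")
  if (nrow(object@pairCU) != nrow(object@pairs))
    msg <- c(msg, "pairCU rows must match pair index table")
  if (length(msg)) msg else TRUE
})

#' @describeIn NullEnsemble number of null matrices
#' @param x a NullEnsemble
#' @export
nullCount <- function(x) length(x@cscores)

#' @describeIn NullEnsemble the i-th randomized matrix
#' @param i matrix index
#' @export
nullMatrix <- function(x, i) {
  m <- x@matrices[, , i, drop = TRUE]
  dimnames(m) <- dimnames(x@observed@mat)
  m
}

#' @describeIn NullEnsemble per-matrix C-scores
#' @export
nullCscores <- function(x) x@cscores

setMethod("show", "NullEnsemble", function(object) {
  cat("NullEnsemble:", nullCount(object), "randomized matrices of",
      nrow(object@observed@mat), "x", ncol(object@observed@mat), "\n")
  cat("  burn-in:", object@burnIn, " spacing:", object@spacing,
      " swap acceptance:", round(object@acceptanceRate, 3), "\n")
  cat("  null C-score mean:", round(mean(object@cscores), 4), "\n")
})

#' Set of molecular operational taxonomic units (MOTUs)
#'
#' Result of greedy identity clustering of primer-trimmed amplicons:
#' cluster membership, representative sequences, per-log abundances and
#' per-tree-species read counts.
#'
#' @slot ids MOTU identifiers, in founding order.
#' @slot members list of member read ids per MOTU.
#' @slot representatives \code{DNAStringSet} of representative (founder)
#'   sequences, one per MOTU.
#' @slot abundance integer matrix logs x MOTUs of read counts.
#' @slot speciesCounts integer matrix MOTUs x tree species of read counts.
#' @export
setClass("MotuSet",
  representation(ids = "character", members = "list",
                 representatives = "ANY", abundance = "matrix",
                 speciesCounts = "matrix"))

setValidity("MotuSet", function(object) {
  msg <- character()
  sizes <- lengths(object@members)
  if (length(object@ids) != length(object@members))
    msg <- c(msg, "one member vector per MOTU id required")
  if (ncol(object@abundance) != length(object@ids))
    msg <- c(msg, "abundance must have one column per MOTU")
  if (!isTRUE(all(colSums(object@abundance) == sizes)))
    msg <- c(msg, "abundances must sum to MOTU sizes")
  if (length(msg)) msg else TRUE
})

#' @describeIn MotuSet MOTU sizes (member counts)
#' @param x a MotuSet
#' @export
motuSizes <- function(x) setNames(lengths(x@members), x@ids)

#' @describeIn MotuSet logical singleton flags (size == 1)
#' @export
isSingleton <- function(x) motuSizes(x) == 1L

#' @describeIn MotuSet logs x MOTUs abundance matrix
#' @export
motuAbundance <- function(x) x@abundance

#' @describeIn MotuSet representative sequences
#' @export
motuRepresentatives <- function(x) x@representatives

setMethod("show", "MotuSet", function(object) {
  sz <- motuSizes(object)
  cat("MotuSet:", length(sz), "MOTUs from", sum(sz), "reads;",
      sum(sz == 1L), "singletons\n")
})

#' Multivariate regression tree
#'
#' Binary tree from greedy splitting of a multivariate abundance response on
#' categorical/ordinal predictors, minimizing within-node sums of squared
#' Euclidean distances to node means.
#'
#' @slot nodes data.frame with one row per node: \code{id}, \code{parent},
#'   \code{depth}, \code{n}, \code{ss}, \code{var}, \code{rule},
#'   \code{isLeaf}, \code{group} (leaf group id, NA for internal nodes).
#' @slot leafAssign named integer vector mapping each sample to its leaf group.
#' @slot rootSS total sum of squares at the root.
#' @export
setClass("MrtTree",
  representation(nodes = "data.frame", leafAssign = "integer",
                 rootSS = "numeric"))

#' @describeIn MrtTree node table
#' @param x an MrtTree
#' @export
mrtNodes <- function(x) x@nodes

#' @describeIn MrtTree leaf-group assignment of the samples
#' @export
mrtGroups <- function(x) x@leafAssign

setMethod("show", "MrtTree", function(object) {
  nl <- sum(object@nodes$isLeaf)
  cat("MrtTree:", nrow(object@nodes), "nodes,", nl, "leaves; root SS =",
      signif(object@rootSS, 5), "\n")
  sp <- object@nodes[!object@nodes$isLeaf, , drop = FALSE]
  if (nrow(sp))
    cat("  splits:", paste(sp$var, sp$rule, sep = " ", collapse = "; "), "\n")
})

#' Signed fungus-diazotroph association network
#'
#' Nodes are taxa retained in significant pairwise co-occurrence tests; edges
#' are significant pairs with at least one nifH endpoint, signed as
#' co-occurrence (Z < -1.96) or avoidance (Z > 1.96).
#'
#' @slot nodes data.frame: \code{id}, \code{kingdom}, \code{affiliation},
#'   \code{degree}.
#' @slot edges data.frame: \code{from}, \code{to}, \code{sign}, \code{z},
#'   \code{p}, \code{width}.
#' @export
setClass("AssociationNetwork",
  representation(nodes = "data.frame", edges = "data.frame"))

setValidity("AssociationNetwork", function(object) {
  msg <- character()
  e <- object@edges; n <- object@nodes
  if (nrow(e)) {
    if (!all(c(e$from, e$to) %in% n$id))
      msg <- c(msg, "edge endpoints must be listed as nodes")
    king <- setNames(n$kingdom, n$id)
    if (!all(king[e$from] == "nifH" | king[e$to] == "nifH"))
      msg <- c(msg, "every edge must have at least one nifH endpoint")
    if (!all(e$sign %in% c("co-occurrence", "avoidance")))
      msg <- c(msg, "edge sign must be co-occurrence or avoidance")
    deg <- table(factor(c(e$from, e$to), levels = n$id))
    if (!all(n$degree == as.integer(deg)))
      msg <- c(msg, "node degrees must match incident edge counts")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn AssociationNetwork node table
#' @param x an AssociationNetwork
#' @export
networkNodes <- function(x) x@nodes

#' @describeIn AssociationNetwork edge table
#' @export
networkEdges <- function(x) x@edges

setMethod("show", "AssociationNetwork", function(object) {
  cat("AssociationNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
  if (nrow(object@edges)) {
    cat("  signs:", sum(object@edges$sign == "co-occurrence"),
        "co-occurrence /", sum(object@edges$sign == "avoidance"),
        "avoidance\n")
    cat("  affiliations:",
        paste(names(table(object@nodes$affiliation)),
              table(object@nodes$affiliation), collapse = ", "), "\n")
  }
})
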