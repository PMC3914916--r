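#' Substrate affiliation from per-species occurrence counts
#'
#' A taxon is affiliated to the tree species carrying at least
#' \code{threshold} of its occurrences (inclusive, so exactly 75% counts as
#' affiliated); otherwise it is a substrate generalist.
#'
#' @param counts matrix or data.frame, taxa x tree species, of occurrence
#'   counts; column names are the species labels.
#' @param threshold affiliation share (default 0.75).
#' @return character vector of affiliations (species label or
#'   \code{"generalist"}), named by taxon.
#' @examples
#' affiliation(cbind(Fagus = c(9, 3), Picea = c(1, 2)))
#' @export
affiliation <- function(counts, threshold = 0.75) {
  m <- as.matrix(counts)
  tot <- rowSums(m)
  if (any(tot == 0)) stop("taxon with zero occurrences: ",
                          paste(rownames(m)[tot == 0], collapse = ", "))
  share <- m / tot
  lab <- apply(share, 1, function(s) {
    k <- which(s >= threshold)
    if (length(k)) colnames(m)[k[1]] else "generalist"
  })
  setNames(lab, rownames(m))
}

widthFromP <- function(p, pMin = 0.0017, pMax = 0.049,
                       wMin = 1, wMax = 5) {
  pc <- clamp(p, pMin, pMax)
  wMin + (wMax - wMin) * (pMax - pc) / (pMax - pMin)
}

#' Assemble the association network from pairwise scores
#'
#' Keeps significant pairs (classification co-occurrence or avoidance) that
#' involve at least one nifH MOTU -- fungus-fungus pairs are dropped -- and
#' builds the signed network. Nodes are the taxa of the retained edges,
#' annotated with kingdom, substrate affiliation and degree; edges carry the
#' sign, the pair's two-sided empirical p (clipped to (0, 0.05] for
#' display), and a width decreasing in p over [0.0017, 0.049].
#'
#' @param pairScores data.frame from \code{\link{pairwiseZ}}.
#' @param speciesCounts taxa x tree-species occurrence counts used for the
#'   affiliation rule (rownames must cover the retained taxa); \code{NULL}
#'   labels every node \code{"generalist"}.
#' @param threshold affiliation threshold (default 0.75).
#' @return an \linkS4class{AssociationNetwork}; no significant pairs give an
#'   empty network.
#' @export
buildNetwork <- function(pairScores, speciesCounts = NULL,
                         threshold = 0.75) {
  sig <- pairScores[pairScores$classification %in%
                      c("co-occurrence", "avoidance"), , drop = FALSE]
  sig <- sig[sig$kingdomA == "nifH" | sig$kingdomB == "nifH", ,
             drop = FALSE]
  if (!nrow(sig)) {
    return(new("AssociationNetwork",
               nodes = data.frame(id = character(), kingdom = character(),
                                  affiliation = character(),
                                  degree = integer()),
               edges = data.frame(from = character(), to = character(),
                                  sign = character(), z = numeric(),
                                  p = numeric(), width = numeric())))
  }
  pDisp <- clamp(sig$p, 1e-6, 0.05)
  edges <- data.frame(from = sig$a, to = sig$b, sign = sig$classification,
                      z = sig$z, p = pDisp, width = widthFromP(pDisp),
                      stringsAsFactors = FALSE)
  ids <- unique(c(edges$from, edges$to))
  king <- setNames(c(sig$kingdomA, sig$kingdomB), c(sig$a, sig$b))
  aff <- if (!is.null(speciesCounts))
    affiliation(speciesCounts[ids, , drop = FALSE], threshold)
  else setNames(rep("generalist", length(ids)), ids)
  deg <- table(factor(c(edges$from, edges$to), levels = ids))
  nodes <- data.frame(id = ids, kingdom = unname(king[ids]),
                      affiliation = unname(aff[ids]),
                      degree = as.integer(deg), stringsAsFactors = FALSE)
  new("AssociationNetwork", nodes = nodes, edges = edges)
}

#' Hubs and mean degree
#'
#' Hubs are nodes of degree strictly greater than \code{hubThreshold}
#' (a node with exactly 10 edges is not a hub). Mean degree of the simple
#' graph is 2E/N.
#'
#' @param network an \linkS4class{AssociationNetwork} (non-empty).
#' @param hubThreshold strict degree cutoff (default 10).
#' @return list with \code{hubs} (node ids) and \code{meanDegree}.
#' @export
hubsAndDegree <- function(network, hubThreshold = 10L) {
  n <- networkNodes(network)
  if (!nrow(n)) stop("empty network")
  list(hubs = n$id[n$degree > hubThreshold],
       meanDegree = 2 * nrow(networkEdges(network)) / nrow(n))
}

#' Per-affiliation subnetwork summary
#'
#' Counts positive (co-occurrence) and negative (avoidance) edges within
#' each affiliation group and bridging each pair of groups, and reports
#' whether any positive edge bridges the Fagus and Picea subnetworks.
#'
#' @param network an \linkS4class{AssociationNetwork}.
#' @return list with \code{within} (data.frame group x sign counts),
#'   \code{bridges} (data.frame groupA, groupB, sign counts) and
#'   \code{positiveFagusPiceaBridge} (logical; NA for an empty network).
#' @export
subnetworkSummary <- function(network) {
  e <- networkEdges(network); n <- networkNodes(network)
  if (!nrow(e))
    return(list(within = data.frame(), bridges = data.frame(),
                positiveFagusPiceaBridge = NA))
  aff <- setNames(n$affiliation, n$id)
  ga <- aff[e$from]; gb <- aff[e$to]
  within <- e[ga == gb, , drop = FALSE]
  wtab <- as.data.frame(table(group = ga[ga == gb],
                              sign = within$sign), stringsAsFactors = FALSE)
  lohi <- t(apply(cbind(ga, gb), 1, sort))
  bridge <- e[ga != gb, , drop = FALSE]
  btab <- if (nrow(bridge))
    as.data.frame(table(groupA = lohi[ga != gb, 1],
                        groupB = lohi[ga != gb, 2],
                        sign = bridge$sign), stringsAsFactors = FALSE)
  else data.frame()
  fp <- any(ga != gb & e$sign == "co-occurrence" &
              ((ga == "Fagus" & gb == "Picea") |
               (ga == "Picea" & gb == "Fagus")))
  list(within = wtab, bridges = btab, positiveFagusPiceaBridge = fp)
}

#' Export an association network
#'
#' Formats: \code{"edge-tsv"} (single annotated TSV with node and edge
#' sections; round-trips losslessly through \code{\link{importNetwork}}),
#' \code{"sif"} (Cytoscape simple-interaction lines) and \code{"graphml"}
#' (via igraph, with kingdom/affiliation node attributes and sign/p/width
#' edge attributes).
#'
#' @param network an \linkS4class{AssociationNetwork}.
#' @param path output file path.
#' @param format one of \code{"edge-tsv"}, \code{"sif"}, \code{"graphml"}.
#' @return \code{path}, invisibly.
#' @export
exportNetwork <- function(network, path,
                          format = c("edge-tsv", "sif", "graphml")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unsupported format: ",
                                              format[1]))
  n <- networkNodes(network); e <- networkEdges(network)
  if (format == "edge-tsv") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("# nifhnet association network v1", con)
    writeLines(paste("N", "id", "kingdom", "affiliation", "degree",
                     sep = "\t"), con)
    if (nrow(n))
      writeLines(paste("N", n$id, n$kingdom, n$affiliation, n$degree,
                       sep = "\t"), con)
    writeLines(paste("E", "from", "to", "sign", "z", "p", "width",
                     sep = "\t"), con)
    if (nrow(e))
      writeLines(paste("E", e$from, e$to, e$sign,
                       formatC(e$z, digits = 15, format = "g"),
                       formatC(e$p, digits = 15, format = "g"),
                       formatC(e$width, digits = 15, format = "g"),
                       sep = "\t"), con)
  } else if (format == "sif") {
    lines <- if (nrow(e))
      paste(e$from, ifelse(e$sign == "co-occurrence", "co-occurs",
                           "avoids"), e$to, sep = "\t")
    else character()
    writeLines(lines, path)
  } else {
    g <- if (nrow(n))
      igraph::graph_from_data_frame(
        if (nrow(e)) e else data.frame(from = character(),
                                       to = character()),
        directed = FALSE, vertices = n)
    else igraph::make_empty_graph(directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a network written as edge-TSV
#'
#' @param path file produced by \code{exportNetwork(format = "edge-tsv")}.
#' @return an \linkS4class{AssociationNetwork}.
#' @export
importNetwork <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  tag <- vapply(fields, `[`, character(1), 1L)
  nl <- fields[tag == "N"][-1]; el <- fields[tag == "E"][-1]
  nodes <- if (length(nl))
    data.frame(id = vapply(nl, `[`, "", 2), kingdom = vapply(nl, `[`, "", 3),
               affiliation = vapply(nl, `[`, "", 4),
               degree = as.integer(vapply(nl, `[`, "", 5)),
               stringsAsFactors = FALSE)
  else data.frame(id = character(), kingdom = character(),
                  affiliation = character(), degree = integer())
  edges <- if (length(el))
    data.frame(from = vapply(el, `[`, "", 2), to = vapply(el, `[`, "", 3),
               sign = vapply(el, `[`, "", 4),
               z = as.numeric(vapply(el, `[`, "", 5)),
               p = as.numeric(vapply(el, `[`, "", 6)),
               width = as.numeric(vapply(el, `[`, "", 7)),
               stringsAsFactors = FALSE)
  else data.frame(from = character(), to = character(), sign = character(),
                  z = numeric(), p = numeric(), width = numeric())
  new("AssociationNetwork", nodes = nodes, edges = edges)
}
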