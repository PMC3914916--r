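#' Write amplicon reads with metadata headers
#'
#' FASTA headers follow a key=value scheme:
#' \code{>read00001 log=L01 species=Fagus motu=M003}. Round-trips
#' losslessly through \code{\link{readAmplicons}}.
#'
#' @param reads \code{DNAStringSet} with \code{mcols()} columns \code{log},
#'   \code{species} and optionally \code{motu}.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeAmplicons <- function(reads, path) {
  meta <- S4Vectors::mcols(reads)
  if (is.null(meta) || !"log" %in% colnames(meta))
    stop("reads must carry a 'log' metadata column")
  hdr <- paste0(names(reads), " log=", meta$log)
  if ("species" %in% colnames(meta) && !all(is.na(meta$species)))
    hdr <- paste0(hdr, " species=", meta$species)
  if ("motu" %in% colnames(meta))
    hdr <- paste0(hdr, " motu=", meta$motu)
  out <- reads
  names(out) <- hdr
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Read amplicon reads and their metadata headers
#'
#' @param path FASTA file whose headers carry \code{log=} (required) and
#'   optional \code{species=}/\code{motu=} key=value fields.
#' @return \code{DNAStringSet} with parsed \code{mcols()}.
#' @export
readAmplicons <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (!length(x)) return(x)
  hdr <- names(x)
  getField <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=\\S+"), hdr))
    out <- rep(NA_character_, length(hdr))
    hit <- grepl(paste0(key, "="), hdr)
    out[hit] <- sub(paste0(key, "="), "", m)
    out
  }
  logs <- getField("log")
  if (anyNA(logs))
    stop("header missing log id: ",
         paste(hdr[is.na(logs)], collapse = "; "))
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(
    log = logs, species = getField("species"), motu = getField("motu"))
  names(x) <- sub(" .*", "", hdr)
  x
}

#' Write a labeled community matrix as TSV
#'
#' The first line is a dialect comment (\code{# dialect=abundance} or
#' \code{# dialect=binary}); round-trips losslessly through
#' \code{\link{readMatrix}}.
#'
#' @param mat labeled numeric matrix (rows = logs or species).
#' @param path output TSV path.
#' @param dialect \code{"abundance"} (non-negative values) or
#'   \code{"binary"} (0/1 only).
#' @return \code{path}, invisibly.
#' @export
writeMatrix <- function(mat, path, dialect = c("abundance", "binary")) {
  dialect <- match.arg(dialect)
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("negative abundance")
  if (dialect == "binary" && !all(mat %in% c(0, 1)))
    stop("binary dialect requires 0/1 cells")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# dialect=", dialect), con)
  writeLines(paste(c("id", colnames(mat)), collapse = "\t"), con)
  for (i in seq_len(nrow(mat)))
    writeLines(paste(c(rownames(mat)[i], mat[i, ]), collapse = "\t"), con)
  invisible(path)
}

#' Read a labeled community matrix from TSV
#'
#' @param path TSV written by \code{\link{writeMatrix}} (or compatible:
#'   optional dialect comment, header row, row labels in column 1).
#' @return numeric matrix with a \code{"dialect"} attribute.
#' @export
readMatrix <- function(path) {
  lines <- readLines(path)
  dialect <- "abundance"
  if (length(lines) && startsWith(lines[1], "#")) {
    if (grepl("dialect=binary", lines[1])) dialect <- "binary"
    lines <- lines[-1]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1L)
    stop("ragged rows: line(s) ",
         paste(which(ncols != ncols[1]), collapse = ", "))
  header <- fields[[1]][-1]
  body <- fields[-1]
  m <- matrix(as.numeric(unlist(lapply(body, `[`, -1))),
              nrow = length(body), byrow = TRUE,
              dimnames = list(vapply(body, `[`, "", 1), header))
  if (anyNA(m)) stop("non-numeric cells")
  if (any(m < 0)) stop("negative abundance")
  if (dialect == "binary" && !all(m %in% c(0, 1)))
    stop("binary dialect with non-0/1 cell")
  attr(m, "dialect") <- dialect
  m
}

#' Default pipeline configuration
#'
#' All stage parameters with their defaults: the 97% clustering identity,
#' k = 4 decay classes, 999 permutations, null-ensemble size 100,
#' |Z| > 1.96 significance, 75% affiliation share, hub degree > 10, and the
#' >= 3-sample occurrence filter. Unknown keys and out-of-range values are
#' rejected.
#'
#' @param ... overrides of the defaults.
#' @return validated configuration list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(seed = 1L, nLogs = 45L, nFungi = 60L, nMotus = 25L,
              speciesEffect = 0.5, divergenceWithin = 0.02,
              identityThreshold = 0.97, kDecay = 4L, nPerm = 999L,
              ensembleN = 100L, burnIn = NULL, spacing = NULL,
              zThreshold = 1.96, affiliationThreshold = 0.75,
              hubThreshold = 10L, minOccurrence = 3L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$identityThreshold <= 0 || cfg$identityThreshold > 1)
    stop("config error: identityThreshold must lie in (0, 1]")
  if (cfg$zThreshold <= 0) stop("config error: zThreshold must be positive")
  if (cfg$affiliationThreshold <= 0.5 || cfg$affiliationThreshold > 1)
    stop("config error: affiliationThreshold must lie in (0.5, 1]")
  if (cfg$ensembleN < 1 || cfg$nPerm < 1 || cfg$minOccurrence < 1)
    stop("config error: counts must be positive")
  cfg
}

#' Run the full pipeline
#'
#' simulate -> cluster -> community -> nullmodel -> network, writing every
#' stage's outputs (FASTA, TSV matrices, JSON results, edge-TSV network)
#' and the effective configuration to \code{outDir}. Reruns with the same
#' configuration reproduce byte-identical numeric outputs.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the stage results and file paths.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "run.log")
  logMsg <- function(...) cat(..., "\n", sep = "",
                              file = logFile, append = TRUE)
  cat("", file = logFile)
  stage <- "config"
  result <- tryCatch({
    jsonlite::write_json(config, file.path(outDir, "config.json"),
                         auto_unbox = TRUE, null = "null")
    stage <- "simulate"
    design <- studyDesign(nLogs = config$nLogs, seed = config$seed)
    logs <- generateLogs(design)
    occ <- generateOccurrences(logs, nFungi = config$nFungi,
                               nMotus = config$nMotus,
                               speciesEffect = config$speciesEffect,
                               seed = config$seed)
    reads <- generateAmplicons(occ$motu,
                               divergenceWithin = config$divergenceWithin,
                               speciesByLog = setNames(logs$species,
                                                       logs$log),
                               seed = config$seed)
    writeAmplicons(reads, file.path(outDir, "amplicons.fasta"))
    writeMatrix(occ$fungal, file.path(outDir, "fungal_occurrence.tsv"),
                "binary")
    writeMatrix(occ$motu, file.path(outDir, "motu_abundance_truth.tsv"))
    write.table(logs, file.path(outDir, "log_metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    logMsg("simulate: ", length(reads), " reads from ", nrow(logs),
           " logs")
    stage <- "cluster"
    tr <- trimPrimers(reads)
    motus <- clusterGreedy(tr$reads[tr$trimmed],
                           threshold = config$identityThreshold)
    writeMatrix(motuAbundance(motus),
                file.path(outDir, "motu_abundance_clustered.tsv"))
    logMsg("cluster: ", sum(tr$trimmed), "/", length(reads),
           " reads trimmed; ", length(motuSizes(motus)), " MOTUs")
    stage <- "community"
    km <- kmeansDecayClasses(setNames(logs$remainingMass, logs$log),
                             k = config$kDecay, seed = config$seed)
    meta <- data.frame(species = factor(logs$species),
                       management = factor(logs$management),
                       decayClass = as.numeric(km$classes[logs$log]))
    ab <- motuAbundance(motus)[logs$log, , drop = FALSE]
    pm <- permanova(brayCurtis(ab),
                    ~ species * decayClass * management, meta,
                    nPerm = config$nPerm, seed = config$seed)
    write.table(pm, file.path(outDir, "permanova.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tree <- mrt(ab, data.frame(species = logs$species,
                               decayClass = factor(km$classes[logs$log]),
                               management = logs$management))
    jsonlite::write_json(mrtNodes(tree), file.path(outDir, "mrt.json"))
    rich <- richnessModels(data.frame(
      sporocarpRichness = rowSums(occ$fungal[logs$log, , drop = FALSE]),
      species = logs$species, nPerDensity = logs$nPerDensity,
      cPerDensity = logs$cPerDensity,
      decayClass = as.numeric(km$classes[logs$log]),
      nifhRichness = rowSums(ab > 0), remainingMass = logs$remainingMass))
    logMsg("community: permanova residual Df ",
           pm$Df[pm$term == "Residuals"])
    stage <- "nullmodel"
    bm <- binarizeAndFilter(occ$fungal, motuAbundance(motus),
                            minOccurrence = config$minOccurrence)
    bmAll <- binarizeAndFilter(occ$fungal, motuAbundance(motus),
                               applyTo = "matrix")
    ensAll <- nullEnsemble(bmAll, N = config$ensembleN,
                           seed = config$seed)
    ens <- nullEnsemble(bm, N = config$ensembleN,
                        burnIn = config$burnIn, spacing = config$spacing,
                        seed = config$seed)
    obsC <- cscore(bmAll); cb <- checkerboardStats(bmAll)
    matStats <- list(
      cscore = obsC, cscoreNullMean = mean(nullCscores(ensAll)),
      cscoreP = matrixTest(obsC, nullCscores(ensAll)),
      checkerboardPairs = cb$neverCooccurPairs,
      checkerboardUnits = cb$checkerboardUnits,
      checkerboardPairsP = matrixTest(cb$neverCooccurPairs,
                                      ensAll@checkerPairs),
      checkerboardUnitsP = matrixTest(cb$checkerboardUnits,
                                      ensAll@checkerUnits),
      swapAcceptanceRate = ens@acceptanceRate)
    pz <- pairwiseZ(ens, zThreshold = config$zThreshold)
    jsonlite::write_json(matStats, file.path(outDir, "matrix_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    write.table(pz, file.path(outDir, "pair_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    logMsg("nullmodel: swap acceptance ",
           signif(ens@acceptanceRate, 4), "; ",
           sum(pz$classification != "none"), " significant pairs")
    stage <- "network"
    spOrder <- sort(unique(logs$species))
    scounts <- rbind(
      t(vapply(colnames(occ$fungal), function(tx)
        c(sum(occ$fungal[logs$species == spOrder[1], tx] > 0),
          sum(occ$fungal[logs$species == spOrder[2], tx] > 0)),
        numeric(2))),
      t(vapply(colnames(motuAbundance(motus)), function(tx)
        c(sum(motuAbundance(motus)[logs$log, tx][logs$species ==
                                                   spOrder[1]] > 0),
          sum(motuAbundance(motus)[logs$log, tx][logs$species ==
                                                   spOrder[2]] > 0)),
        numeric(2))))
    colnames(scounts) <- spOrder
    net <- buildNetwork(pz, speciesCounts = scounts,
                        threshold = config$affiliationThreshold)
    exportNetwork(net, file.path(outDir, "network.tsv"), "edge-tsv")
    exportNetwork(net, file.path(outDir, "network.sif"), "sif")
    exportNetwork(net, file.path(outDir, "network.graphml"), "graphml")
    logMsg("network: ", nrow(networkNodes(net)), " nodes, ",
           nrow(networkEdges(net)), " edges")
    list(logs = logs, occurrences = occ, reads = reads, motus = motus,
         decay = km, permanova = pm, mrt = tree, richness = rich,
         matrixStats = matStats, pairScores = pz, network = net,
         outDir = outDir)
  }, error = function(e) {
    logMsg("FAILED at stage ", stage, ": ", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}
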