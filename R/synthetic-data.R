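#' Study design for the synthetic dead-wood survey
#'
#' Describes the sampling layout the generator emulates: logs of two tree
#' species (Fagus sylvatica, Picea abies) drawn from plots under three forest
#' management types. Defaults mirror a 45-log survey.
#'
#' @param nLogs number of dead-wood logs (>= 4; default 45).
#' @param speciesLabels tree-species labels (exactly two).
#' @param managementLabels forest-management labels (exactly three).
#' @param seed integer seed controlling all randomness downstream.
#' @return a \code{studyDesign} list.
#' @examples
#' d <- studyDesign(nLogs = 45, seed = 1)
#' @export
studyDesign <- function(nLogs = 45L,
                        speciesLabels = c("Fagus", "Picea"),
                        managementLabels = c("extensive_beech",
                                             "managed_beech",
                                             "managed_spruce"),
                        seed = 1L) {
  nLogs <- as.integer(nLogs)
  if (is.na(nLogs) || nLogs < 4L)
    stop("design error: nLogs must be at least 4")
  if (length(speciesLabels) != 2L)
    stop("design error: exactly two tree species labels required")
  if (length(managementLabels) != 3L)
    stop("design error: exactly three management labels required")
  structure(list(nLogs = nLogs, speciesLabels = speciesLabels,
                 managementLabels = managementLabels,
                 seed = as.integer(seed)),
            class = "studyDesign")
}

#' Generate per-log covariates
#'
#' Draws a table of log-level covariates emulating a dead-wood survey:
#' remaining mass after decay (uniform within four decay strata), water
#' content (unimodal in remaining mass, peaking at \code{waterOptimum}),
#' nitrogen per density unit (rising, in expectation, as remaining mass
#' falls) and carbon per density unit (higher in Fagus wood). Both tree
#' species and all management types are always represented.
#'
#' @param design a \code{\link{studyDesign}}.
#' @param waterOptimum water content (percent) at the mid-decay peak
#'   (default 54.9).
#' @param covariateStrength coupling between decay progress and N per
#'   density; 0 decouples them (mass and N then uncorrelated in
#'   expectation). Default 1.
#' @return data.frame with columns \code{log}, \code{species},
#'   \code{management}, \code{remainingMass}, \code{waterContent},
#'   \code{nPerDensity}, \code{cPerDensity}.
#' @examples
#' logs <- generateLogs(studyDesign(seed = 7))
#' @export
generateLogs <- function(design, waterOptimum = 54.9, covariateStrength = 1) {
  stopifnot(inherits(design, "studyDesign"))
  n <- design$nLogs
  withSeed(stageSeed(design$seed, "logs"), {
    species <- design$speciesLabels[rep_len(c(1L, 2L), n)]
    management <- design$managementLabels[rep_len(c(1L, 2L, 3L), n)]
    # four decay strata on remaining mass, filled round-robin
    lo <- c(80, 55, 30, 8); hi <- c(98, 80, 55, 30)
    stratum <- rep_len(1:4, n)
    mass <- runif(n, lo[stratum], hi[stratum])
    water <- waterOptimum - 0.006 * (mass - 55)^2 + rnorm(n, 0, 2.5)
    water <- clamp(water, 5, 95)
    nDens <- 0.0009 * (1 + covariateStrength * 1.8 * (100 - mass) / 100) *
      rlnorm(n, 0, 0.22)
    cDens <- ifelse(species == design$speciesLabels[1], 0.30, 0.21) *
      rlnorm(n, 0, 0.12)
    data.frame(log = sprintf("L%02d", seq_len(n)),
               species = species, management = management,
               remainingMass = mass, waterContent = water,
               nPerDensity = nDens, cPerDensity = cDens,
               stringsAsFactors = FALSE)
  })
}

#' Declare a planted pairwise association
#'
#' Ground truth for recovery tests: a fungus-MOTU (or MOTU-MOTU) pair whose
#' joint occurrence is coupled. At strength 0 the pair is independent; at
#' strength 1 a positive pair always co-occurs where either occurs and a
#' negative pair never co-occurs.
#'
#' @param a,b taxon ids (at least one must be a nifH MOTU, i.e. start
#'   with "M").
#' @param sign \code{"positive"} or \code{"negative"}.
#' @param strength probability shift in [0, 1].
#' @return a \code{plantedAssociation} list.
#' @export
plantedAssociation <- function(a, b, sign = c("positive", "negative"),
                               strength = 1) {
  sign <- match.arg(sign)
  if (strength < 0 || strength > 1) stop("strength must lie in [0, 1]")
  if (!grepl("^M", a) && !grepl("^M", b))
    stop("at least one member of a planted pair must be a nifH MOTU")
  structure(list(a = a, b = b, sign = sign, strength = strength),
            class = "plantedAssociation")
}

#' Generate fungal and nifH occurrence tables with planted associations
#'
#' Occurrence model: per-taxon baseline prevalence (rank-abundance shaped)
#' times per-log suitability (tree-species preference scaled by
#' \code{speciesEffect}, plus a decay-stage response). Planted pairs are
#' drawn from a mixture copula on the joint Bernoulli: with probability
#' \code{strength} the two indicators are fully coupled (positive: equal;
#' negative: mutually exclusive), otherwise independent. Per-log nifH MOTU
#' richness is kept inside \code{richnessRange} by adding/removing the
#' non-planted MOTUs with the most/least favourable occurrence probability.
#'
#' @param logs output of \code{\link{generateLogs}}.
#' @param nFungi,nMotus numbers of fungal species and nifH MOTUs.
#' @param planted list of \code{\link{plantedAssociation}} objects; a taxon
#'   may appear in at most one pair.
#' @param speciesEffect magnitude of the tree-species effect on composition
#'   (free parameter; default 0.5).
#' @param decayEffect magnitude of the decay-stage (remaining-mass) effect
#'   on per-taxon suitability (default 0.4). Set both effects to 0 for an
#'   exchangeable independence null.
#' @param richnessRange admissible per-log nifH richness (default 3--14);
#'   \code{NULL} disables the adjustment (used for independence
#'   calibration).
#' @param abundanceMean mean extra clone count per present MOTU cell
#'   (abundance = 1 + Poisson(\code{abundanceMean})).
#' @param seed integer seed.
#' @return list with \code{fungal} (logs x species 0/1 sporocarp matrix),
#'   \code{motu} (logs x MOTUs clone-count matrix) and \code{truth}
#'   (planted pairs and model parameters).
#' @examples
#' logs <- generateLogs(studyDesign(seed = 1))
#' occ <- generateOccurrences(logs, seed = 1)
#' range(rowSums(occ$motu > 0))
#' @export
generateOccurrences <- function(logs, nFungi = 60L, nMotus = 60L,
                                planted = list(), speciesEffect = 0.5,
                                decayEffect = 0.4,
                                richnessRange = c(3L, 14L),
                                abundanceMean = 2, seed = 1L) {
  if (nFungi < 1L || nMotus < 1L) stop("taxon counts must be positive")
  n <- nrow(logs)
  motuIds <- sprintf("M%03d", seq_len(nMotus))
  fungIds <- sprintf("F%03d", seq_len(nFungi))
  allIds <- c(motuIds, fungIds)
  plantedTaxa <- unlist(lapply(planted, function(p) c(p$a, p$b)))
  if (length(plantedTaxa)) {
    unknown <- setdiff(plantedTaxa, allIds)
    if (length(unknown))
      stop("planted pair references unknown taxon: ",
           paste(unknown, collapse = ", "))
    if (anyDuplicated(plantedTaxa))
      stop("a taxon may appear in at most one planted pair")
  }
  withSeed(stageSeed(seed, "occurrences"), {
    sL <- ifelse(logs$species == sort(unique(logs$species))[1], 1, -1)
    massScaled <- (logs$remainingMass - 55) / 45

    baseM <- 0.55 * exp(-(seq_len(nMotus) - 1) / 15) + 0.01
    baseF <- 0.50 * exp(-(seq_len(nFungi) - 1) / 12) + 0.012
    prefM <- runif(nMotus, -1, 1); prefF <- runif(nFungi, -1, 1)
    decM <- runif(nMotus, -1, 1);  decF <- runif(nFungi, -1, 1)
    # fungal sporocarp richness is higher on Fagus than Picea
    fungSpeciesMult <- ifelse(sL > 0, 1.35, 0.90)

    pM <- sapply(seq_len(nMotus), function(i)
      clamp(baseM[i] * (1 + speciesEffect * prefM[i] * sL) *
              (1 + decayEffect * decM[i] * massScaled), 0.004, 0.95))
    pF <- sapply(seq_len(nFungi), function(j)
      clamp(baseF[j] * fungSpeciesMult *
              (1 + speciesEffect * prefF[j] * sL) *
              (1 + decayEffect * decF[j] * massScaled), 0.004, 0.95))
    colnames(pM) <- motuIds; colnames(pF) <- fungIds
    P <- cbind(pM, pF)                       # logs x taxa probabilities

    X <- matrix(rbinom(length(P), 1L, P), nrow = n,
                dimnames = list(logs$log, allIds))
    # planted pairs overwrite their two columns via the mixture copula
    for (p in planted) {
      pa <- P[, p$a]; pb <- P[, p$b]
      coupled <- runif(n) < p$strength
      if (p$sign == "positive") {
        z <- rbinom(n, 1L, (pa + pb) / 2)
        X[coupled, p$a] <- z[coupled]
        X[coupled, p$b] <- z[coupled]
      } else {
        if (any(pa + pb > 1))
          warning("negative planted pair with pa + pb > 1; exclusivity ",
                  "cannot be guaranteed at those logs")
        u <- runif(n)
        X[coupled, p$a] <- as.integer(u[coupled] < pa[coupled])
        X[coupled, p$b] <- as.integer(u[coupled] > 1 - pb[coupled])
      }
      X[!coupled, p$a] <- rbinom(sum(!coupled), 1L, pa[!coupled])
      X[!coupled, p$b] <- rbinom(sum(!coupled), 1L, pb[!coupled])
    }

    motuX <- X[, motuIds, drop = FALSE]
    if (!is.null(richnessRange)) {
      free <- setdiff(motuIds, plantedTaxa)
      for (l in seq_len(n)) {
        r <- sum(motuX[l, ])
        if (r < richnessRange[1]) {
          absent <- free[motuX[l, free] == 0L]
          add <- absent[order(pM[l, absent], decreasing = TRUE)]
          add <- head(add, richnessRange[1] - r)
          motuX[l, add] <- 1L
        } else if (r > richnessRange[2]) {
          present <- free[motuX[l, free] == 1L]
          drop <- present[order(pM[l, present])]
          drop <- head(drop, r - richnessRange[2])
          motuX[l, drop] <- 0L
        }
      }
    }
    # clone counts: 1 + Poisson extra reads where present
    motuAb <- motuX * (1L + matrix(rpois(length(motuX), abundanceMean),
                                   nrow = n))
    fungal <- X[, fungIds, drop = FALSE]

    truth <- list(
      planted = if (length(planted))
        do.call(rbind, lapply(planted, function(p)
          data.frame(a = p$a, b = p$b, sign = p$sign,
                     strength = p$strength)))
      else data.frame(a = character(), b = character(),
                      sign = character(), strength = numeric()),
      speciesEffect = speciesEffect, richnessRange = richnessRange,
      seed = seed)
    list(fungal = fungal, motu = motuAb, truth = truth)
  })
}

#' Default PolF/PolR degenerate primer pair
#'
#' The universal nifH primers whose sites flank the amplified fragment.
#'
#' @return list with IUPAC strings \code{forward} and \code{reverse}.
#' @export
polPrimers <- function() {
  list(forward = "TGCGAYCCSAARGCBGACTC", reverse = "ATSGCCATCATYTCRCCGGA")
}

# path to the bundled synthetic nifH coding core (320 bp, cys codons at
# amino-acid positions 54 and 93)
nifhCorePath <- function()
  system.file("extdata", "nifh_core_synthetic.fasta", package = "nifhnet")

nifhCore <- function() {
  s <- Biostrings::readDNAStringSet(nifhCorePath())
  as.character(s[[1]])
}

# substitute base at nucleotide position pos, choosing an alternative that
# does not create a stop codon in reading frame 0
codingAlternative <- function(seqChars, pos) {
  stops <- c("TAA", "TAG", "TGA")
  cStart <- pos - (pos - 1L) %% 3L
  for (alt in sample(setdiff(c("A", "C", "G", "T"), seqChars[pos]))) {
    codon <- seqChars[cStart:min(cStart + 2L, length(seqChars))]
    codon[pos - cStart + 1L] <- alt
    if (length(codon) < 3L || !(paste(codon, collapse = "") %in% stops))
      return(alt)
  }
  NA_character_
}

#' Generate amplicon reads from a MOTU abundance table
#'
#' Each read is a concrete instance of the forward primer site, a mutated
#' copy of the MOTU seed sequence, and the reverse complement of a concrete
#' reverse-primer instance (360 bp in total with default primers). MOTU seed
#' sequences descend from a bundled synthetic nifH coding core by
#' substitutions at \code{divergenceBetween}; within a MOTU, substitutions
#' are confined to a per-MOTU set of variable sites of size
#' \code{divergenceWithin * length}, so any two reads of one MOTU diverge by
#' at most \code{divergenceWithin}. All substitutions keep reading frame 0
#' free of stop codons and spare the two conserved cysteine codons.
#'
#' @param motuTable logs x MOTUs abundance matrix (read counts).
#' @param divergenceWithin maximum within-MOTU divergence (default 0.02;
#'   values >= 0.03 trigger a warning because 97% clustering may then merge
#'   or split MOTUs).
#' @param divergenceBetween substitution fraction separating each MOTU seed
#'   from the common core (default 0.12).
#' @param primers primer pair as from \code{\link{polPrimers}}.
#' @param speciesByLog optional named character vector log -> tree species,
#'   stored in the read metadata.
#' @param seed integer seed.
#' @return \code{DNAStringSet} of reads; \code{mcols()} carries \code{log},
#'   \code{species} and the truth \code{motu} id.
#' @examples
#' occ <- generateOccurrences(generateLogs(studyDesign(seed = 1)),
#'                            nMotus = 5, nFungi = 5, seed = 1)
#' reads <- generateAmplicons(occ$motu[, 1:3], seed = 1)
#' @export
generateAmplicons <- function(motuTable, divergenceWithin = 0.02,
                              divergenceBetween = 0.12,
                              primers = polPrimers(), speciesByLog = NULL,
                              seed = 1L) {
  if (divergenceWithin < 0) stop("divergenceWithin must be non-negative")
  if (divergenceWithin >= 0.03)
    warning("divergenceWithin >= 0.03: clusters may merge or split at the ",
            "default 97% identity threshold")
  core <- strsplit(nifhCore(), "")[[1]]
  L <- length(core)
  protectedNt <- c(160:162, 277:279)     # cys codons at aa 54 and 93
  motuIds <- colnames(motuTable)
  logsIds <- rownames(motuTable)
  withSeed(stageSeed(seed, "amplicons"), {
    seeds <- list(); varSites <- list(); altAllele <- list()
    for (m in motuIds) {
      s <- core
      nmut <- round(divergenceBetween * L)
      pos <- sample(setdiff(seq_len(L), protectedNt), nmut)
      for (p in pos) {
        alt <- codingAlternative(s, p)
        if (!is.na(alt)) s[p] <- alt
      }
      seeds[[m]] <- s
      nvar <- round(divergenceWithin * L)
      vs <- if (nvar > 0)
        sample(setdiff(seq_len(L), protectedNt), nvar) else integer()
      varSites[[m]] <- vs
      altAllele[[m]] <- vapply(vs, function(p) codingAlternative(s, p),
                               character(1))
    }
    seqs <- character(); metaLog <- character(); metaMotu <- character()
    for (l in logsIds) for (m in motuIds) {
      k <- motuTable[l, m]
      if (k == 0) next
      for (r in seq_len(k)) {
        s <- seeds[[m]]
        vs <- varSites[[m]]
        if (length(vs)) {
          flip <- runif(length(vs)) < 0.5
          s[vs[flip]] <- altAllele[[m]][flip]
        }
        read <- paste0(sampleIupac(primers$forward),
                       paste(s, collapse = ""),
                       revcompIupac(sampleIupac(primers$reverse)))
        seqs <- c(seqs, read)
        metaLog <- c(metaLog, l); metaMotu <- c(metaMotu, m)
      }
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("read%05d", seq_along(out))
    sp <- if (!is.null(speciesByLog)) unname(speciesByLog[metaLog])
          else rep(NA_character_, length(out))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      log = metaLog, species = sp, motu = metaMotu)
    out
  })
}
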