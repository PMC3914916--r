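#' Trim degenerate primer sites from amplicon reads
#'
#' Matches the IUPAC-expanded forward primer at the 5' end and the reverse
#' complement of the reverse primer at the 3' end (exact length, at most
#' \code{maxMismatch} mismatches each) and removes both. Reads where either
#' site fails to match -- including reads shorter than the two primers
#' combined -- are flagged and returned unchanged.
#'
#' @param reads \code{DNAStringSet} (metadata columns are carried through).
#' @param primers primer pair as from \code{\link{polPrimers}}.
#' @param maxMismatch mismatches tolerated per primer site (default 0).
#' @return list with \code{reads} (trimmed where matched) and logical
#'   \code{trimmed} flags.
#' @examples
#' r <- Biostrings::DNAStringSet(paste0("TGCGACCCGAAGGCGGACTC", "ACGTACGT",
#'                                      "TCCGGCGAGATGATGGCGAT"))
#' trimPrimers(r)$reads
#' @export
trimPrimers <- function(reads, primers = polPrimers(), maxMismatch = 0L) {
  if (!length(reads)) return(list(reads = reads, trimmed = logical()))
  fwd <- toupper(primers$forward)
  revrc <- revcompIupac(primers$reverse)
  nf <- nchar(fwd); nr <- nchar(revrc)
  sq <- as.character(reads)
  if (any(!nzchar(sq))) stop("empty sequence")
  trimmed <- logical(length(sq))
  out <- sq
  for (i in seq_along(sq)) {
    len <- nchar(sq[i])
    if (len < nf + nr + 1L) next                       # too short: flagged
    mf <- iupacMismatches(fwd, sq[i], at = 1L)
    mr <- iupacMismatches(revrc, sq[i], at = len - nr + 1L)
    if (!is.na(mf) && !is.na(mr) && mf <= maxMismatch && mr <= maxMismatch) {
      out[i] <- substr(sq[i], nf + 1L, len - nr)
      trimmed[i] <- TRUE
    }
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- names(reads)
  S4Vectors::mcols(res) <- S4Vectors::mcols(reads)
  list(reads = res, trimmed = trimmed)
}

#' Global-alignment nucleotide identity
#'
#' Identity of the optimal Needleman-Wunsch global alignment, with the
#' shorter sequence length as denominator (the CD-HIT convention), so a
#' perfect prefix scores 1.
#'
#' @param a,b nucleotide strings (or \code{DNAString}s).
#' @return fraction in [0, 1]; symmetric in its arguments.
#' @examples
#' pairwiseIdentity("AAAA", "AAAT")   # 0.75
#' pairwiseIdentity("AAAA", "AAAAAA") # 1 under the shorter-length convention
#' @export
pairwiseIdentity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = dnaScore(),
                                       gapOpening = 5, gapExtension = 2)
  nid <- Biostrings::nmatch(aln)
  nid / min(nchar(a), nchar(b))
}

# +1/-1 nucleotide scoring with affine gaps 5/2 for identity alignments
dnaScore <- local({
  m <- NULL
  function() {
    if (is.null(m))
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1)
    m
  }
})

# identities of one sequence against a set of representatives (vectorized)
identityToReps <- function(reps, x) {
  if (!length(reps)) return(numeric())
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(reps), x,
                                       type = "global",
                                       substitutionMatrix = dnaScore(),
                                       gapOpening = 5, gapExtension = 2)
  Biostrings::nmatch(aln) / pmin(nchar(reps), nchar(as.character(x)))
}

#' Greedy identity clustering of amplicons into MOTUs
#'
#' CD-HIT-style incremental clustering: reads are processed in order of
#' decreasing length (ties by input order); each read joins the first
#' existing cluster whose representative it matches at identity >=
#' \code{threshold}, otherwise it founds a new cluster and becomes its
#' representative.
#'
#' @param reads primer-trimmed \code{DNAStringSet}; \code{mcols()} columns
#'   \code{log} and \code{species}, when present, feed the abundance matrix
#'   and per-species counts.
#' @param threshold identity cutoff in (0, 1] (default 0.97).
#' @return a \linkS4class{MotuSet} (empty input gives an empty set).
#' @examples
#' r <- Biostrings::DNAStringSet(rep("ACGTACGTACGT", 3))
#' names(r) <- paste0("r", 1:3)
#' motuSizes(clusterGreedy(r))
#' @export
clusterGreedy <- function(reads, threshold = 0.97) {
  if (threshold <= 0 || threshold > 1)
    stop("identity threshold must lie in (0, 1]")
  meta <- S4Vectors::mcols(reads)
  if (!length(reads)) {
    return(new("MotuSet", ids = character(), members = list(),
               representatives = Biostrings::DNAStringSet(),
               abundance = matrix(integer(), 1, 0,
                                  dimnames = list("all", NULL)),
               speciesCounts = matrix(integer(), 0, 0)))
  }
  if (is.null(names(reads))) names(reads) <- sprintf("read%05d",
                                                     seq_along(reads))
  ord <- order(-Biostrings::width(reads), seq_along(reads))
  reps <- character(); members <- list(); repChars <- list()
  sq <- as.character(reads)
  # Hamming screen for equal-length pairs: the ungapped alignment shows the
  # optimal global alignment has identity >= 1 - h/L, so a Hamming hit is a
  # certain hit; a rep more than `margin` below threshold cannot reach it
  # (default gap penalties make gapped realignment strictly costly); only
  # the band between needs a true alignment.
  margin <- 0.08
  for (i in ord) {
    ci <- strsplit(sq[i], "")[[1]]; li <- length(ci)
    hit <- 0L
    for (k in seq_along(reps)) {
      if (length(repChars[[k]]) == li) {
        idH <- 1 - sum(repChars[[k]] != ci) / li
        if (idH >= threshold) { hit <- k; break }
        if (idH < threshold - margin) next
      }
      if (identityToReps(reps[k], sq[i]) >= threshold) { hit <- k; break }
    }
    if (hit) {
      members[[hit]] <- c(members[[hit]], names(reads)[i])
    } else {
      reps <- c(reps, sq[i])
      repChars[[length(reps)]] <- ci
      members[[length(reps)]] <- names(reads)[i]
    }
  }
  ids <- sprintf("MOTU%03d", seq_along(reps))
  logv <- if (!is.null(meta) && "log" %in% colnames(meta))
    setNames(as.character(meta$log), names(reads))
  else setNames(rep("all", length(reads)), names(reads))
  logLevels <- unique(logv)
  ab <- sapply(members, function(mem)
    as.integer(table(factor(logv[mem], levels = logLevels))))
  ab <- matrix(ab, nrow = length(logLevels),
               dimnames = list(logLevels, ids))
  spv <- if (!is.null(meta) && "species" %in% colnames(meta) &&
             !all(is.na(meta$species)))
    setNames(as.character(meta$species), names(reads))
  else NULL
  sc <- if (!is.null(spv)) {
    lev <- sort(unique(stats::na.omit(spv)))
    m <- vapply(members, function(mem)
      as.integer(table(factor(spv[mem], levels = lev))),
      integer(length(lev)))
    m <- matrix(m, nrow = length(lev))
    matrix(t(m), nrow = length(members), dimnames = list(ids, lev))
  } else matrix(integer(), nrow = length(ids), ncol = 0,
                dimnames = list(ids, NULL))
  repSet <- Biostrings::DNAStringSet(reps)
  names(repSet) <- ids
  new("MotuSet", ids = ids, members = members, representatives = repSet,
      abundance = ab, speciesCounts = sc)
}

# bundled synthetic nifH reference protein (translation of the coding core)
referenceProtein <- function() {
  core <- nifhCore()
  as.character(Biostrings::translate(Biostrings::DNAString(
    substr(core, 1, 3 * (nchar(core) %/% 3)))))
}

translateFrame <- function(seq, frame) {
  s <- as.character(seq)
  s <- substr(s, frame + 1L, nchar(s))
  s <- substr(s, 1L, 3L * (nchar(s) %/% 3L))
  if (!nzchar(s)) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(s)))
}

#' Select the open reading frame of a trimmed amplicon
#'
#' Translates the three forward frames and returns one without a premature
#' stop codon (a stop in the final codon is tolerated). When several frames
#' are stop-free, the one whose translation aligns best to the bundled
#' synthetic nifH reference protein wins; remaining ties go to the lowest
#' frame index. Frames are forward-strand only: the forward primer fixes
#' the amplicon orientation.
#'
#' @param seq primer-trimmed nucleotide sequence (length >= 3).
#' @return frame in {0, 1, 2}, or \code{NA_integer_} when every frame
#'   contains an internal stop.
#' @export
selectReadingFrame <- function(seq) {
  s <- as.character(seq)
  if (nchar(s) < 3L) stop("sequence shorter than one codon")
  prots <- vapply(0:2, function(f) translateFrame(s, f), character(1))
  internalStop <- vapply(prots, function(p)
    grepl("[*]", substr(p, 1L, nchar(p) - 1L)), logical(1))
  open <- unname(which(!internalStop))
  if (!length(open)) return(NA_integer_)
  if (length(open) == 1L) return(open - 1L)
  ref <- Biostrings::AAString(referenceProtein())
  scores <- vapply(open, function(k) {
    p <- sub("[*]$", "", prots[k])
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(p), ref, type = "overlap",
      substitutionMatrix = "BLOSUM62")@score
  }, numeric(1))
  open[which.max(scores)] - 1L    # which.max takes the first (lowest) frame
}

#' Per-column majority consensus protein
#'
#' Majority residue per alignment column over equal-length member proteins
#' (the substitution-only amplicon model guarantees equal lengths); ties go
#' to the representative's residue (first member by default). A singleton's
#' consensus is its own translation. The conserved-cysteine flag is TRUE iff
#' cysteine occupies both configured reference-alignment positions, where
#' the Fe4S4-coordinating residues of functional dinitrogenase reductases
#' sit.
#'
#' @param proteins character vector of equal-length amino-acid strings.
#' @param representative the tie-breaking member (default first).
#' @param cysPositions alignment positions checked for cysteine
#'   (default 54 and 93).
#' @return list with \code{consensus}, \code{cysteineConserved}.
#' @export
consensusProtein <- function(proteins, representative = proteins[1],
                             cysPositions = c(54L, 93L)) {
  if (!length(proteins)) stop("no member proteins")
  lens <- nchar(proteins)
  if (length(unique(lens)) != 1L)
    stop("member proteins differ in length; indel-aware consensus is ",
         "unsupported")
  mat <- do.call(rbind, strsplit(proteins, ""))
  repCh <- strsplit(representative, "")[[1]]
  cons <- vapply(seq_len(ncol(mat)), function(j) {
    tab <- table(mat[, j])
    best <- names(tab)[tab == max(tab)]
    if (length(best) == 1L) best else {
      if (repCh[j] %in% best) repCh[j] else best[1]
    }
  }, character(1))
  consensus <- paste(cons, collapse = "")
  ok <- all(cysPositions <= nchar(consensus)) &&
    all(substring(consensus, cysPositions, cysPositions) == "C")
  list(consensus = consensus, cysteineConserved = ok)
}

#' Consensus proteins for every MOTU of a set
#'
#' For each MOTU, selects the reading frame on the representative, translates
#' all members in that frame and forms the majority consensus
#' (\code{\link{consensusProtein}}). MOTUs whose representative has no
#' stop-free frame are flagged with \code{NA}.
#'
#' @param motus a \linkS4class{MotuSet}.
#' @param reads the primer-trimmed \code{DNAStringSet} the set was built
#'   from (member ids must match read names).
#' @param cysPositions passed to \code{\link{consensusProtein}}.
#' @return data.frame: \code{motu}, \code{frame}, \code{consensus},
#'   \code{cysteineConserved}, \code{singleton}.
#' @export
consensusProteins <- function(motus, reads, cysPositions = c(54L, 93L)) {
  sq <- setNames(as.character(reads), names(reads))
  res <- lapply(seq_along(motus@ids), function(k) {
    rep <- as.character(motus@representatives[[k]])
    frame <- selectReadingFrame(rep)
    if (is.na(frame))
      return(data.frame(motu = motus@ids[k], frame = NA_integer_,
                        consensus = NA_character_,
                        cysteineConserved = NA))
    prots <- vapply(sq[motus@members[[k]]],
                    function(s) sub("[*]$", "", translateFrame(s, frame)),
                    character(1))
    cp <- consensusProtein(unname(prots),
                           representative = sub("[*]$", "",
                                                translateFrame(rep, frame)),
                           cysPositions = cysPositions)
    data.frame(motu = motus@ids[k], frame = frame,
               consensus = cp$consensus,
               cysteineConserved = cp$cysteineConserved)
  })
  out <- do.call(rbind, res)
  out$singleton <- unname(isSingleton(motus))
  out
}

#' Rank-abundance and exclusivity summaries of a MOTU set
#'
#' @param motus a \linkS4class{MotuSet} (at least one MOTU).
#' @return list with \code{rankAbundance} (MOTUs sorted by size descending,
#'   ties by id), \code{singletonFraction}, and \code{exclusivity} -- counts
#'   of MOTUs found in only the first tree species, only the second, or
#'   shared (when per-species counts are available).
#' @export
motuSummaries <- function(motus) {
  sz <- motuSizes(motus)
  if (!length(sz)) stop("at least one MOTU required")
  ord <- order(-sz, names(sz))
  rank <- data.frame(rank = seq_along(sz), motu = names(sz)[ord],
                     size = unname(sz[ord]),
                     singleton = unname(sz[ord] == 1L))
  sf <- sum(sz == 1L) / length(sz)
  excl <- NULL
  sc <- motus@speciesCounts
  if (ncol(sc) == 2L) {
    onlyA <- sum(sc[, 1] > 0 & sc[, 2] == 0)
    onlyB <- sum(sc[, 2] > 0 & sc[, 1] == 0)
    shared <- sum(sc[, 1] > 0 & sc[, 2] > 0)
    excl <- setNames(c(onlyA, onlyB, shared),
                     c(paste0("only_", colnames(sc)[1]),
                       paste0("only_", colnames(sc)[2]), "shared"))
  }
  list(rankAbundance = rank, singletonFraction = sf, exclusivity = excl)
}
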