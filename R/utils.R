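# Internal helpers shared across modules.

IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Expand an IUPAC degenerate nucleotide string to a concrete instance
#'
#' Draws one concrete base uniformly at each degenerate position. Used by the
#' amplicon generator to emit realistic primer-site variants.
#'
#' @param x IUPAC nucleotide string.
#' @return concrete ACGT string of the same length.
#' @keywords internal
sampleIupac <- function(x) {
  ch <- strsplit(toupper(x), "")[[1]]
  bad <- setdiff(ch, names(IUPAC))
  if (length(bad)) stop("not IUPAC nucleotide codes: ", paste(bad, collapse = ","))
  paste(vapply(ch, function(b) {
    opts <- IUPAC[[b]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

# number of mismatches of a concrete sequence against an IUPAC pattern,
# aligned at a fixed offset (1-based)
iupacMismatches <- function(pattern, subject, at = 1L) {
  p <- strsplit(toupper(pattern), "")[[1]]
  s <- strsplit(toupper(subject), "")[[1]]
  idx <- seq(at, at + length(p) - 1L)
  if (max(idx) > length(s)) return(NA_integer_)
  sum(!mapply(function(pc, sc) sc %in% IUPAC[[pc]], p, s[idx]))
}

revcompIupac <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  ch <- rev(strsplit(toupper(x), "")[[1]])
  paste(comp[ch], collapse = "")
}

# run code under a locally seeded RNG, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

# deterministic per-stage substream seeds below 2^31
stageSeed <- function(seed, stage) {
  offsets <- c(logs = 11L, occurrences = 23L, amplicons = 37L,
               cluster = 53L, community = 71L, nullmodel = 89L,
               network = 101L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
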