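---
title: "Methods: from nifH amplicons to fungus-diazotroph co-occurrence networks"
author: "nifhnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from nifH amplicons to fungus-diazotroph co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nifhnet)
```

## The scientific problem

Dead wood is extremely nitrogen poor (C:N ratios of several hundred to
one), yet wood-decaying fungi mobilize enough N to build hyphae and
sporocarps. One long-standing hypothesis is that diazotrophic
(N-fixing) bacteria, detectable through their *nifH* (dinitrogenase
reductase) genes, supply part of that nitrogen, which would leave a
statistical fingerprint: non-random co-occurrence between *nifH*
genotypes and fungal species across dead-wood logs.

`nifhnet` implements the full analysis chain needed to look for that
fingerprint in a clone-library survey of logs of two tree species
(*Fagus sylvatica*, *Picea abies*) under three forest-management types:

1. **Amplicon processing** — degenerate PolF/PolR primer trimming,
   greedy 97%-identity clustering of the 360-bp *nifH* fragment into
   MOTUs (molecular operational taxonomic units), reading-frame
   selection and majority-consensus proteins with a check of the two
   Fe~4~S~4~-coordinating cysteines.
2. **Community structure** — Bray-Curtis perMANOVA, multivariate
   regression trees (MRT), PCA of the tree's group means, k-means decay
   classes and sporocarp-richness regressions.
3. **Co-occurrence null models** — C-score and checkerboard statistics
   against fixed-fixed (row- and column-margin preserving) sequential
   swap ensembles, with pairwise Z-scores.
4. **Network assembly** — signed fungus-MOTU association networks with
   substrate affiliation, hub detection and Cytoscape-compatible export.
5. **Synthetic data** — a generator that emulates the 45-log study
   design with planted ground truth, so that every stage is testable
   without any external data.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions the pipeline is exercised under.

**Log covariates.** 45 logs split between the two tree species and the
three management types. Remaining mass after decay is drawn uniformly
within four decay strata filled round-robin, so every decay stage is
represented. Water content is unimodal in remaining mass with its peak
(default 54.9%) at mid-decay — decaying wood takes up water until
late-stage collapse. N per density unit increases in expectation as mass
is lost (times lognormal noise); setting `covariateStrength = 0`
decouples them exactly, which the tests use to verify the null
behaviour of downstream regressions. C per density is higher in
*Fagus* than in *Picea* wood.

**Occurrences.** Each taxon has a rank-abundance-shaped baseline
prevalence multiplied by per-log suitability: a tree-species preference
scaled by `speciesEffect` and a decay response scaled by `decayEffect`.
The study data give no quantitative effect size for the tree-species
effect on composition, so it is a free parameter (default 0.5, enough
to make tree species the dominant MRT split without silencing the decay
signal). Planted pairwise associations are drawn from a mixture copula
on the joint Bernoulli: with probability `strength` the two indicators
are fully coupled (positive: identical; negative: mutually exclusive,
attainable when the occurrence probabilities sum to at most 1),
otherwise independent. Strength 0 therefore yields exact independence —
the property the calibration tests rely on — and strength 1 yields the
deterministic limiting cases. Per-log nifH richness is held inside
3–14, the observed range in this study design, by adjusting only
non-planted MOTUs.

**Amplicons.** Each read is a concrete instance of the degenerate
forward primer site, a mutated copy of its MOTU's seed sequence, and
the reverse complement of a reverse-primer instance (360 bp in total).
MOTU seeds descend from a bundled *synthetic* 320-bp coding core
(`inst/extdata/nifh_core_synthetic.fasta`) by ~12% substitutions, so
between-MOTU identity sits far below the 97% threshold. Within a MOTU,
substitutions are confined to a small per-MOTU set of variable sites
(`divergenceWithin` × length, default 2%), mimicking hypervariable
positions in real marker genes. This choice matters: it bounds the
divergence between any two reads of one MOTU by `divergenceWithin`, so
97% clustering recovers the planted MOTUs exactly at the 2% default,
whereas independently scattered mutations would let read pairs drift to
twice that distance and straddle the threshold. All substitutions keep
frame 0 stop-free and spare the two cysteine codons (amino-acid
positions 54 and 93), so translation and the conserved-cysteine check
have known truth.

**What the generator does not emulate:** chimeras, sequencing error
profiles, indels, phylogenetic structure among MOTUs, spatial
autocorrelation among logs, or abundance-biased PCR. Passing tests
therefore demonstrate the correctness of the statistical machinery
under a clean substitution-only, independence-or-planted world — not
robustness to those artefacts.

## Amplicon processing

*Primer trimming* expands IUPAC codes exactly and requires a full-length
match at both ends (0 mismatches by default; configurable for noisier
data). Unmatched reads are flagged, never silently altered.

*Identity* is the match count of the optimal global (Needleman-Wunsch)
alignment divided by the shorter sequence length — the CD-HIT
convention. Scoring is +1/−1 with affine gap penalties 5/2. Whether
identity should be global or local for such short amplicons is not
settled; global is used and noted as a potential divergence from other
tools.

*Clustering* is CD-HIT-style greedy incremental clustering: reads in
decreasing length order (ties by input order) join the first cluster
whose representative they match at ≥ 97%, else found a new cluster.
Determinism follows from the fixed processing order. As a performance
device, equal-length comparisons are screened by Hamming distance: the
ungapped alignment guarantees alignment identity ≥ 1 − h/L, so a
Hamming hit is accepted outright, and a representative more than 8
percentage points below threshold is rejected outright (with +1/−1/5/2
scoring, gapped realignment of substitution-only sequences cannot bridge
that gap); only the narrow band between triggers a true alignment.

*Frames* are forward-strand only, since the forward primer fixes the
amplicon orientation. Among stop-free frames the translation aligning
best (BLOSUM62) to the bundled synthetic reference protein wins; ties go
to the lowest frame index. *Consensus* is the per-column majority with
ties resolved to the representative's residue; indel-aware consensus is
out of scope because the substitution-only model keeps members
equal-length, and length disagreement is an error rather than a silent
gap insertion.

## Community structure

*Decay classes* come from standard 1-D k-means on remaining mass
(k = 4, 50 random restarts, seeded), relabelled 1–4 by descending
center so class 1 is the least decayed. In one dimension the optimum is
a contiguous interval partition, which the tests verify against an
exhaustive ordered-partition search.

*perMANOVA* uses sequential (Type I) sums of squares in the order the
model lists its terms, entering decay class as a numeric single-df
covariate — this reproduces the single-df decay row and the
residual/total Df bookkeeping (33/44 at n = 45) of the three-factor
design. Rows are permuted freely (no strata); p = (#{permuted F ≥
observed} + 1)/(n~perm~ + 1), so 999 permutations bound p below at
0.001. Computation is delegated to `vegan::adonis2`; the wrapper
enforces complete metadata, rejects rank-deficient designs naming the
aliased terms, and checks the SS/Df identities.

*MRT* is greedy binary splitting of the abundance matrix minimizing
within-node sums of squared Euclidean distances, with fixed stop rules
(node ≥ 5 to split, depth ≤ 4, relative improvement ≥ 1% of root SS)
and no cross-validated pruning — the analysis it mirrors names no
pruning rule, and fixed rules keep the tree deterministic.

*PCA of group means* eigendecomposes the covariance of the leaf-group
mean vectors and projects samples onto those axes. The "intersect
correlation" reported per axis is defined here as the correlation
between sample scores and their group-mean scores (the source analysis
does not define the term); axes above 0.8 are flagged as potentially
carrying significant between-group variation.

*Richness models* fit sporocarp richness on tree species, log N and
log C per density, decay class (numeric) and nifH richness by OLS,
reporting the full sequential ANOVA (residual Df 39 at n = 45)
alongside backward elimination on marginal F-test p-values
(drop the largest until all retained p < 0.05). Degree-2 polynomial and
linear fits per tree species cover the richness-vs-mass, -vs-log N and
-vs-nifH relationships.

## Co-occurrence null models

The presence/absence machinery is authored here rather than delegated,
since its exact conventions are the heart of the analysis:

- **C-score** — mean over all R(R−1)/2 species pairs of the
  checkerboard units CU~ij~ = (r~i~ − S~ij~)(r~j~ − S~ij~), where r are
  row totals and S the shared-site count. Larger values mean
  segregation.
- **Checkerboard index** — reported both as the number of species pairs
  that never co-occur (the wording of the source analysis, and the
  default) and as total checkerboard units (the classical statistic);
  which one a given legacy program printed is ambiguous, so both are
  computed.
- **Fixed-fixed null** — sequential swap: sample a 2×2 submatrix
  uniformly at random; flip it iff it is a checkerboard. Because the
  proposal is uniform and the flip condition symmetric, the chain is
  doubly stochastic and its stationary distribution is uniform over the
  margin-preserving state space — verified by exhaustive enumeration of
  a 4×4 state space and a chi-square uniformity test. Burn-in defaults
  to 10× and sampling spacing to 5× the number of presences (the
  sampler's "default settings" are otherwise unspecified); both are
  configurable and the swap acceptance rate is reported to diagnose
  near-degenerate matrices. A matrix with zero checkerboard submatrices
  warns: its null distribution is a point mass.
- **Pairwise Z** — Z = (CU~obs~ − mean CU~null~)/sd CU~null~ against an
  ensemble of 100 matrices by default (the documented choice of the
  legacy pairwise program; configurable). Z < −1.96 is co-occurrence,
  Z > +1.96 avoidance. A zero null sd with CU~obs~ equal to the null
  mean gives Z = 0 ("none"); otherwise the pair is flagged
  indeterminate rather than forced into a category. Only species
  present in ≥ 3 samples enter pairwise analysis; the matrix-level test
  keeps all species, mirroring the order of the source description.
- **Tail probabilities** use the add-one convention
  (count + 1)/(N + 1), so p is never 0 — the same logic as the
  permutation floor.

Under independence (generator at strength 0, both suitability effects
0), the |Z| > 1.96 flag rate is ≈ 5%, i.e. the significance convention
behaves as a nominal-level test; the acceptance suite checks this over
500 replicates of 20 species × 20 sites with N = 100, judging the mean
against three binomial standard errors computed on the number of
replicates (pairs within a replicate share one null ensemble and are
not independent draws).

## Network assembly

Significant pairs with at least one nifH endpoint become edges
(fungus-fungus pairs are dropped); co-occurrence and avoidance keep
their signs. Substrate affiliation assigns a taxon to the tree species
carrying ≥ 75% of its occurrences — inclusive at exactly 75%, since the
source states "a threshold of 75%" without strictness — else
"generalist". Hubs are nodes of degree strictly greater than 10,
matching the printed "> 10 degrees". Mean degree is 2E/N on the
filtered simple graph (whether the original network viewer counted
multi-edges is unknowable; there are none here). Edge widths map the
pair's two-sided empirical p, clipped to [0.0017, 0.049], linearly and
decreasingly onto [1, 5], so the most significant edge is thickest.
Export formats are an annotated edge-TSV (lossless round trip), SIF and
GraphML.

## Reproducibility and problem sizes

Every stochastic step takes a seed; a single pipeline seed fans out to
per-stage substreams, and reruns are byte-identical. The test suite
sizes its simulations to stay quick while keeping Monte Carlo error
well inside the asserted tolerances: oracle equivalence uses 200 random
matrices up to 8×10, exhaustive splits up to 10 samples and exhaustive
1-D partitions up to 12 points; the uniformity check samples 18,000
states of an enumerable 4×4 space; calibration uses 500 replicates at
20 × 20 with ensembles of 100.

## Known limitations

- Indels and chimeras are out of scope end to end; real amplicon data
  would need upstream denoising.
- The greedy clustering depends on processing order near the threshold,
  as all CD-HIT-style algorithms do; the oracle test asserts only that
  clusters refine the ≥-threshold identity-graph components.
- The bundled reference protein is synthetic; frame selection on real
  *nifH* reads should substitute a curated reference.
- Pairwise Z-scores inherit the discreteness of checkerboard units;
  with small ensembles the normal cutoff is approximate, which is why
  the calibration property is stated with Monte Carlo tolerance.
- The observed statistics of the original survey (its C-score,
  checkerboard values and 54 significant pairs) depend on its
  unpublished occurrence matrices; nothing here re-derives them, and
  the package makes no claim to.
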