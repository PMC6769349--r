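---
title: "Models and methods behind grfevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind grfevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grfevol)
```

`grfevol` packages the full computational arc of a plant gene-family study
— of the kind built around the growth-regulating factor (GRF) family of
transcription factors — as seeded, testable stages: family delineation by
conserved domains, homolog calling, selection and dating analysis,
phylogeny, promoter censuses and expression statistics. This vignette
records the models, the tunable parameters, the numerical conventions, and
the places where a genuinely open design choice had to be fixed.

## Family delineation and protein characterization

GRF proteins are defined by two N-terminal domains: QLQ
(Gln-Leu-Gln, a protein-interaction region) and WRC (Trp-Arg-Cys, carrying
a Cys3His zinc finger). Profile-HMM scoring of these domains is out of
scope here; instead membership is called from **spacing patterns** over
residue classes, shipped as an editable TSV
(`inst/extdata/domain_patterns.tsv`):

* QLQ core: `Q-x(2,4)-L-x(2,4)-Q`;
* WRC core: `W-R-C` with the C read as the first zinc-finger cysteine,
  continuing `x(6,12)-C-x(8,14)-C-x(1,3)-H`;
* FFD and TQL as C-terminal tripeptides tolerating one substitution.

A protein is a family member iff it has at least one QLQ *and* one WRC
hit. The scanner reports non-overlapping leftmost matches with minimal
spans, which makes plantings in synthetic fixtures exactly recoverable.
Because the accepted spacings of any particular HMM library are not
recoverable from pattern form alone, genome-scale membership calls should
be read as candidate lists; this is a deliberate, documented surrogate.

Molecular weight uses average (not monoisotopic) residue masses plus one
water; the isoelectric point solves `charge(pH) = 0` by bisection on a
Henderson–Hasselbalch model with the EMBOSS pKa set. Both tables ship as
data files so they can be audited or swapped. The bisection agrees with a
1e-4-pH brute-force grid scan to 1e-3 pH units across random peptides (a
standing test). Family reports always recompute column means from
per-gene values rather than echoing any published summary, because
published table means are occasionally internally inconsistent — the
bundled reference family table is one example, where the quoted mean
molecular weight (39,250.5 Da) differs from the mean of its own column
(≈39,182.6 Da).

## Homolog calling

All-against-all heuristic BLASTN searching is replaced by **exact
Smith–Waterman local alignment** with affine gaps and BLASTN-like scores
(match +2, mismatch −3, gap open −5, gap extend −2; a gap of length L
costs `open + L·extend`). At gene-family scale (tens of sequences, kb
lengths) exactness is affordable and buys determinism and oracle
testability — the suite checks the scores against exhaustive enumeration
on ≤6-mers. Both strands are scanned; the better strand is kept, ties to
the forward strand. Score ties in best-hit selection break to the
lexicographically smallest target id.

Orthologs are **bidirectional best hits** between two species' CDS sets,
kept only when the best local alignment spans *more than* 300 gap-free
columns (strict `>`; `bbh_min_aln`). Paralogs are all within-species
pairs spanning more than 300 bp at *at least* 40% identity (`≥`;
`paralog_min_identity`). The boundary semantics (strict vs inclusive) are
frozen in tests. "Aligned length" is read as the gap-free column count of
the single best local alignment, not a sum over multiple high-scoring
segments — the alternative reading cannot be distinguished from published
methods text, so one convention is fixed and documented.

## Ka/Ks: Nei–Gojobori (1986) with Jukes–Cantor correction

The selection analysis is the package's computational core and is
hand-authored:

* **Sites.** For each codon position, the synonymous site fraction is the
  fraction of the three single-base changes that preserve the amino acid,
  with changes to stop codons excluded from the denominator. Each position
  contributes one site, so `S + N = 3 ×` (counted codons) exactly.
* **Differences.** For a codon pair differing at k positions, all k!
  orderings of the single-base steps are averaged with equal weight;
  pathways through stop codons are excluded. If every pathway crosses a
  stop, the column is flagged uncountable and dropped from the counts
  (reported in the result).
* **Correction.** `Ka = JC(Nd/N)`, `Ks = JC(Sd/S)` with
  `JC(p) = −(3/4)·ln(1 − 4p/3)`; `p ≥ 3/4` (pathway-averaged proportions
  can even exceed 1) is saturation and clears the corresponding validity
  flag. `Ka/Ks` is reported only when Ks is valid and positive; at
  `Ks = 0` the ratio is *undefined*, never infinity.

Both counting conventions are exercised against brute-force enumeration
over every sense-codon pair in the test suite. Codon alignments are built
by globally aligning the translated proteins and back-translating, so
indels always appear as whole-codon gap triples.

Sliding-window profiles use windows of 150 bp stepped by 9 bp
(`window_len`, `window_step`) over the *ungapped* nucleotide coordinates
of the codon alignment; both defaults are codon multiples, so windows
never split codons. Invalid windows (saturated or zero-site) are reported
with their flags rather than silently dropped.

Divergence times use the molecular-clock conversion `T = Ks / (2λ)` with
the grass synonymous rate `λ = 6.5×10⁻⁹` substitutions/site/year, reported
in million years. The formula is deliberately the exact inverse of the
simulator's divergence targeting (below), making dating a true round trip.

Selection classes partition on the ratio: > 1 positive, < 1 purifying,
equal to 1 (within a 1e-9 tolerance) neutral; undefined ratios are
"undetermined".

## Phylogeny

Pairwise protein **p-distances** (mismatched / gap-free columns of global
alignments) feed **neighbor joining**. Replacing a progressive multiple
alignment with pairwise distances is a deliberate simplification: NJ
consumes only the distance matrix, and pairwise distances keep the stage
exactly testable (NJ is provably exact on additive matrices, which the
suite verifies on 4–8-taxon tree metrics; topologies are also
cross-checked against an independent NJ implementation). The distance
model is p-distance by default — a Poisson-type correction would be a
one-line change but is not the default because at within-family
divergences the difference is negligible relative to topology stability.

Determinism rules: labels are sorted before any computation; Q-criterion
ties break to the smallest (i, j) under sorted-label order; negative limb
estimates are clamped to zero and counted in `attr(tree, "clamped")`.

**Bootstrap** resampling under pairwise distances has no shared column
set, so each replicate resamples every pair's own alignment columns with
replacement, with the RNG stream keyed to (seed, replicate, sorted pair
labels). Supports are therefore invariant to input order and exactly
reproducible. Support is the fraction of replicate trees containing each
internal bipartition. This per-pair scheme preserves the marginal
distribution of each distance but not the across-pair correlation a
shared-column bootstrap would give; supports on very short internal edges
are accordingly conservative.

Subfamily labels propagate from anchor leaves (reference proteins of
known subfamily): each unlabeled leaf takes the subfamily of the smallest
clade containing it whose anchors are unanimous; leaves whose nearest
anchored clade is mixed are reported "unassigned" with a warning, never
guessed.

## Promoter censuses and expression statistics

Cis-elements are scanned as IUPAC consensus strings from a curated,
editable dictionary (`inst/extdata/motif_dictionary.tsv`) covering the
classic development / hormone / stress elements (Skn-1, GCN4, CAT-box,
CCGTCC-box, circadian, CGTCA, TGACG, GARE, P-box, ABRE, motif IIb, CE1,
TCA, TGA-element, AuxRR-core, TGA-box, HSE, ARE, GC, LTR, Box-W1, WUN).
Matching is exact IUPAC matching on the forward strand of the supplied
promoter, overlaps included. CGTCA and TGACG are reverse complements of
one another but remain separate entries because MeJA-response censuses
conventionally report them separately. Proprietary scoring matrices of
web-based promoter scanners cannot be reproduced from consensus strings,
so absolute counts from such tools are not comparable; the package's
accuracy claims rest on planted-motif fixtures, which are recovered
exactly.

qRT-PCR analysis uses the standard single-reference-gene 2^−ΔΔCt
estimator: `ΔCt = Ct_target − Ct_reference` per replicate, ΔΔCt against
the control (0 h) time point, control fold ≡ 1. This estimator is implied
by, though not named in, "control defined as 1" normalization schemes.
Significance is a two-sided Welch t-test on replicate ΔCt values versus
control — chosen as the conservative default where the original software's
test is unnamed — with stars `**` for p < 0.01 and `*` for p < 0.05.
Fewer than two replicates per group yields a flagged, undefined p.

Expression heatmap ordering clusters genes with distance 1 − Pearson
correlation and average linkage (both config-exposed, since the
referenced web tool documents neither); rows are label-sorted first and
leaves are ordered tighter-cluster-first (ties to the smaller label), so
the output is invariant to input row order. Constant rows have undefined
correlation: they are flagged and placed last, outside the dendrogram.

## The synthetic-data engine

Every generator is seeded, deterministic, and returns a ground-truth
record consumed directly by tests.

* `simulate_cds`: ATG + GC-weighted sense codons + one stop; `n_codons`
  is the protein length, so the ORF is `3(n_codons + 1)` bp.
* `evolve_pair`: acceptance–rejection codon evolution — uniform
  single-base proposals accepted with probability 1 (synonymous), ω
  (nonsynonymous), 0 (stop-creating); start/stop codons are protected so
  copies stay valid ORFs. Each lineage runs until its accepted synonymous
  events reach `S_ancestor × target_ks/2`, so the pair's realized
  synonymous divergence approximates `target_ks`. This is an intentional
  approximation to a full codon rate matrix: it keeps realized ω directly
  interpretable (the suite verifies convergence to ω at 10,000 codons
  within ±0.03) without rate-matrix machinery. No indels, no among-site
  rate heterogeneity, no codon-usage realism beyond GC control — so
  passing recovery tests demonstrates correctness of the estimators under
  the model's own assumptions, not robustness to alignment error or rate
  variation in real data.
* `simulate_family`: sequential duplications at given times (Mya),
  cycling deterministically through live lineages; between events every
  lineage accrues `λ·Δt` synonymous events per synonymous site — exactly
  the inverse of `T = Ks/2λ`, so dating recovery is a round trip.
  `simulate_ortholog_sets` builds unrelated genes split at a species
  divergence for benchmarking reciprocal-best-hit calling.
* `plant_promoters`: uniform background, chance matches of the requested
  motifs destroyed by off-pattern point edits, instances planted at
  recorded non-overlapping positions, final sequence re-verified so the
  scan equals the planting table exactly.
* `simulate_ct`: `Ct_target = base − log2(fold) + ε`,
  `Ct_ref = base_ref + ε`, Gaussian ε with sd `sigma` (default study
  shape: three replicates, σ ≈ 0.1 Ct — a typical technical-replicate
  spread).

## Study constants and problem sizes

All study constants live in `pipeline_config()` — λ = 6.5e-9, 150/9 bp
windows, > 300 bp aligned-length floor, ≥ 40% paralog identity, 1,000
bootstrap replicates, 2,000 bp promoters — and are never hard-coded in a
stage. The statistical suites run at the sizes the recovery claims are
stated for: ω ∈ {0.1, 0.3, 1.0} at 3,000 codons × 20 replicates, dating
round trips on 3,000-codon families, 20-vs-20 ortholog sets near
Ks ≈ 0.3, 17-promoter planting fixtures, 50-fixture qPCR recovery and
500-test null calibration. Unit tests use smaller instances of the same
generators; bootstrap unit tests use tens of replicates since support
*reproducibility* (not support magnitude) is what they assert. The
false-star rate under the null is judged by an exact binomial test
against the nominal 5% level rather than a hard cutoff, which is the
correct reading of a Type-I-error calibration for a finite sample.

## Known limitations

* Domain patterns are surrogates for profile HMMs; borderline family
  members can differ from HMM-based calls.
* NG86 with equal pathway weighting and JC correction ignores
  transition/transversion bias and codon-frequency effects; published
  per-pair values computed by other implementations can differ at the
  third decimal even on identical inputs (alignment trimming,
  gap/ambiguity conventions). The `compare_kaks_table()` checker exists
  for exactly this comparison when the original sequences are available,
  with a |Δ| ≤ 0.01 agreement band.
* The bootstrap's per-pair resampling is conservative on short internal
  edges (see above).
* Promoter scanning is forward-strand, exact-consensus only; no PWM
  scores, no de-novo discovery.
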