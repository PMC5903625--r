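---
title: "Taxon-stratified functional profiling of gut metatranscriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Taxon-stratified functional profiling of gut metatranscriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtxprof)
```

## The analysis problem

`mtxprof` analyses community mRNA (metatranscriptome) profiles from
diet-intervention studies of the gut microbiota. The motivating setting is a
2x2 mouse design crossing dietary protein (NP normal, HP high) with fat
(LF low, HF high), with caecal read data assembled upstream into contigs
carrying predicted protein-coding ORFs. The package takes over from there:

1. **Quantification.** The expression level of each ORF in each sample is
   the total number of aligned nucleotides falling inside the ORF interval,
   summed over reads (`count_aligned_nucleotides()`). Counts are then
   normalized by each sample's total ORF-mapped nucleotides
   (`normalize_per_sample()`), so every sample becomes a composition summing
   to 1. No gene-length correction is applied by default: the stated
   normalization rule is by sample total only, so longer genes legitimately
   carry more weight. An optional per-kilobase mode exists for users who
   want the alternative convention.
2. **Annotation.** Each ORF receives the taxonomic family of its best
   protein hit (highest bit score; ties broken by ascending e-value, then
   lexicographic subject id — a total order, so the result cannot depend on
   input row order) and at most one KEGG orthology (KO) identifier.
3. **Profiling.** Normalized activity is aggregated to KO, family, and
   function-category level (peptidases, amino-acid metabolism, amino-acid
   transporters, SCFA production pathways), optionally stratified by family.
4. **Inference.** Per-KO Welch t-tests between protein levels feed a
   hypergeometric KEGG-module enrichment; caecal SCFA concentrations are
   compared by pairwise t-tests; category activity by exact Wilcoxon tests;
   samples are ordinated by Pearson-distance/Ward clustering and redundancy
   analysis (RDA) with a Monte Carlo permutation test.

## Counting conventions

Coordinates are 0-based half-open internally; GFF3 I/O converts to and from
the 1-based inclusive convention. Only aligned (match/mismatch) CIGAR
operations contribute nucleotides — insertions, clips, reference skips and
deletions contribute nothing. Strand is ignored (double-stranded cDNA from
random hexamers is unstranded). A read overlapping two ORFs contributes its
overlap to each; multi-mapped reads are counted where reported, with no
fractional splitting — the simplest auditable rule given that no
multi-mapping policy is stated for the original protocol. Alignments to
contigs absent from the catalog accumulate in a logged `unassigned` bucket
rather than raising an error, because a stray reference name should not
abort a multi-hour run.

## Module enrichment as a hypergeometric tail

For a direction (say HP), the KOs individually significant at
`alpha = 0.05` (two-sided Welch t-test on normalized activity; raw
p-values, mirroring the reported raw P < 0.05 convention, with
Benjamini–Hochberg available behind a flag) form a significant set of size
$s$ inside the universe of $N$ *detected* KOs (nonzero activity in at least
one sample; undetected KOs cannot be "found", so they are excluded from
both the universe and the module size). For a module with $n$ detected
members of which $k$ are significant, the enrichment "likelihood" is the
upper hypergeometric tail

$$p = \sum_{j \ge k} \frac{\binom{s}{j}\binom{N-s}{n-j}}{\binom{N}{n}},$$

the standard formalization of "$k$ of $n$ module members were found
significant". A binomial approximation is available as an option. Both the
full module size and the detected count are reported, since "number of KOs
in a module" is ambiguous between the two. NP-enriched and HP-enriched
analyses run separately on the corresponding significant sets, producing
the two blocks of the enrichment table.

**A calibration caveat that is structural, not a bug.** Realistic KEGG
modules are small (3–10 KOs here). With a universe of ~200 detected KOs
and ~5% KO-level significance, a module's expected significant-member
count is below 1, and the discrete tail's attainable p-values jump from
roughly 0.1 straight past 0.05 down to ~0.01. The test is therefore
conservative at conventional thresholds: its null rejection rate at
`alpha = 0.05` (computed by the acceptance suite over thousands of null
simulations) sits near 0.01, not 0.05. This is an intrinsic property of
one-sided exact tests on small discrete counts; power against real planted
effects remains excellent (see the recovery results the acceptance script
computes), but users should read module p-values as conservative.

## The synthetic community generator

The generator exists so every downstream statistic can be validated against
a known ground truth (`community_truth`). Its defaults encode the study
conditions the pipeline targets:

* **Design.** Four diets x 4 replicates by default; a
  `c(NPLF = 3, NPHF = 4, HPLF = 4, HPHF = 4)` subset mirrors the
  three-mice-NPLF metatranscriptome sampling, while SCFA panels use the
  full study of 10 mice per diet. Mouse weights are drawn around
  diet-specific means (heavier under high fat; SD 2 g).
* **Community.** Six families; under NP the composition is dominated by
  *Lachnospiraceae* (0.40) with *Erysipelotrichaceae* at 0.10; under HP
  *Erysipelotrichaceae* rises to 0.25 and *Lachnospiraceae* falls to 0.25.
  Directions follow the reported community shifts; the magnitudes are
  synthetic conventions chosen once for desk-scale statistical power, as no
  quantitative effect sizes are published for them.
* **Planted modules.** Three sugar-metabolism modules (M00377, M00422,
  M00196) are expressed 4-fold higher under NP; three protein-metabolism
  modules (M00018, M00299, M00236) 4-fold higher under HP. Module sizes
  mirror their KEGG counterparts; the member KO ids are synthetic
  placeholders (K75xxx) because no module membership list is published,
  while the SCFA pathway KOs are the real identifiers.
* **SCFA panel.** Per-acid, per-diet means in μmol/g with truncated
  Gaussian noise (negative draws rejected and redrawn); branched acids
  (iso-butyrate, iso-valerate) and valerate are elevated under HP, with
  SDs large enough that only some contrasts reach significance — matching
  the qualitative pattern of high inter-mouse variation.

### The template-repertoire design

Every family carries the *same* gene template: one ORF per KO in the pool
plus unannotated background ORFs, with ORF lengths drawn once and shared
across families. Families differ only in their overall activity fraction.
Two useful properties follow analytically:

* KO-level activity totals are invariant to community-composition shifts
  (the family fractions sum to 1 within each sample), so composition
  changes do not masquerade as functional changes.
* Planted module folds are applied *budget-preservingly*: within each
  family, the unannotated background ORFs are scaled down so the family's
  total expected activity is unchanged. Consequently a planted fold of 4
  produces an exactly 4-fold ratio of normalized module activity between
  protein levels at zero dispersion — the recovery tests can assert
  exactness rather than approximation. The generator refuses configurations
  whose background mass cannot absorb the folds (raise the background ORF
  count or lower the fold).

This symmetry is deliberately idealized. Real communities have
family-specific gene repertoires, so real taxonomic shifts *do* move
KO-level totals; passing recovery tests on the template design shows the
statistics recover what was planted, not that real data are this clean.
Other realism gaps: uniform random contig sequence (no codon structure —
sequence content is never interrogated), no sequencing-error or quality
model, no rRNA contamination, one ORF per contig.

### Noise model

Expected ORF activity is
`family_fraction(family, diet) x within_family_share(orf, protein_level)`.
A per-ORF, per-sample multiplicative log-normal factor with log-SD equal to
`dispersion` perturbs the expected activities, and the sample's depth
(total aligned nucleotides; default 10^6, desk scale) is then allocated in
a single multinomial draw. This gives overdispersed compositional counts
from one interpretable parameter, exact column sums, and a closed-form
expectation at zero dispersion. At moderate dispersion the mean count is
within O(CV²/n) of `depth x p`, which the Monte-Carlo suite verifies.
Alignment records are then emitted so that re-counting reproduces the
simulated matrix exactly (reads placed fully inside ORFs; an optional
boundary-read mode shifts a fraction of reads across ORF edges for
stress-testing the overlap arithmetic).

## Multivariate choices

* **Clustering** uses `d = 1 - r` (Pearson) between sample columns of the
  log10-transformed matrix and Ward linkage in the `ward.D2` convention —
  the Lance–Williams update applied to squared input dissimilarities. The
  named method is just "Ward"; `ward.D2` is chosen and documented because
  it treats the supplied (non-Euclidean) distances deterministically and
  matches the greedy objective-recomputation oracle the tests use.
* **Log10 pseudocount** defaults to half the smallest nonzero entry —
  scale-aware, avoiding an arbitrary +1 on fractional abundances. A zero
  entry with a zero pseudocount is an error, never silently -Inf.
* **RDA** centers the response per feature, projects onto the centered
  explanatory columns (QR), and takes the SVD of the fitted values;
  the constrained fraction is fitted-SS over total-SS and per-axis
  fractions are squared singular values over total SS. Nominal variables
  enter as one-hot indicators with the first level dropped; continuous
  covariates are standardized. Collinear columns are dropped with a
  warning; at rank ≥ n−1 the fraction saturates at 1 and says so. The
  in-package implementation is cross-checked in the test suite against
  both a direct regression + eigendecomposition oracle and `vegan::rda`.
* **Permutation test**: rows of the explanatory table are permuted jointly,
  default 999 permutations, add-one p-value
  `(1 + #{permuted ≥ observed}) / (1 + n)` so p can never be zero.
* **Species filter**: features whose variance captured by the first two
  canonical axes is ≥ 50% of their total variance are retained for biplot
  display, reproducing the usual decluttering rule.
* **iPath widths** are `log10(1 + c)` of KO read counts summed within a
  diet group (per-group is the default; per-sample widths are obtained by
  passing a single sample id). The `+1` handles zero counts, which are
  omitted from the selection file anyway.

## Small-sample testing conventions

Wilcoxon category tests use exact enumeration for group sizes up to 8
(continuous activities rarely tie) and the normal approximation beyond.
t-tests are Welch, two-sided throughout: the pooled-versus-Welch choice is
not documented for the original analysis, and Welch is the safer default.
A KO or acid with zero variance and equal means in both groups is reported
with p = 1 and flagged degenerate rather than erroring.

The K01895 (acetyl-CoA synthetase) membership in *both* the acetate and
propionate pathway KO sets is preserved exactly as published; pathway
activities are therefore not a partition and may double-count that enzyme.
`split_k01895 = TRUE` reassigns it to acetate only for users who prefer
disjoint sets.

## Problem sizes used by the validation suite

The bundled configuration simulates 6 families x 320 template ORFs
(1,920 ORFs, 200-KO universe) at 2x10^5 nucleotides per sample — small
enough that the full pipeline, the 3,000-dataset null calibration, the
200-simulation recovery study and the 500-dataset RDA calibration all run
comfortably on a laptop, while deep enough that counting noise is
negligible next to the planted biology. These sizes are package choices;
all of them scale up through configuration.

## Known limitations

* The generator's template symmetry (above) makes family-stratified
  recovery easier than on real data.
* Module enrichment p-values are conservative for small modules (see the
  discreteness discussion).
* RDA biplot scaling conventions of commercial ordination software are not
  reproduced; scores are reported in the natural SVD scaling.
* MITChip-style probe matrices are accepted wherever an abundance matrix is
  (clustering, RDA) but probe-level signal extraction is out of scope.
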