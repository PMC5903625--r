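# mtxprof — taxon-stratified functional profiling of gut metatranscriptomes

`mtxprof` is an R package for analysing microbial community mRNA
(metatranscriptome) profiles from diet-intervention studies, built around a
2×2 mouse design crossing dietary protein (NP/HP) with fat (LF/HF). It is
aimed at microbiome researchers who have assembled contigs with predicted
ORFs, read alignments, protein best-hit tables and KO annotations, and want
a tested, reproducible route from those inputs to diet-contrast statistics.

The pipeline implements:

* **Aligned-nucleotide ORF quantification** — expression of ORF *o* in
  sample *s* is the total number of aligned bases overlapping the ORF
  interval, followed by per-sample normalization
  `x(o,s) / Σ_o x(o,s)` (each sample becomes a composition summing to 1).
* **Best-hit family taxonomy** — each ORF takes the family of its
  highest-bit-score protein hit (ties: ascending e-value, then subject id).
* **Family-stratified functional profiles** — peptidases, amino-acid
  metabolism, amino-acid transporters, and the acetate / propionate /
  butyrate production pathways (KO sets K00925, K00625, K01895, K13788 /
  K01895, K01026 / K01034, K01035, K01896, K00929, K00634), with per-diet
  means and SDs, plus iPath-style `log10(1 + count)` width exports.
* **KEGG-module enrichment** — per-KO Welch t-tests between protein levels
  at P < 0.05; per module, the upper hypergeometric tail of observing ≥ k
  significant members among its n detected KOs in the detected-KO universe,
  run separately for NP- and HP-enriched directions.
* **SCFA statistics** — pairwise t-tests of caecal acid concentrations
  (μmol/g) at matched fat level, and exact Wilcoxon tests on category
  activity.
* **Multivariate analysis** — log10 transform with a scale-aware
  pseudocount, Pearson-distance/Ward (`ward.D2`) sample clustering with
  Newick export, and redundancy analysis (RDA: center → project onto
  explanatory variables → SVD of fitted values) with a Monte-Carlo
  permutation test and the ≥50 %-variance-on-axes-1–2 species filter.
* **A synthetic-community generator** with planted ground truth — a
  family-structured community (Erysipelotrichaceae up, Lachnospiraceae down
  under HP), 4-fold diet-responsive modules, and SCFA panels with elevated
  branched acids under HP — used by the test suite to verify that every
  statistic recovers what was planted.

See `vignettes/metatranscriptome-profiling.Rmd` for the model details and
design decisions.

## Worked example

Run the bundled synthetic study (15 metatranscriptome samples, 1,920 ORFs,
200 KOs, planted 4-fold module effects) end to end:

```r
library(mtxprof)
cfg <- validate_config(system.file("extdata", "synthetic_config.yaml",
                                   package = "mtxprof"))
cfg$output_dir <- "demo_out"
run_pipeline(cfg)

enr <- read.delim("demo_out/module_enrichment.tsv")
enr[enr$significant, c("module_id", "n_detected", "k_significant",
                       "p_enrichment", "direction")]
#>   module_id n_detected k_significant p_enrichment direction
#> 1    M00377         10            10     2.88e-11        NP
#> 2    M00422          5             5     1.04e-05        NP
#> 3    M00196          4             4     1.13e-04        NP
#> 7    M00018         10            10     1.57e-11        HP
#> 8    M00299          4             4     9.25e-05        HP
#> 9    M00236          3             3     1.01e-03        HP
```

All six planted modules are recovered in the correct direction block:
the three sugar-metabolism modules as NP-enriched, the three
protein-metabolism modules as HP-enriched, each with all detected member
KOs individually significant (`k_significant == n_detected`) and
correspondingly small hypergeometric tail probabilities.

```r
scfa <- read.delim("demo_out/scfa_tests.tsv")
subset(scfa, significant & acid == "iso-butyrate")
#>            acid diet_a diet_b mean_a mean_b  p_value
#> 5  iso-butyrate   NPLF   HPLF  0.287  0.632 1.91e-06
#> 11 iso-butyrate   NPHF   HPHF  0.232  0.629 1.71e-06

read.delim("demo_out/rda_summary.tsv")[1:3, ]
#>          axis fraction
#> 1 constrained   0.9724
#> 2        RDA1   0.9060
#> 3        RDA2   0.0105
```

The branched-chain acid iso-butyrate — a marker of protein fermentation —
is significantly elevated in the high-protein groups at both fat levels,
and the explanatory variables (diet, weight, six acids) account for 97 %
of the variance in the log-activity matrix, with the protein contrast
dominating the first canonical axis. The output directory also contains the
normalized matrices, KO differential table, family and stratified category
profiles, SCFA pathway profile with per-diet SDs, iPath selection files,
the Ward tree (`clustering.nwk`) and the RDA score triptych.

A thin command-line front end with the verbs `simulate`, `quantify`,
`annotate`, `diff`, `strata`, `ordinate` and `run-all` ships at
`inst/cli/mtxprof.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mtxprof.R", package="mtxprof"))')" \
    run-all --config config.yaml --out out_dir --seed 1
```

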