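---
title: "Developmental methylome and expression-divergence analysis with methdev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developmental methylome and expression-divergence analysis with methdev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis

`methdev` implements a comparative epigenomic/transcriptomic workflow for two
related fungal species sampled at three developmental stages — mycelium (MY),
primordium (PR) and fruit body (FB). Fungal CG methylomes are strongly
bimodal: most cytosines in CG context carry little or no methylation, while a
minority — concentrated in transposable elements (TEs) and TE-rich intergenic
space — is heavily methylated. The workflow asks how this landscape changes
across fruit-body development, and how methylation relates to gene and TE
expression and to interspecific expression divergence of 1:1 orthologs.

The pipeline stages are:

1. **mCG calling.** At each CG site with depth ≥ 5, methylated read counts are
   tested against the bisulfite non-conversion background (0.3%, measured from
   unmethylated lambda DNA in the underlying assay design) with a one-sided
   binomial test, `P(X >= k)` for `X ~ Binomial(n, 0.003)`. P-values are
   Benjamini–Hochberg adjusted per sample; a site is an mCG when `q < 0.01`
   and its raw level exceeds 5%.
2. **DMR detection.** 1 kb windows at 200 bp steps; a window enters testing
   only when it carries ≥ 10 mCGs in at least one of the two stages of a
   transition. The test is Fisher's exact test on the pooled
   methylated/unmethylated read counts of all covered CG sites in the window
   ("reads as the counting agent", not averaged site levels), BH-adjusted over
   eligible windows. Windows with `q < 0.01` and a pooled level change
   `|Δ| ≥ 0.15` are hyper (higher in the later stage) or hypo; overlapping
   same-direction windows merge into maximal DMRs. Book-ended windows do not
   merge.
3. **Methylated promoters and gene bodies.** A promoter (1 kb upstream of the
   TSS, strand-aware) or a gene body qualifies as methylated (MP/MGB) at
   ≥ 10 mCG/kb in at least one stage; qualifying regions are re-tested between
   stages with the same Fisher/BH/Δ machinery, with the region as the unit.
4. **Expression.** TPM quantification; "expressed" means replicate-mean
   TPM > 1 in at least one stage; differential expression per transition by a
   built-in negative-binomial Wald test (below); DEGs at `q < 0.01` and
   `|log2FC| > 1`.
5. **Ortholog divergence.** Pairs pass the alignment filter at consensus
   fraction > 70% and consensus length > 300 bp (strict inequalities). For
   each phase (phase 1 = MY→PR, phase 2 = PR→FB), the two species' DE
   statuses map onto five classes: DE0, DE1-Pt, DE1-Pe, DE2-identical,
   DE2-opposite. The mapping is total: every status pair lands in exactly one
   class, so class counts always sum to the number of pairs.
6. **Inferential statistics.** Hypergeometric over-representation of GO terms
   (BH; enriched at `q < 0.05` with ≥ 5 overlapping genes), Games–Howell
   post-hoc comparisons (Welch t with Welch–Satterthwaite df referred to the
   studentized range), Mann–Whitney tests, two-sided exact binomial
   comparison of two counts, and Pearson correlation tests.

## The built-in study generator

Every stage can be exercised without external data through `sim_config()` /
`simulate_study()`, which emulate the statistical structure the analysis
assumes and emit complete ground-truth tables.

```{r}
library(methdev)
run <- run_pipeline(pipeline_config(out_dir = "methdev-run", seed = 1))
```

**Methylome.** CpG sites are laid down at ~25 bp mean spacing (fungal genomes
are CpG-dense). Each site draws a latent methylation level from a
two-component Beta mixture. The component centres default to 0.02 and 0.90
with concentration 50; the concentration was fixed once so that each
component keeps essentially all of its mass on its own side of the 10%
boundary used by bimodality summaries (the low component leaks ~0.6% above
it) while still producing realistic scatter for threshold tests. The
low-component weight depends on the feature kind at the site — 0.97 in genic
space (gene ± 1 kb), 0.30 in intergenic space and, on average, 0.30 in TEs.
Two mechanisms create the TE-centred geography the analysis studies:

* **Element heterogeneity.** Each TE draws its own low-component weight from
  a Beta distribution centred on the configured mean (concentration 2), so
  some elements are nearly fully methylated and others barely — the spread a
  repeat landscape of old and young elements shows. Without it, per-element
  mean levels cluster so tightly that level–expression correlations are
  undetectable at desk scale.
* **Spreading.** For non-TE sites the high-component probability gains
  `0.55 * exp(-d/600bp)` with `d` the distance to the nearest TE, emulating
  methylation spreading out of elements into flanks and promoters.

Observed counts are `Binomial(depth, level*(1-ε) + (1-level)*ε)` at depth
`1 + Poisson(19)` per stage (mean 20×, within the 5–30× range of the assay),
with ε = 0.003 the non-conversion rate. Latent levels are shared across
stages; planted DMRs shift the later stage of one transition by ±0.30 inside
recorded 2 kb intervals (direction chosen by the local latent mean, so hyper
DMRs land in lowly methylated ground and hypo DMRs in highly methylated
ground; levels are clamped to [0,1] with a warning where a shift overshoots).

**Expression.** Orthologs share log-normal baseline means (meanlog log(200),
sdlog 0.8). Divergence classes are planted per phase with |log2 shift| = 2:
DE1 shifts one species, DE2-identical both with one random sign,
DE2-opposite both with opposite signs. Counts are negative binomial
(dispersion 0.05) for three replicates per species and stage, with mild
log-normal library-size factors so the median-of-ratios normalisation is
exercised. The default genome hosts 150 genes and 150 TEs per species on two
400 kb chromosomes — sizes chosen so that window, tertile and correlation
analyses all have non-trivial sample sizes while a full run stays in tens of
seconds.

**Repressive coupling.** When methylomes are supplied, a gene's expression
mean is multiplied by `exp(-2.5 * (promoter level + 0.5 * body level))` and a
TE's by `exp(-2.5 * element level)`, implementing the repressive role of DNA
methylation the analysis is designed to detect: it produces the negative
TE methylation–expression correlation, the decrease of promoter methylation
across expression tertiles, and — through spreading — the ordering of
promoter-to-TE distances by methylation class.

**What the generator does not emulate:** sequence content (CpG positions are
positional only), read-level artefacts (mapping bias, duplicates, M-bias),
TE nesting and fragmentation, CHG/CHH methylation, isoform structure, and
biological WGBS replicates (one methylome per species × stage, mirroring a
design where only RNA-seq is replicated). Passing tests therefore demonstrate
the statistical machinery — calibration, recovery, thresholds, plumbing — not
robustness to alignment-level artefacts of real libraries.

## The negative-binomial Wald test

The differential-expression stage is self-contained: median-of-ratios size
factors (computed on features with all-positive counts), per-feature
method-of-moments dispersion from the pooled within-group variances, a Wald
test on `log2((mu_B + 0.5)/(mu_A + 0.5))` (the 0.5 pseudocount keeps the
statistic defined and label-symmetric for features with an empty side), and
BH adjustment over tested features. Features with zero counts everywhere are
untested.

With three replicates per side, the raw moment estimate of the dispersion is
extremely noisy, and its downward errors inflate Wald statistics enough to
destroy type-I control. The dispersion actually used is therefore the
maximum of the per-feature moment estimate, a 10%-trimmed ensemble mean of
all features' estimates, and a floor of 0.01. This deliberately sacrifices a
little power for features with genuinely low dispersion in exchange for
calibration at small n — at the generator's effect sizes the power cost is
negligible (the test suite checks both the null false-positive fraction and
the power on planted 8-fold changes). DESeq2, where installed, is used in
the test suite as an independent cross-check of the fold-change estimates,
never as the implementation. A precomputed external DE table can be used in
place of `de_test()` by supplying any tibble with `feature_id`, `log2fc`,
`qvalue`, `status` to `ortholog_divergence()`.

## Conventions and numerical choices

* **Coordinates** are 0-based half-open everywhere inside the package; GFF3
  is converted at the boundary, BED is native. CG sites are kept per strand;
  `read_cytosine_report(merge_symmetric_cpg = TRUE)` pools the two strands of
  a CpG dyad instead (off by default, since the pooling choice is an analysis
  decision the caller should make consciously).
* **Thresholds** follow the study design throughout and are strict
  inequalities where stated: mCG `q < 0.01` and level `> 0.05`; depth
  `>= 5`; DMR `q < 0.01`, `|Δ| >= 0.15`; ortholog consensus `> 0.70` and
  `> 300 bp`; expressed `TPM > 1`.
* **BH scope:** per sample for mCG calling; per transition over eligible
  windows for DMRs; over tested features for DE; over tested terms for
  enrichment.
* **Eligibility vs testing:** the ≥ 10 mCG window filter counts called mCGs,
  but the Fisher table pools reads of *all* covered CG sites — the filter
  and the test are deliberately decoupled. For MPs/MGBs the eligibility is
  the density form (≥ 10 mCG/kb), reusing the MP/MGB definition.
* **Site-to-feature precedence** when features overlap:
  exon > intron > promoter > downstream-1kb > TE > intergenic, so category
  counts always partition the sites. The gene-centric ordering reflects that
  the per-category accounting is a genic summary; TE-level analyses use the
  TE annotation directly instead.
* **Tertiles and ties.** Expression and promoter-methylation tertiles are cut
  on ranks with deterministic tie-breaking by gene id, giving classes of
  equal size ±1 even under heavy ties.
* **TE-distance ordering.** Promoter classes are compared on mean distance to
  the nearest TE: at desk scale the most methylated promoter classes overlap
  TEs outright, so medians tie at zero and the mean is the informative
  statistic; the `medium`/`high` comparison is treated as non-strict for the
  same reason.
* **Degenerate inputs.** Zero-variance correlations, all-zero TPM columns,
  zero-margin Fisher tables and empty eligible-window sets all return
  `NA`/empty results with a warning rather than failing.
* **Determinism.** One global seed fans out to fixed per-stage child seeds
  (`derive_seed()`), so any stage can be re-run in isolation and a full rerun
  is byte-identical; the run manifest records every threshold and output
  checksum.

## Problem sizes used by the checks

The packaged checks run the caller on pure-null methylomes of 10⁵ sites over
20 seeds, recover planted DMRs over 10 seeds (two transitions each), verify
the latent mixture weight on a 5×10⁴-site genome, classify divergence over
10 simulated studies, measure DE calibration on 10 × 5 000 null features and
power on 20 × 100 planted 8-fold changes, and run the full pipeline twice to
confirm checksum-identical reruns. These sizes are the package's choice of a
desk-scale study: large enough for the binomial/Fisher/BH asymptotics and
tight acceptance bands, small enough to iterate on comfortably.

## Limitations

The DMR caller is the windowed Fisher design it implements — no smoothing,
no HMM, no replicate-aware dispersion for WGBS (the emulated design has
none). The NB test has no Cook's-distance outlier handling or shrunken fold
changes. GO enrichment is a flat over-representation test; term ancestry is
whatever the supplied gene–term map encodes, and the universe defaults to
the expressed ortholog set of the comparison but should be chosen by the
analyst. Headline counts from any real study of this design depend on
genome assembly and annotation versions; the package's claims are about the
method's behaviour under known ground truth, not about reproducing any
particular organism's numbers.
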