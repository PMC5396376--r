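---
title: "Methods: tile-based methylation, motif enrichment and panel qPCR analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tile-based methylation, motif enrichment and panel qPCR analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exitkit)
```

This vignette documents the statistical procedures implemented in `exitkit`,
the defaults they ship with, and the deliberate numerical choices behind them.
Every stage can be exercised on synthetic data with exported ground truth, so
the examples below are fully reproducible offline.

## 1. Differential methylation from CpG coverage

### Model and procedure

The unit of analysis is the CpG record: chromosome, 0-based position of the C,
methylated and unmethylated read counts, and a sample id. Analysis proceeds in
five stages:

1. **Depth filtering** (`filter_cpgs()`): records with coverage below
   `min_depth = 5` are removed, then — per sample — records whose coverage lies
   *strictly above* the `1 - 0.001` empirical quantile (type 7) of the
   remaining coverages are removed. The per-sample top-coverage cut discards
   PCR-duplicated or repetitive outlier sites; it is applied per sample because
   library complexity differs between samples, and a pooled cut would let a
   deep library's routine coverage purge a shallow one.
2. **Common-site intersection** (`intersect_common_cpgs()`): only sites covered
   in *every* sample enter the tile universe, so all downstream contrasts are
   computed on one shared support.
3. **Tiling** (`tile_methylation()`): the genome is cut into fixed, anchored,
   non-overlapping 400 bp windows (`[0, 400)`, `[400, 800)`, …). Tiles with
   fewer than 3 common CpGs are dropped. Tile methylation is
   **coverage-weighted**: pooled methylated reads over pooled total reads, not
   the mean of per-site percentages, so a 5x site cannot outvote a 50x site.
   Anchored non-overlapping tiles (rather than sliding windows) keep every tile
   statistically independent of its neighbours and make the tile universe a
   deterministic function of the site set.
4. **Pooling** (`pool_tiles()`): replicate counts are summed per tile within a
   condition/timepoint, keeping only tiles present in all selected samples.
5. **Calling** (`call_dmrs()`): each tile contributes a 2x2 table (methylated /
   unmethylated by group) to a two-sided Fisher exact test;
   Benjamini–Hochberg q-values are computed across all tested tiles. A tile is
   a DMR when `|difference| > 20` percentage points **and** `q < 0.05`
   (strict inequalities).

`classify_temporal()` relabels a two-timepoint DMR run as gain / loss / stable,
and `maintained_acquisition()` flags tiles that gained methylation early but
dropped by more than the threshold later.

### Numerical choices

- The two-sided Fisher p-value uses the **minimum-likelihood definition**: the
  sum of hypergeometric probabilities no greater than the observed one, with a
  `1 + 1e-7` relative tolerance on the tie comparison. This is the same
  convention as `stats::fisher.test`, which serves as an independent oracle in
  the test suite (agreement to 1e-10 over every 2x2 table with margins up to
  60). One-sided p-values are exact hypergeometric tail sums via `phyper`.
- All quantiles anywhere in the package (coverage cut, LOD, permutation
  envelopes, delta summaries) are **type 7**, R's default, so results are
  reproducible from the documentation alone.
- Coordinates are 0-based half-open everywhere in memory; the 1-based bismark
  coverage dialect exists only at the I/O boundary (`read_bismark_cov()` /
  `write_bismark_cov()`).

### Recovery is defined on the tested universe

The depth and common-site filters remove sites *before* any testing: across 12
samples at a mean depth of 20, roughly a fifth of tiles lose their 3-CpG
minimum somewhere and never enter the tested universe. `dmr_recovery()`
therefore defines sensitivity over planted tiles **present in the tested
universe** and reports `n_untested` separately — a caller cannot recover what
it never tests, and hiding the dropout inside the sensitivity number would
conflate filter behaviour with caller behaviour.

### Worked example

```{r dmr}
sim <- sim_methylome(seed = 1)   # 2 conditions x 3 timepoints x 2 replicates
cp <- intersect_common_cpgs(filter_cpgs(sim$cpgs))
tiles <- tile_methylation(cp)
pool <- function(cond, tp) {
  ids <- sim$design$sample_id[sim$design$condition == cond &
                                sim$design$timepoint == tp]
  pool_tiles(tiles, ids)
}
dmrs <- call_dmrs(pool("Ctrl", 6), pool("KO", 6))
dmr_recovery(dmrs, sim$truth$planted_dmrs, status = "hypo")
```

## 2. Genomic-region classes and metagene profiles

`annotate_tiles()` assigns each tile to the first region class it overlaps (at
least one bp) in a fixed precedence order — CGI, canyon, HCP, LCP, enhancer,
TE, exon, intron, with `"other"` as fallback — so every tile gets exactly one
label. Promoters are split into high- and low-CpG classes by the CpG
observed/expected ratio `(N_CG * L) / (N_C * N_G)` with the boundary at 0.29;
the inequality is **strict**, so a promoter exactly at 0.29 is low-CpG. N bases
are excluded from all counts with the effective length reduced accordingly.
`metagene_profile()` length-normalises gene bodies into 40 bins with 20
fixed-width flank bins per side, flips minus-strand genes so bins run 5' to 3',
and reports coverage-weighted methylation per bin (`NA`, never zero, for empty
bins).

## 3. Bipartite motif enrichment

`scan_bipartite()` finds ordered pairs of IUPAC half-sites on the same strand
whose gap (end of the first to start of the second) satisfies
`0 <= gap <= max_gap` — half-sites never overlap. When the two motifs differ,
both orders are counted once each; minus-strand pairs are found on the reverse
complement and reported in plus-strand coordinates. Two published
parameterisations ship as presets (`motif_preset()`): `"methods"` (two
`YACCTG`, gap at most 40) and `"results-fig2d"` (`CACCTG` plus `CACCT`, gap at
most 45). They come from the same source material, which is internally
inconsistent about the definition, so both are provided and neither is
"corrected" toward the other.

Enrichment (`deg_motif_report()`) uses the **presence** of at least one
bipartite hit per promoter as the unit, not the hit count: hit counts within a
promoter are strongly dependent (one extra half-site occurrence manufactures
many pairs), while presence is a well-defined Bernoulli event per gene that
feeds a one-sided Fisher exact test against the genome-wide promoter
background. Upregulated promoters are tested for over-representation,
downregulated ones for under-representation, and the combined set for
over-representation.

```{r motif}
scan_bipartite("CACCTGAAAACACCTG")
```

## 4. Transcriptome utilities

- `counts_to_tpm()`: `count / length` rates scaled so each sample sums to 1e6.
- `filter_genes()` applies three sequential filters: drop short-noncoding
  biotypes; keep genes with at least 5 TPM in at least 3 samples (both
  boundaries inclusive); drop the `floor(0.2 * n)` remaining genes with the
  lowest standard deviation of `log2(tpm + 1)` (ties broken by gene id, so the
  result is deterministic).
- `deg_call()`: a gene is differential when `|log2FC| > 1` and `p < 0.01`,
  both strict.
- `pi_rank()`: `pi = -log10(q) * log2FC`, combining significance with signed
  effect size for preranked enrichment tools. log2 fold-change (not raw FC) is
  used so up- and downregulation are symmetric around zero; zero q-values are
  clamped to the smallest positive q so ranks are preserved without
  infinities.
- `deg_persistence()`: fraction of first-timepoint DEGs still called in the
  same direction later, plus a full fate partition
  (persisted / dropped / switched).
- `correlation_cluster()`: average-linkage clustering on `1 - Spearman`, with
  a deterministic leaf order (the subtree containing the smallest original
  item index goes left at every merge) so heatmap layouts are reproducible.

## 5. High-throughput qPCR panels

The pipeline (`qpcr_pipeline()`) chains four stages:

1. `filter_assays()`: wells with quality below 0.5 count as undetected; assays
   detected in fewer than half the samples are removed.
2. `remove_outlier_samples()`: each sample's aggregation score is the mean of
   `detected * quality` over assays; samples below `median - 3 * MAD` are
   removed (MAD with the consistency constant 1.4826, so `k = 3` is roughly a
   3-sigma rule).
3. `quantile_normalize_impute()`: classical quantile normalization — per
   sample, observed values are replaced by cross-sample rank means; tied raw
   values share the mean of their implicated rank means; samples with missing
   wells are normalized against the reference interpolated at their reduced
   rank grid. Missing cells are then imputed as the replicate-group mean of the
   assay's normalized values. Imputation runs **before** LOD scoring so that a
   well that simply dropped out inherits its replicates' signal; only cells
   missing in *all* replicates fall through to the LOD.
4. `lod_and_express()`: the limit of detection is the pooled 75% quantile
   (type 7) of all normalized Ct values plus 10 cycles; `log2_expr = LOD -
   ct_norm` and `abs_expr = 2^log2_expr`. The LOD is pooled rather than
   per-assay by default because panel assays share chemistry and cycle range,
   and a pooled LOD gives all assays one comparable expression origin
   (`per_assay = TRUE` is available).

Note that quantile normalization equalizes entire column distributions, so a
fold-change applied to *every* assay of a group is removed by construction;
planted per-assay differences are identified relative to the rest of the
panel.

```{r qpcr}
sim <- sim_ct_table(seed = 7)
res <- qpcr_pipeline(sim$ct, sim$replicate_groups)
res$outlier_samples
res$lod
```

## 6. Peak proximity at demethylated regions

`assign_peaks()` anchors each peak at its narrowPeak summit when present,
otherwise its midpoint, and assigns it to the region with the nearest midpoint
on the same chromosome (ties to the lower-coordinate region). Distances are
signed by genome coordinates (regions carry no strand).
`permutation_background()` re-places every anchor uniformly on its own
chromosome — preserving per-chromosome peak counts — `n_perm = 200` times, and
reports per-bin permutation means, a pointwise 95% envelope, and the
enrichment ratio `observed / max(mean, 1)` (the pseudo-count floor keeps
near-empty background bins from producing unstable ratios).

## 7. Synthetic generators and their scope

All generators are pure functions of their parameters and an explicit `seed`
(`withr::with_seed`; the caller's RNG state is untouched), and every one
exports its ground truth.

- `sim_methylome()`: coverage is truncated negative binomial (size 4, mean 20,
  minimum 1); methylated reads are Binomial at the latent per-tile methylation.
  Baselines are bimodal (60% Beta(1, 9) hypomethylated, 40% Beta(9, 1));
  CGI/canyon tiles resist gain. Both conditions gain +30 points at 35% of
  tiles between the first two timepoints; the gain is planted only at tiles
  hypomethylated enough for the full effect to manifest, honouring the
  invariant that planted effects must be realizable at least 5 points above
  the calling threshold. The knockout then loses 30 points at 100 tiles drawn
  from the gained set at the last timepoint. Ill-posed parameter choices warn;
  planted tiles that cannot reach the 3-CpG minimum are flagged
  unrecoverable.
- `sim_counts()`: two-group NB counts at known dispersion with planted log2
  fold-changes, plus a built-in exact NB comparison (edgeR at the known
  dispersion) standing in for an externally produced DE table — the DE model
  itself is out of scope; the package consumes contrast tables.
- `sim_ct_table()`, `sim_peaks()`, `sim_genome()`, `sim_annotation()`:
  analogous planted-truth generators for the remaining modules.

Not modelled: read-level data (no FASTQ), bisulfite conversion chemistry,
strand-resolved CpG asymmetry, linkage between modules beyond shared
coordinates.

## 8. Problem sizes used in validation

The shipped test suite validates, among others: the bipartite scanner against
a quadratic brute-force enumeration on 1,000 random 2 kb sequences (both
presets, exact hit-set equality); the exact tests against independent tail-sum
oracles over *every* 2x2 table with margins up to 60 (about 3.4 million
tables); DMR recovery across 5 generator seeds (sensitivity >= 0.9, empirical
FDR <= 0.1) and null calibration across 20 seeds; region annotation against an
all-pairs oracle on 10,000 tiles x 1,000 intervals; and the qPCR outlier rule
across 100 seeds. `scripts/acceptance.R` recomputes the headline quantities
for any seed and writes them as JSON.
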