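---
title: "Nominating transcriptional regulators of the DLAM state: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominating transcriptional regulators of the DLAM state: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlamreg)
```

## The problem

Microglia and peripheral macrophages in damaged, lipid-rich tissues converge
on a shared transcriptional activation state — the DLAM state, an umbrella
over what individual studies call disease-associated microglia (DAM),
lipid-associated macrophages (LAM) and TREM2-high plaque macrophages. The
effector genes of this state (lipid handling, lysosomal processing,
efferocytosis) are well catalogued; the transcription factors that drive it
are not. `dlamreg` implements a reusable, testable version of the
computational strategy used to nominate such regulators:

1. aggregate sparse single-cell profiles into **metacells**;
2. reconstruct TF-centric **gene regulatory networks** by mutual
   information with data-processing-inequality (DPI) pruning and bootstrap
   consolidation;
3. test each TF's **regulon** for over-representation of DLAM genesets and
   nominate TFs by a two-tier cross-species consensus;
4. locate **proxy-binding sites** (open-chromatin peaks containing the
   TF's sequence motif) near target promoters;
5. ask whether disease heritability concentrates in those sites
   (**stratified LD-score regression**);
6. compare perturbation signatures against DLAM signatures (**RRHO**,
   Spearman rank tests, preranked **GSEA**).

Real inputs for this workflow are controlled-access or archive-scale.
The package therefore ships synthetic-data generators with planted ground
truth; every stage has a parameter-recovery test, and the test suite runs
the whole pipeline end to end at a desk scale.

## Metacells

Counts are CPM-normalized; pairwise cell distance is `1 - r`, the Pearson
correlation distance, computed on `log2(CPM + 1)` (logging damps the
leverage of highly expressed genes; a raw-CPM mode exists via
`correlation_distance(log = FALSE)`). `sub_size` seed cells are drawn
without replacement and each is merged with its `num_neighbors - 1` nearest
cells — raw counts are summed, so a metacell's total equals its members'
library sizes; overlapping membership is allowed, matching the aggregation
semantics of the metacell routines used in single-cell regulatory-network
work. Neighbor ties are broken by cell ID so results are reproducible.
After re-normalization, genes detected in fewer than 75% of metacells are
dropped (`ceiling` rule: "at least 75%" reads conservatively as
`>= ceiling(0.75 * n)` columns).

Defaults (`num_neighbors = 10`, `sub_size = 200`) are deliberate desk-scale
settings exposed in the API; per-dataset values in real analyses are tuning
choices, not constants of the method.

## Mutual information networks

`estimate_mi()` is a rank-based adaptive-partitioning estimator: both
vectors are rank-transformed to (0, 1] and the unit square is recursively
split into four equal-area quadrants while the occupancy chi-square of the
four cells exceeds 7.815 (the 5% point of chi-square with 3 df) and the
parent holds at least `4 * min_leaf` points (`min_leaf = 8`), so children
hold at least `min_leaf` points on average. A literal per-child minimum
instead of the parent-size rule stops recursion exactly where dependence is
strongest and underestimates strong associations by a factor of ~0.65; the
parent-size rule reproduces the Gaussian closed form
`-0.5 * log(1 - rho^2)` within 0.1 nats at n = 5,000 across the tested
correlation range. MI is reported in nats. Rank ties are broken by adding
uniform jitter in (0, 1e-9) from the seeded stream before ranking, keeping
bootstrap resamples (which duplicate columns) well defined.

The edge threshold is calibrated by permutation: `mi_threshold()` draws
`n_null` null MI values from random gene pairs with one member permuted,
fits `log(tail probability)` linearly in MI over the largest null values,
and extrapolates to the target tail probability (1e-8 by default, mirroring
the conventional setting). At metacell sample sizes the null has a point
mass at exactly zero — more than 99% of permuted pairs never pass the first
chi-square split — so the fit uses the top `tail_frac` of draws restricted
to positive values; with fewer than 20 positive values the calibration
errors out rather than extrapolating from noise.

Candidate edges are all (regulator, gene) pairs at or above the threshold.
DPI then removes, within every triangle whose three edges are present, the
edge whose MI is below both others (evaluated against pre-pruning values;
a tolerance inflates the weaker edge before comparison). A TF–TF edge is
itself removable when the third vertex of its triangle is a regulator.

Networks are consolidated over bootstraps: columns are resampled with
replacement, a network is inferred per bootstrap at the fixed full-data
threshold (recomputing per bootstrap would make bootstraps incomparable),
and each unique edge's support count is tested against a Poisson null with
rate equal to the mean support over unique edges, Benjamini–Hochberg
corrected (retained at FDR < 0.05). Meta-networks pool bootstraps across
datasets and consolidate the pooled counts with the same procedure, so a
single-dataset meta-network is identical to that dataset's own
consolidation. Bootstrap b uses the derived substream seed
`seed + 1009 * (20 + b)`, making every stage reproducible bit for bit.

## Regulon enrichment and consensus nomination

A TF's regulon is its retained target set. Over-representation of a DLAM
geneset in a regulon is the upper-tail hypergeometric probability with the
**expressed-gene universe** — the genes surviving that network's metacell
filter. Using all annotated genes instead would inflate enrichment for any
regulon drawn from expressed genes and is rejected. FDR is computed across
TFs within each (network, geneset) stratum, matching the per-network
nomination semantics; a TF is nominated in a network only when it passes
FDR < 0.2 for **every** geneset tested there.

Consensus nomination is two-tiered, keyed through a 1:1 ortholog map
(many-to-many mappings are excluded — a TF without a one-to-one ortholog
cannot be called conserved): `replicated` requires nomination in at least
two networks of each species; `high_confidence` requires nomination in at
least half (ceiling) of each species' networks and, when an expressed-gene
list is supplied, presence in it. TFs with no retained regulon simply score
zero nominations rather than missing values.

## Cistrome analysis

Promoters are strand-independent TSS ± 2 kb windows (clipped at zero),
stored 0-based half-open. Motifs are probability matrices with a 1e-4
pseudocount applied on read; scanning scores every offset on both strands
with log2 odds against a background (uniform 0.25 by default), skipping
windows containing N. When a motif carries no threshold, 80% of its maximum
attainable score is used — per-motif thresholds of external scanners are
tool-specific and not portable. A proxy-binding site is a peak with at
least one hit anywhere in the peak (a flag restricts to promoter-overlapping
subregions if wanted); a gene is proxy-bound when its promoter overlaps a
proxy-binding peak by at least 1 bp (half-open, so touching an exclusive
boundary does not count). Position histograms map hit centers to offsets
from region centers in `window / bin` bins (2,000/20 = 100 by default).
Interval work is delegated to `GenomicRanges`.

## Partitioned heritability

`sim_gwas()` draws standardized Gaussian dosages with AR(1) correlation
inside LD blocks and independence across blocks. Each block's correlation
is drawn uniformly from `ld_rho = c(0.1, 0.95)` by default: real genomes
have strongly heterogeneous LD, and this heterogeneity is also what gives
LD-score regression between-block leverage — with a constant correlation
every block presents an identical LD-score profile and the base coefficient
is identified only from within-block contrasts whose residuals are highly
correlated, which makes the enrichment ratio estimator unstable at desk
scale. A scalar `ld_rho` reproduces the constant-correlation design.
Planted enrichment is defined on the estimand scale: per-SNP effect
variance inside the annotation equals `enrichment * h2 / M` (the fold over
the genome-average per-SNP heritability), so the stratified regression's
enrichment target equals the planted value; the generator errors if the
annotation would exceed total heritability. Chi-squares are squared t
statistics of the marginal phenotype-on-genotype regressions, and the
cohort matrix doubles as the LD reference panel.

LD scores use a base-pair window (default spanning one LD block; there is
no genetic map in the synthetic world) and the small-sample adjustment
`r2 - (1 - r2) / (n_panel - 2)`. The regression fits
`chi2 ~ N * sum_c tau_c * l(j, c) + intercept` by weighted least squares
with the two-step weighting of LD-score regression: a first pass weighted
`1 / max(l_base, 1)` (LD overcounting), then re-weighted by the inverse
squared predicted chi-square mean (heteroskedasticity), floored to keep
weights finite. Per-annotation heritability follows from the tau
coefficients; enrichment is the proportion of heritability over the
proportion of SNPs; uncertainty comes from a delete-a-block jackknife over
contiguous SNP blocks (20 at desk scale; the conventional 200 is a
parameter), with the enrichment p-value from the jackknife t statistic of
`prop_h2 - prop_snps`. Analyses of real summary statistics conventionally
exclude the APOE (chr19:45,000,000–45,800,000) and MHC/HLA
(chr6:28,477,797–33,448,354) regions; `filter_sumstats_regions()` applies
any such list before regression.

## Signature comparison

The ranking metric is `-log10(p) * sign(log2FC)` with p floored at 1e-300.
RRHO splits each ranked list at the metric's sign change; concordant
quadrants pair up-with-up and down-with-down sublists, discordant quadrants
pair opposites. Pixel (i, j) tests the overlap of the top `i * step` and
`j * step` prefixes by upper-tail hypergeometric probability against the
common-gene universe; the default step is
`max(1, ceiling(sqrt(min sublist length)))` and is recorded in the result.
BH adjustment spans all pixels of all four quadrants of one map. Pixels
carry `-log10(adjusted p)` signed by over- versus under-representation, and
the warmest pixel of each concordant quadrant is reported with its overlap
gene list. Venn-style overlap tests restricted to a fixed universe (for
example a published DLAM geneset) use `restricted_overlap_test()`.
Metric ties are broken by `|log2FC|` then gene ID, so maps are reproducible.

Preranked GSEA accumulates `|metric|^weight` at geneset hits (normalized to
sum to one) against a uniform miss decrement; the enrichment score is the
extreme running-sum deviation. The null draws random genesets of matching
size — the only permutation scheme available to preranked input — with
1,000 permutations by default; NES divides by the mean magnitude of
same-sign null scores, the nominal p is the same-sign tail fraction, and
the FDR q follows the standard same-sign pooled-null procedure. Genes
absent from a signature are dropped, never zero-imputed.

## The synthetic-data generators

`sim_scrna()` plants a DLAM-like state in `dlam_fraction` of cells. Every
TF carries a per-cell activity `a = N(0, activity_sd^2)` plus an
`effect_size` shift in its "on" cells — the shared DLAM cells for the
planted TFs, an independent random subset (`decoy_fraction = 0.25`) for
each decoy TF. Targets respond on the log scale through signed weights
with magnitude uniform in [0.5, 1.5]; signs alternate across each TF's
targets so that an activation state moves genes both up and down, as real
DLAM signatures do. Composition is hierarchical: each module (the planted
TFs with their 60 DLAM targets, each decoy TF with its 8-gene module, and
the background) owns a fixed share of the library proportional to its
genes' base rates, and activities redistribute mass only within the module.
This makes decoy modules exactly independent of the DLAM module in
composition — with a single global normalizer, the activated module's
mass shift leaks into every other gene's relative abundance and decoy TFs
acquire genuine (but unintended) dependence on DLAM genes. Counts are
negative binomial (`dispersion = 0.1`) around `libsize * proportion`, with
log-normal library sizes (median 5,000, sigma 0.3). Defaults:
`effect_size = 2.5` and `activity_sd = 1`, i.e. marker genes shift by
1.8–5.4 log2 units between states — the strong induction real DAM/LAM
markers show — over substantial cell-to-cell regulon-activity
heterogeneity; regulator base rates are drawn well-expressed
(log-normal around 3x the typical gene), since annotated-TF lists in
practice contain detectably expressed genes. `sim_scrna_panel()` draws one
topology and many independent count datasets across two species with
suffixed IDs and an identity ortholog map, so conservation logic is
testable with known truth.

What the generators do **not** emulate: ambient RNA, doublets, batch
effects, cell-type annotation errors, real LD maps, allele coding or
genotype discreteness, and geneset curation noise beyond random subsetting.
Passing tests therefore demonstrate algorithmic correctness and
recoverability under a clean generative model, not robustness to every
artifact of real data.

## Problem sizes and reproducibility

The test suite exercises the full pipeline at 2,000 cells x 500 genes x 30
TFs per dataset, six datasets per replicate, ten seed replicates with
50-bootstrap consolidation; heritability recovery uses 2,000 SNPs x 1,000
individuals over 50 replicates; RRHO and GSEA calibrations use 2,000-gene
signatures and 1,000-permutation nulls. These sizes were chosen so the
whole suite runs on a laptop in minutes while every recovery margin stays
wide. All randomness flows through explicit integer seeds; repeated runs
are bit-identical, including the command-line stages.

## Known limitations

- The MI threshold is an extrapolation four orders of magnitude beyond the
  empirical null tail; it is validated by the permuted-matrix zero-edge
  check, not by exactness.
- Poisson consolidation treats bootstrap supports as exchangeable across
  edges; strongly heterogeneous true-edge strengths make the null rate
  conservative for weak edges.
- The enrichment ratio of stratified LD-score regression is heavy-tailed
  whenever total-heritability estimates approach zero; at very small SNP
  counts single-replicate estimates should be read with their jackknife
  intervals.
- Mode of regulation (activation versus repression) and per-cell
  regulator-activity scoring are out of scope, as are peak calling, motif
  discovery and differential-expression model fitting.
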