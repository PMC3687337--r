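---
title: "Quantitative comparison of ChIP-Seq peak sets: model, assumptions and validation"
author: "peaknorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative comparison of ChIP-Seq peak sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peaknorm)
```

## The problem

Two ChIP-Seq experiments — say a histone mark profiled in wild-type and in
knockout cells — cannot be compared by raw read counts: sequencing depth,
immunoprecipitation efficiency and library complexity all differ between
samples, and the distortion is usually intensity-dependent rather than a
single global factor. `peaknorm` implements the M-A normalization strategy
for peak catalogs: at every peak region the pair of read densities is
summarized as

* `M = log2(density_KO / density_WT)` — the log fold difference, and
* `A = 0.5 * log2(density_KO * density_WT)` — the average log intensity,

and the systematic dependence of M on A is estimated and removed.

## Model and assumptions

The anchor set for normalization is the *common peaks*: regions called as a
peak in both samples. The key biological assumption is that most common
peaks represent binding determined by the same mechanism in both samples,
so their *true* intensities agree and any observed trend of M against A
over common peaks reflects only the technical scaling between libraries.
Under that assumption a straight line

```
M = b0 + b1 * A + error
```

fitted robustly over common peaks is the technical reference. Robustness
matters because a minority of common peaks are genuinely differential;
Huber iteratively-reweighted least squares (tuning constant 1.345, at most
50 iterations, convergence when coefficients move < 1e-8, scale
re-estimated each iteration as the MAD of residuals about zero) downweights
them instead of letting them tilt the line. Tukey bisquare weights are
available for heavier contamination.

The fitted line is then extrapolated to *all* peaks — common and
sample-unique alike — and the residual

```
M_normalized = M - (b0 + b1 * A)
```

is the quantitative measure of differential binding. Peaks with
`M_normalized > 1` (more than twofold higher normalized density in the
knockout) are called KO-specific, `M_normalized < -1` wild-type–specific,
and everything in between common; the inequalities are strict, so a value
of exactly 1 is not a specific call. When the compared mark co-locates with
a factor whose peaks are expected to change (e.g. fitting an H3K4me1
comparison while a demethylase is deleted), common peaks overlapping that
factor's binding sites can be excluded from the fit through the `mask`
argument; they are still normalized and classified.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_overlap_bp` | 1 bp | interval overlap needed for two peaks to pair |
| `pseudocount` | 1 read | added to every region count before densities |
| `density` | `per_kb` | count / length × 1000; `raw` uses plain counts |
| `method` | `huber` | robust weight function (`bisquare` optional) |
| `threshold` | 1 (log2) | specific-peak cutoff on |normalized M| |
| `shift_bp` | 0 | read midpoint shift when counting from reads |

Pairing is one-to-one: each peak of the first catalog is matched to the
unmatched peak of the second with maximal overlap (ties to the leftmost).
The fit refuses to run on fewer than 10 common peaks.

Read density is per kilobase so that regions of different width are
comparable; the pseudocount keeps M finite at regions with zero reads in
one sample (inevitable for sample-unique peaks). Both choices have a
visible numerical consequence discussed under *Numerical behaviour*.

## Genomic annotation and target assignment

Peaks are anchored at their summit (or midpoint when no summit is known)
and classified into five compartments with windows oriented by the strand
of the nearest gene model: distal promoter (−10 kb to −4 kb of the TSS),
proximal promoter (−4 kb to +2 kb), exon, intron, intergenic. Offsets are
half-open ranges in the direction of transcription. When an anchor
satisfies several definitions the precedence is proximal promoter > distal
promoter > exon > intron, reflecting that promoter assignment is the claim
downstream analyses prioritize; intergenic is everything else. Annotations
with several transcripts per symbol are collapsed to the longest
transcript so every symbol has one deterministic TSS.

Target genes are assigned by nearest TSS (ties to the lexicographically
smaller symbol), one gene per peak. Target genes are optionally partitioned
by binding location into *distal and promoter*, *distal only* and
*promoter only* groups — a peak is a promoter peak for its gene when its
anchor falls in that gene's proximal promoter window.

## Enrichment statistics

Two complementary statistics connect peak targets to gene signatures:

1. **Overlap enrichment**: observed overlap between a target set and a
   signature divided by the overlap expected at random given both sizes and
   the gene universe (`es = k / (|T||S|/|U|)`), with a one-sided Fisher's
   exact p-value (the hypergeometric upper tail). The universe defaults to
   all annotation symbols and is configurable; an `es` of 1 means exactly
   the random expectation.
2. **GSEA-style running score**: genes are ranked by a signal-to-noise
   ratio between conditions, `(mean_ko − mean_wt)/(sd_ko + sd_wt)` with
   each sd floored at `max(0.2 |mean|, 0.2)`; walking down the list, set
   members add increments proportional to `|score|^p` (normalized to sum
   to 1) and non-members subtract `1/(N − N_hits)`. The enrichment score is
   the signed extremum of the running sum. The null is *gene-set
   permutation*: random same-size sets drawn from the ranked genes
   (1000 permutations by default). NES divides the observed ES by the mean
   |ES| of same-sign permutations; the nominal p is the same-sign tail
   fraction, reported as 1/n_perm when no same-sign permutation exists; the
   FDR is a ratio-of-tails q-value against the pooled sign-normalized
   permutation distribution, clipped to [0, 1]. A phenotype-permutation
   null is deliberately out of scope.

## Expression integration

Differential expression uses a per-gene two-tailed t-test on log2 values
with a fold-change filter (defaults: ≥1.5-fold and p ≤ 0.05, no
multiple-testing correction — mirroring the common microarray filter this
pipeline accompanies; Benjamini-Hochberg values can be added by the user
from the reported p's). Welch's unequal-variance form is the default
because it is robust to variance differences between conditions and
coincides with the classic test when variances agree; the pooled form is
available via `var_equal = TRUE`. Expression ratios of knockout over
wild-type are summarized per target-gene group as five-number summaries,
and `delta_delta_ct()` implements qPCR relative quantification
(`2^-ΔΔCt`).

## The synthetic world

Every stage is validated against `simulate_experiment()`, which generates:

* a single-chromosome annotation (default 1000 genes, 50 Mb, one gene per
  uniformly spaced slot, random strand, 2–5 exons) — spacing guarantees
  each gene's full promoter footprint fits its slot;
* 2000 common peaks obeying a latent scaling law `M = 0.4 + 0.1 A` with
  Gaussian log2 noise (sd 0.3) split antisymmetrically between the two
  samples so A stays noise-free, plus 200 KO-specific and 200
  wild-type–specific peaks whose KO-side density is shifted by ±2.5 log2
  units and which are placed in promoter or distal windows of designated
  target genes (each present only in its own sample's catalog);
* integer read counts `round(density × length/1000)` for both samples over
  every region, and optionally reads whose midpoints reproduce those
  counts exactly;
* a 150-gene signature drawn with 8-fold odds for KO-target genes plus a
  uniform control signature;
* replicate expression (4 + 4, baseline N(7, 1), +1 log2 at KO targets,
  residual sd 0.3).

Peak widths are 0.5–2 kb and common-peak A values are uniform on (4, 12)
(log2 reads/kb), spanning the intensity range of a typical histone-mark
MA plot. Placement sweeps left to right so that regions are mutually
disjoint and no common peak invades a differential gene's promoter
footprint; truth labels are therefore exact by construction.

What the generator does *not* emulate: GC and mappability bias, fragment
size, peak-calling uncertainty, overlapping or multi-summit peaks,
chromosome structure, and probe-level microarray noise. A green test
establishes that the algorithms recover a known scaling law, known
differential peaks and known enrichments under clean conditions — not that
the defaults are optimal for any particular real dataset.

## Numerical behaviour worth knowing

* **Pseudocount bias at the intercept.** Adding one read to both counts
  shrinks |M| slightly, and more so at low A. Over common peaks this bends
  the M-A cloud a little, and because the intercept is an extrapolation to
  A = 0 — four log2 units below the lowest data — the fitted intercept of
  the default scenario lands about 0.03–0.08 below the generating 0.4
  while the slope is recovered to well within 0.01. With the pseudocount
  disabled (possible whenever all counts are positive) the intercept is
  recovered to within rounding noise. This is a property of any
  pseudocounted M-A fit, not of the optimizer.
* **Degenerate fits.** A noiseless line gives a zero MAD; the IRLS detects
  this and returns the exact least-squares line instead of dividing by a
  zero scale.
* **Zero-variance genes.** The sd floor in the ranking metric and the
  `se == 0` guard in the t-test keep both finite; identical replicates
  with equal means give p = 1.
* **Boundary conventions.** All coordinates are 0-based half-open (BED);
  touching intervals do not overlap; a read midpoint exactly at a region
  end is outside; classification at |normalized M| = threshold is
  `common`; promoter windows are half-open in offset space.
* **Determinism.** Every stochastic stage takes a seed; the simulator
  derives per-stage seeds from one master seed, and the pipeline seeds its
  GSEA permutations from the configuration, so whole runs are
  byte-reproducible.

## Design choices made where the design was open

* *Common-peak criterion*: ≥1 bp overlap with one-to-one maximal-overlap
  matching — the simplest reproducible rule; the threshold is an argument.
* *Peak anchor*: summit when present (the binding-position estimate),
  midpoint otherwise.
* *Fitting set*: only common peaks ever enter the reference fit;
  sample-unique peaks are normalized but cannot influence the reference,
  because nothing constrains their cross-sample scaling.
* *Cross-sample counts for unique peaks* are measured, not imputed: the
  pipeline counts both samples' reads over every union-catalog region (or
  requires a counts table covering it).
* *One gene per peak* (nearest TSS) rather than all genes within a window:
  deterministic, and consistent with summarizing a catalog as one target
  set per condition.
* *Universe for overlap enrichment*: all annotation symbols by default;
  analyses restricted to assayed genes can pass the expression symbols
  instead.
* *Fisher sidedness*: one-sided (greater) because each enrichment claim is
  directional; two-sided available.

## Known limitations

Only two-sample comparisons are supported (no multi-sample joint
normalization); peak calling, read alignment and microarray preprocessing
are upstream of this package; transcript isoforms beyond the
longest-transcript rule are not modelled; the GSEA null is gene-set
permutation only, which is anti-conservative relative to phenotype
permutation when genes are strongly correlated.
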