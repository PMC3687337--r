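# peaknorm

Quantitative comparison of ChIP-Seq peak catalogs between two conditions,
for epigenomics analysts who need to say *which* binding sites or histone
marks changed after a perturbation — not just where peaks are.

Raw read counts from two ChIP-Seq libraries are not comparable: depth, IP
efficiency and library complexity distort signal in an intensity-dependent
way. `peaknorm` removes that distortion with an M-A normalization over
common peaks. For each region with read densities $d_{KO}, d_{WT}$,

$$M = \log_2\frac{d_{KO}}{d_{WT}}, \qquad A = \tfrac12 \log_2 (d_{KO}\, d_{WT}),$$

and, assuming the true intensities of most common peaks agree between
samples, a robust (Huber IRLS) line $M = b_0 + b_1 A$ fitted over the
common peaks captures the purely technical scaling. The line is
extrapolated to all peaks and the residual $M_{norm} = M - (b_0 + b_1 A)$
quantifies differential binding: $M_{norm} > 1$ defines KO-specific peaks,
$M_{norm} < -1$ wild-type–specific ones.

Around that core the package provides the full downstream path: genomic
compartment classification (distal promoter −10..−4 kb, proximal promoter
−4..+2 kb of the TSS, exon, intron, intergenic), nearest-TSS target-gene
assignment, Venn-style multi-set peak overlap, observed/expected gene-set
overlap enrichment with Fisher's exact test, a GSEA-style running
enrichment score with gene-set permutation, differential-expression
filtering (Welch t, fold cutoff), ΔΔCt relative expression, and a fully
seeded synthetic-experiment generator with ground-truth labels that the
test suite validates every stage against.

## Worked example

A complete simulated experiment with a known scaling law
($b_0 = 0.4, b_1 = 0.1$, noise sd 0.3, 200 + 200 differential peaks at
ΔM = ±2.5):

```r
library(peaknorm)

sim <- simulate_experiment(sim_params(seed = 7))
fit <- manorm(sim$experiment$ko, sim$experiment$wt,
              counts = sim$experiment$counts)
summary(fit)
#> Quantitative peak comparison summary
#>   regions: 2400 (common=2000, unique_ko=200, unique_wt=200)
#>   reference: M = 0.350499 + 0.10548 * A  [huber, n_fit = 2000]
#>   mean normalized M over fitted peaks: -0.0006018
#>   labels: ko_specific=201, wt_specific=201, common=1998
```

The robust fit recovers the generating slope almost exactly and the
intercept to within a few hundredths (the +1-read pseudocount bends the
M-A cloud slightly at low intensities; see the vignette), and the specific
peak calls recover the 200 + 200 planted differential regions with one
false positive on each side. The KO-specific target genes are then tested
against the planted signature:

```r
ann <- sim$annotation
tab <- as.data.frame(fit)
union_ps <- peak_set(tab$chrom, tab$start, tab$end, sample_label = "union")
targets <- map_peaks_to_targets(union_ps[tab$label == "ko_specific", ], ann)
overlap_enrichment(targets, sim$signatures$SYNTH_KO_SIGNATURE,
                   unique(ann$symbol))
#> Overlap enrichment: ES = 3, p = 5.249e-33 (greater)
#>   overlap 90 of target 200 x signature 150 in universe 1000

diff <- differential_genes(sim$expression, direction = "up")
fraction_bound(diff$gene[diff$passes], targets)$fraction
#> [1] 0.9844559
```

ES = 3 means three times more KO-target genes fall in the signature than
expected at random for these set sizes; 98% of significantly upregulated
genes carry a KO-specific peak, as planted. `run_pipeline(pipeline_config(...))`
chains all stages from files on disk (peaks as BED, annotation as a
refFlat-like table, signatures as GMT, expression as TSV) and writes result
tables plus a byte-reproducible JSON summary; `plot(fit)` draws the MA
plots before and after normalization.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the default synthetic experiment under the given seed, runs the
complete pipeline (pairing, normalization, classification, annotation,
enrichment, GSEA, expression integration) against the installed package and
writes its report to `--out`, logging the fitted reference line and label
counts along the way.
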