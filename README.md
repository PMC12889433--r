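# bamscape

Statistical toolkit for quantifying the decline of border-associated
macrophages (BAM) in Alzheimer's disease (AD). Brain-resident macrophages
split into parenchymal microglia and BAMs of the meninges, perivascular
spaces and choroid plexus; BAMs are further divided into BAM1
(CD206-low / MHC-II-high) and BAM2 (CD206-high / MHC-II-low), the highly
endocytic subset whose numbers and metabolic fitness fall as disease
progresses. `bamscape` implements the composition statistics, clinical
covariate models, Compass-style metabolic post-processing and morphological
image quantification needed to measure that decline — together with a
synthetic-data generator with recorded ground truth, so every estimator can
be validated end-to-end without any external download.

## The statistics at the package's core

**Cluster enrichment.** For cluster *c*, the naive enrichment score is
*s(c) = n_AD(c) / n(c)*, the fraction of the cluster's cells originating
from AD donors; normalized scores divide by the mean of *s* over clusters,
so they average to exactly 1 and overall differences in cell numbers cancel
(`cluster_enrichment()`).

**BAM2:BAM1 ratio score.** Per donor,
*ℰ = exp((n_CD206 − n_MHCII) / N)*, with *n_CD206* the BAM2 count,
*n_MHCII* the BAM1 count and *N* the donor's total cell count
(`bam_ratio_score()`). ℰ obeys the reciprocity
*ℰ(a, b, N)·ℰ(b, a, N) = 1* and lies in [e⁻¹, e¹].

**Clinical models.** Ordinary least squares of BAM fraction or ℰ on sex,
Braak score, post-mortem interval, CERAD score, education, and APOE E2/E4
allele counts, after retaining only donors with at least 0.1% of cells
annotated to the target populations (`filter_patients()`,
`clinical_model()`, forest plot via `autoplot()`).

**Metabolic post-processing.** Per-cell Compass reaction penalties are
pseudobulked into metacells of 10 cells (`pseudobulk()`), converted to flux
as *−log(1 + penalty)*, min-fixed and z-scored per reaction
(`penalty_to_flux()`). Disease effects are Cohen's d per reaction (pooled
SD) with rank-sum p-values and Benjamini–Hochberg adjustment
(`reaction_effects()`); pathways (subsystems) with at least 3 reactions are
called enriched when |median d| > 0.1 (`subsystem_summarize()`). The
healthy→AD *transition distance* of a cell type is the distribution of all
pairwise Euclidean distances between its healthy and AD samples, computed
via the Gram expansion ‖a−b‖² = ‖a‖² + ‖b‖² − 2a·b
(`transition_distance()`).

**Image quantification.** Max projection → rolling-ball background
subtraction (radius 50 px) → disk median filter → fixed threshold →
8-connected particle analysis gives % area and cell densities
(`subtract_background()`, `analyze_particles()`, `count_cells()`). The
CAA% macro measures the percent of the vessel mask (eroded ×2, dilated ×2)
covered by amyloid signal (`caa_fraction()`).

**Outlier flagging.** Per-cluster healthy→AD expression deltas are flagged
by a Hampel filter: beyond median ± 3·MAD (MAD scaled by 1.4826)
(`gwas_delta_flags()`).

## Worked example

```r
library(bamscape)

cfg <- synthetic_config(seed = 42, n_patients_per_condition = 20)
dat <- gen_cell_table(cfg)                       # AD depletes BAM2 2-fold
cluster_enrichment(dat$cells, condition_of_interest = "AD")
#> # A tibble: 4 × 5
#>   cluster   n_cells n_condition naive_score normalized_score
#>   <chr>       <int>       <int>       <dbl>            <dbl>
#> 1 BAM1         4987        2588       0.519            1.08
#> 2 BAM2         3512        1176       0.335            0.700
#> 3 DC           3369        1803       0.535            1.12
#> 4 microglia   70531       36998       0.525            1.10

bam_ratio_score(n_cd206 = 10, n_mhcii = 5, n_total = 100)
#> [1] 1.051271
```

The normalized BAM2 score of 0.700 < 1 reads as under-representation of
BAM2 cells among AD cells relative to the other clusters — the generated
2-fold depletion — while BAM1, DC and microglia sit near 1. The ratio score
exp(5/100) ≈ 1.05 says CD206-high cells slightly outnumber MHCII-high ones
in that donor.

An end-to-end run over one generated scenario (depletion + Braak coupling,
one metabolically shifted pathway, a 20%-coverage image):

```r
res <- run_pipeline(demo_config(seed = 42))
res$metabolic$subsystems_bam2
#> # A tibble: 4 × 6
#>   subsystem n_reactions median_d direction enriched n_significant
#>   <chr>           <int>    <dbl>     <dbl> <lgl>            <int>
#> 1 SS01               10  -1.20          -1 TRUE                10
#> 2 SS02               10  -0.0579        -1 FALSE                1
#> 3 SS03               10  -0.387         -1 TRUE                 1
#> 4 SS04               10   0.315          1 TRUE                 1
res$imaging[c("caa_percent", "true_coverage_pct")]
#> $caa_percent
#> [1] 18.96635
#> $true_coverage_pct
#> [1] 19.79783
```

SS01 — the pathway the generator shifted for BAM2-AD cells — shows a strong
negative median flux effect with all 10 member reactions significant; the
measured CAA% lands within a percentage point of the generator's recorded
coverage. (The spurious flags on SS03/SS04 illustrate the |median d| > 0.1
rule's behaviour at the demo's small metacell counts; the methods vignette
quantifies this.)

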