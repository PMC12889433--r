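---
title: "Models and methods behind bamscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bamscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bamscape)
```

`bamscape` measures the decline of border-associated macrophages (BAM) in
Alzheimer's disease along three axes — cell-type composition, metabolic
state, and tissue morphology — and ships a synthetic-data generator whose
recorded ground truth turns every estimator into a testable claim. This
vignette explains the models, the tunable parameters and their defaults,
the numerical choices, and what the synthetic validation does and does not
establish about real data.

## Composition statistics

### Cluster enrichment

For cluster $c$ with $n(c)$ cells of which $n_{AD}(c)$ come from AD
donors, the naive enrichment score is $s(c) = n_{AD}(c)/n(c)$ and the
normalized score is $s(c)/\bar{s}$, the mean taken over clusters. The
normalization cancels global differences in the number of profiled cells
per condition; by construction the normalized scores average to exactly 1
(asserted to $10^{-9}$ in the tests). If no cluster contains any cell of
the condition of interest the normalization is undefined and
`cluster_enrichment()` raises an error rather than returning NaNs.

### The exponential BAM2:BAM1 score

Per donor, $\mathcal{E} = \exp\!\big((n_{CD206} - n_{MHCII})/N\big)$ with
$N$ the donor's **total** cell count. The denominator choice (all cells,
not all BAMs) follows the score's written definition; because
$n_{CD206} + n_{MHCII} \le N$, the score is confined to
$[e^{-1}, e^{1}]$ and satisfies
$\mathcal{E}(a,b,N)\,\mathcal{E}(b,a,N) = 1$.

### Donor filtering

`filter_patients()` retains donors for whom at least 0.1% of cells carry a
target label; the boundary is inclusive ("at least"), so a donor at exactly
0.1% is kept. The filter is idempotent.

### Signature-ratio cluster annotation

`signature_ratio()` scores each cell for two gene programs as the mean
expression of the program's genes minus the mean of a size-matched, seeded
random background set, exponentiates, and averages the per-cell ratio
$\exp(\text{score}_A - \text{score}_B)$ within clusters. Standard
module-scoring tools draw background genes from matched expression bins;
the uniform random background used here is a deliberate simplification —
bin-matching corrects for mean-expression confounding that the synthetic
expression fixtures do not exhibit, and replicating one tool's binning
heuristic would tie the package to that tool's internals. Identical gene
sets share one background draw, so `set_a = set_b` yields a ratio of
exactly 1 (a reported tie), as does all-zero expression.

### Hampel flagging of per-cluster deltas

`gwas_delta_flags()` flags clusters whose healthy-to-AD expression change
lies outside median $\pm\, k \cdot$MAD, MAD scaled by 1.4826 so it
estimates a Gaussian SD. $k = 3$ by default — the conventional Hampel
setting, chosen here because no value is prescribed. When the MAD collapses
to zero but deltas differ, every delta unequal to the median is flagged by
its sign (the documented edge rule; with fewer than half the values
distinct the filter would otherwise be blind). What the per-cluster delta
*is* — mean expression change, module-score change, log fold change — is
the caller's choice; the operation is agnostic and the tests exercise it
with simple mean-expression deltas.

### Clinical linear models

`clinical_model()` fits ordinary least squares of a per-donor response
(BAM fraction or $\mathcal{E}$) on a fixed covariate set: sex, Braak score,
post-mortem interval, CERAD score, educational attainment and APOE E2/E4
allele counts. Braak and CERAD enter as numeric ordinals and no
interactions are fitted — the model is a plain linear combination of the
stated predictors. Rank deficiency is an error naming the aliased columns,
not a silently dropped term. For fraction responses the package's own
analyses use the empirical logit
$\log\big((n + 0.5)/(N - n + 0.5)\big)$: with a multiplicative effect on
the pre-normalised cell-type proportion, the donor's *odds* of a cell
belonging to the type scale exactly with the fold, so the log-odds slope
recovers the log-fold directly, whereas the log-*fraction* slope is
attenuated by the compositional renormalisation; the half-count offset
keeps zero counts finite and is close to unbiased for $\log \lambda$ once
expected counts exceed about 3.

## Metabolic post-processing

### Pseudobulking

`pseudobulk()` randomly partitions cells into disjoint metacells of exactly
10 (configurable) within each cell-type × condition stratum and sums the
member columns. Leftover cells are dropped, keeping every metacell exactly
the stated size rather than merging remainders into an odd-sized group; a
stratum smaller than the group size yields zero metacells with a warning.
Sums are the default (penalty inputs are counts-like); means are available
and make no difference after the per-reaction z-scoring below.

### Penalty-to-flux transformation

Flux is $-\log(1 + \text{penalty})$, monotone decreasing in the penalty
(lower penalty = greater capacity to carry flux). The raw flux matrix is
then *min-fixed* — the global minimum subtracted so the matrix minimum is
zero, the common reading of the post-processing step — and each reaction
row is z-scored across samples. Because z-scoring is shift-invariant per
reaction, the min-fix provably cannot change the final output; rather than
debate the reading, the pipeline-equality test asserts the outputs with and
without min-fix agree to $10^{-12}$. Constant rows cannot be z-scored; they
are set to zero and flagged.

### Effect sizes and subsystem calls

Cohen's d per reaction uses the pooled ($n-1$ weighted) SD; "the mean
divided by the standard deviation" leaves the SD unspecified, and the
pooled form is the standard two-sample convention. d is computed on the
z-scored flux by default (switchable to raw $-\log$ penalties); both are
affine-invariant so the choice rarely matters. Per-reaction significance is
a two-sided Wilcoxon rank-sum test with Benjamini–Hochberg adjustment
across all reactions in the comparison (not within subsystems), carried
through at $p_{adj} < 0.1$. A subsystem qualifies with at least 3 member
reactions and is called enriched when $|\text{median } d| > 0.1$.
Zero-pooled-SD reactions with unequal means receive a signed-infinity
sentinel, are excluded from subsystem medians, and are logged.

At small metacell counts the $|\text{median } d| > 0.1$ rule false-flags
readily: with $m$ metacells per arm the null sampling SD of a single
reaction's d is $\approx\sqrt{2/m}$ and of a 10-reaction subsystem median
$\approx 0.56\sqrt{2/m}$, so $m = 100$ gives a per-subsystem null flag
probability of roughly 7%, and the package's demo (8–40 metacells) flags
null pathways visibly. This is a property of the fixed threshold, not of
the implementation; the null-calibration test compares the observed flag
rate against a condition-permutation estimate of the same quantity.

### Transition distance

The transition distance of a cell type is the set of Euclidean distances
between *every* healthy × AD sample pair in that cell type (samples are not
paired). Distances are computed with the expansion
$\lVert a-b\rVert^2 = \lVert a\rVert^2 + \lVert b\rVert^2 - 2\,a\cdot b$
via one cross-product; negative rounding artifacts are clamped at zero
before the square root, and the result matches a per-pair loop to
$10^{-8}$ relative on random instances. Cell types are compared by
two-sided rank-sum tests on their distance distributions with BH
adjustment. A caveat carried over from the procedure itself: each sample
contributes to many pairs, so the pairs are not independent and the
rank-sum p-values are anti-conservative in absolute terms; they are used
as a ranking device across cell types, which is how the summary should be
read.

## Image quantification

Planes are `y × x` matrices; stacks are channel-first `(channel, z, y, x)`
arrays with a physical pixel size, 0-based pixel-centred coordinates, and
areas reported in both px² and µm².

### Rolling-ball background subtraction

The background is the grayscale opening of the plane with a *non-flat*
ball structuring element of the given pixel radius (default 50) — the
classical rolling-ball definition, not any tool's paraboloid approximation;
the contract is ground-truth recovery, not bit-equality with an external
program. Two numerical choices matter:

* the background is estimated on a 3×3-mean smoothed copy, so the ball
  rides under the signal rather than under individual noise minima;
* the ball's height profile is scaled to the plane's dynamic range
  (range/radius), which makes the operation commute exactly with any
  positive rescaling of the intensities — a gain change with an equally
  scaled threshold cannot change a mask. An unscaled ball in raw intensity
  units would behave differently at different camera gains.

A radius at least as large as the image degenerates to global-minimum
subtraction, with a warning. Output is clipped at zero.

### Filtering, masking, morphology, particles

The disk median filter uses reflected edges. Masks come from fixed absolute
thresholds by default — sections compared against each other must be
thresholded identically, so auto-thresholding (Otsu) is an explicit opt-in,
never silent. Erosion/dilation use a 3×3 square element, one pass per
stated iteration; the vessel pipeline's erode ×2 / dilate ×2 is an opening
(idempotent, asserted in tests). Particle analysis labels 8-connected
components (diagonally touching pixels join; configurable to 4) and
discards components below a minimum area; counts equal an independent
flood-fill oracle on random masks.

### The CAA% macro

`caa_fraction()` mirrors the vessel-coverage macro: vessel channel →
max-project → rolling ball(50) → median(3) → fixed threshold → erode ×2 →
dilate ×2; the mask area is the total vessel area. The plaque channel is
max-projected and preprocessed the same way (rolling ball, median radius
2 — the channel-level % area settings), restricted to the vessel mask, and
thresholded; CAA% = 100 × plaque-positive area inside the mask / mask
area. The macro's prose spells the preprocessing out only for the vessel
channel; applying the channel-level projection/background/median procedure
to the amyloid channel as well is this package's reading, adopted because
thresholding a raw max projection rides on the projected noise floor.
Thresholds are caller-supplied absolute values (the original macro's
values are not published, so recovery against generator ground truth — not
value matching — is the validation surface). Plaque signal added strictly
inside the vessel mask can only raise CAA%; signal beyond the median
filter's reach of the mask cannot change it.

## The synthetic-data generator

The generator emulates the statistical structure each analysis consumes;
all randomness flows from one seed, with per-component sub-streams derived
deterministically so adding one output never perturbs another. Identical
configuration and seed give bit-identical datasets.

**Cohort composition.** Baseline proportions microglia 85%, BAM1 6%, BAM2
5%, DC 4% — BAMs sit at roughly 4–6% of the brain immune landscape, and 5%
is a convenience within that range, not a measured value. In AD donors the
BAM2 proportion is divided by `bam2_ad_depletion_fold` (default 2); with a
clinical table present it is further multiplied by
`braak_fold_per_step^-braak` (default fold 2 per stage, matching the
magnitude of the reported per-stage decline), then renormalised. Donor
heterogeneity is log-normal on the BAM2 proportion with
`patient_sd_log = 0.4` — without it, per-donor fractions would be pure
multinomial noise and regression standard errors implausibly small for
human cohorts. Cell counts per donor are uniform on 1000–3000 by default.
Braak is drawn 0–6 with more mass at high stages in AD; PMI is gamma
(mean 8 h), education normal (16 ± 3 y), CERAD 1–4 skewed by condition,
APOE allele counts binomial with a higher E4 frequency in AD.

**Reaction penalties.** Penalties are
$\exp(\mathcal{N}(\mu + \delta, \sigma))$ per reaction × cell, with
$\delta$ applied only to (subsystem, cell type, AD) triples named in the
shift map. Default: 90 reactions in nine 10-reaction subsystems,
$\mu = 0, \sigma = 1$. The recovery analyses shift one subsystem by +0.5
log units for BAM2-AD cells: after pseudobulking and the flux transform
this produces a median Cohen's d near −1.2 in the BAM2 comparison, a
desk-scale analogue of disease-driven metabolic dysregulation concentrated
in one cell type.

**Images.** The vessel channel contains random-walk tubes (default 4
vessels, 15 px wide — the large pial/penetrating vessels the CAA macro
targets; substantially thinner tubes would fall below the resolution of
the macro's own median(3)/erode ×2 steps). The plaque channel contains
dense-core blobs: super-Gaussian (order 2) profiles with a steep edge,
half-maximum radius 8 px. Plaques are placed by rejection sampling against
the noiseless vessel mask — on-vessel while below target (with shrinking
radii to land inside the tolerance), off-vessel and disjoint afterwards —
until realised coverage is within one percentage point of the target; an
unreachable target is an error, never a silent miss. A 100% target paints
plaque over the vessel mask plus a 2 px margin so full coverage is exact.
Noise is Poisson shot noise plus Gaussian read noise (SD 2); `snr` sets
the photon budget by solving $A/\sqrt{A + \sigma_{read}^2} = \text{snr}$
for the peak amplitude $A$ (snr 5 → $A \approx 28.5$), mirroring how real
fluorescence SNR scales with photon counts. Ground truth records the exact
noiseless vessel area, coverage, particle count and amplitude, and always
equals direct recomputation from the noiseless masks.

**What passing the synthetic validation does and does not show.** The
generator produces independent cells given donor proportions, log-normal
penalties, and geometrically simple vessels and plaques. It does not
emulate sequencing depth or UMI sampling, transcriptional covariance
between cells of one donor, Compass's actual penalty distributions,
3-D vessel topology, anisotropic optics, or hand-drawn anatomical ROIs.
Recovery on this substrate demonstrates that the estimators are correctly
implemented and calibrated under their stated assumptions — not that those
assumptions hold in any particular tissue dataset.

## Problem sizes used in validation

The validation suite runs composition recovery at 40 donors/arm over 100
seeds; Braak-slope recovery at 200 donors with 5000–10000 cells each over
100 seeds (expected counts in the rarest stratum stay above ~3, where the
empirical logit is effectively unbiased); metabolic recovery at 100
metacells/arm (1000 cells) per cell type over 100 seeds; type-I-error
calibration over 200 simulated null responses; and image recovery at
256×256×8 stacks with target coverages {0, 5, 20, 50, 100}% at snr 5,
plus 20 smaller stacks for the monotonicity property. These sizes were
chosen so each check's Monte-Carlo error is small against the property it
asserts while the whole suite stays desk-scale.

## Known limitations

* The clinical model is OLS with a fixed covariate list; no mixed effects,
  no interactions, no ordinal link for CERAD/Braak.
* Rank-sum tests on transition-distance pairs ignore pairwise dependence
  (see above); treat the p-values as a ranking.
* The rolling ball is the classical non-flat opening; results will differ
  in detail from tools that approximate the ball with a paraboloid or that
  downsample large-radius images.
* `signature_ratio()`'s random background is not expression-bin matched.
* The generator's plaque/vessel geometry is 2-D extruded into z; there is
  no vessel branching and no spatially varying PSF.
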