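# pcnslMultimodal

Sex-stratified multimodal analysis of primary CNS lymphoma (PCNSL) cohorts.

PCNSL is a rare extranodal non-Hodgkin lymphoma confined to the brain and its
coverings, with higher incidence and worse outcomes in male patients. Studies
of such cohorts combine three data modalities — immunohistochemistry (IHC) of
tissue-microarray cores, MR-based tumor segmentations, and clinical/treatment
tables — and analyse them separately for female and male patients. This
package implements that full analysis chain as tested, reusable R functions,
together with synthetic-data generators that plant known ground truth for
every stage, so the pipeline can be validated end to end without access to
patient data.

## What the package computes

**IHC immune scoring** (`scoreCore`). A brightfield H-DAB tile is unmixed in
optical-density space (Beer–Lambert: OD = C·M, with M the unit-norm
hematoxylin/DAB stain matrix; concentrations recovered via M⁻¹). Each stain
channel is thresholded by the *conjunction* of Phansalkar's local threshold
t = m·(1 + p·e^(−q·m) + k·(s/r − 1)) and Otsu's global threshold, cleaned by
an 8-neighbor rule (a pixel survives only with ≥ 2 positive neighbors),
split by watershed on the negated Euclidean distance transform, and counted.
The immune score is 100·n_DAB⁺/(n_DAB⁺ + n_hema⁺).

**Spatial immune heterogeneity** (`densityMap`, `ratioHeatmap`,
`multisectorCorrelation`). Cell centroids become unit-mass Gaussian kernels
(default σ = 186 µm = 204 px at 0.92 µm/px, calibrated so a 1 mm² circle
holds 1 − exp(−A/(2πσ²)) ≈ 99 % of each kernel's mass); the pixel-wise
percent-positive map is 100·ρ_DAB/ρ_hema on valid pixels. Immune scores from
multisector cores of the same tumor are pooled over all unordered
within-patient pairs and summarized by Pearson's R.

**MR features** (`compartmentVolumes`, `countFoci`, `locationPercentages`).
Compartment volumes in cm³ from voxel counts; tumor foci as 26-connected
components of the enhancing compartment; location percentages of the main
tumor mass against a co-registered atlas, with the deep composite (corpus
callosum, periventricular regions, basal ganglia, thalamus, brainstem,
cerebellum).

**Sex-stratified clustering** (`sexStratifiedClustering`). Iterative
random-forest imputation of single missing entries, within-stratum
z-scoring, Ward minimum-variance clustering on Euclidean distances, a
minimum-cluster-size rule (clusters of n < 4 are flagged excluded), and
cluster characterization by ANOVA / Kruskal–Wallis tests.

**Survival modelling** (`kmFit`, `logrankTest`, `optimalCutoff`,
`univariableScreen`, `coxBackward`, `cohortCompare`). Kaplan–Meier curves
and log-rank tests on the immunocompetent first-line-chemotherapy subset;
survival-optimal cutoffs by exhaustive split search maximizing the log-rank
statistic; a per-stratum univariable screen (p < 0.1 in any of female, male,
all); backward-eliminated Cox proportional-hazards models (Efron ties,
HR = e^β with Wald 95 % CIs); and a female-vs-male comparison table
(t / Mann–Whitney / Fisher by variable type).

## Worked example

```r
library(pcnslMultimodal)

# a synthetic core with 80 negative nuclei and 20 DAB+ cells
tl <- simulateTile(tileConfig(nNegative = 80, nPositive = 20, seed = 11))
scoreCore(tl$tile, marker = "CD3")$score
#> ImmuneScore [CD3]: 20.00% positive (20 DAB+ / 80 hema+)

# a 10 mm spherical enhancing focus at 1 mm isotropic voxels
sc <- simulateSegmentationCase(
  shapeVoxels = c(48, 48, 48),
  plantedFoci = list(list(center = c(24, 24, 24), radiusMm = 10,
                          compartment = 1)))
compartmentVolumes(sc)
#> enhancingCm3  necroticCm3     edemaCm3
#>        4.169        0.000        0.000   # analytic 4/3*pi = 4.189 cm^3

# a treatment-prevalence contrast from 2x2 counts (13/41 vs 3/33)
fisherFromCounts(13, 41, 3, 33)
#> [1] 0.02374291
```

The score recovers the planted 20 % fraction exactly; the digitized sphere
volume is within 0.5 % of the analytic value; the Fisher p-value rounds to
0.02.

A full synthetic run — cohort generation through clustering and Cox
modelling — is one call:

```r
report <- runPipeline(list(seed = 1, outDir = "pcnsl-demo"))
```

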