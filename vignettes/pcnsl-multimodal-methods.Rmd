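---
title: "Methods: sex-stratified multimodal PCNSL analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-stratified multimodal PCNSL analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcnslMultimodal)
```

This vignette documents the models behind each stage of the pipeline, the
parameters that matter, the numerical choices, and what the synthetic-data
generators do and do not emulate. Primary CNS lymphoma (PCNSL) cohorts are
small and multimodal — tissue-microarray (TMA) immunohistochemistry,
MR-based tumor segmentations, and clinical tables — and the analyses here
are deliberately sex-stratified, because effect sizes that differ in sign
between female and male patients cancel in pooled analyses.

## IHC cell scoring

### Model

Brightfield H-DAB staining mixes linearly in optical-density (OD) space
(Beer–Lambert). With per-channel OD defined as
$\mathrm{OD}_c = -\log_{10}((I_c + 1)/256)$ (the +1 offset avoids
$\log 0$ at intensity 0; any fixed positive offset works and this one is
exactly inverted by the renderer), a pixel's OD vector is
$\mathrm{OD} = c_h v_h + c_d v_d$ with unit-norm stain vectors
$v_h \approx (0.650, 0.704, 0.286)$ and $v_d \approx (0.269, 0.568, 0.778)$
— the classical published H-DAB pair. Concentrations are recovered by the
inverse of the 3×3 matrix completed with the unit cross product as a
residual channel; negative concentrations (noise) are clipped to zero.
Because the synthetic renderer uses the same basis, render/deconvolve is an
exact round trip on unquantized tiles; 8-bit quantization perturbs recovered
concentrations by a few times $10^{-3}$.

### Segmentation and counting

Each concentration map is thresholded by the conjunction (logical AND) of

* **Phansalkar's local threshold**
  $t = m\,(1 + p e^{-qm} + k(s/r - 1))$ with $r = 0.5$ on the max-normalized
  map, window radius 15 px, $k = 0.25$, $p = 2$, $q = 10$ — the original
  publication's constants, suited to low-contrast stained tissue; and
* **Otsu's global threshold** on the same normalized map.

AND is the only combination that uses both thresholds: OR reduces to
whichever is looser. Two further gates are applied:

* an absolute concentration floor `minStainOd = 0.1` OD per pixel. Both
  Otsu and Phansalkar are *relative* thresholds; on a channel that carries
  no stain at all they would split the noise distribution and hallucinate
  objects. Channel noise of SD 0.02 OD, amplified by roughly 1.7× through
  the non-orthogonal stain basis, stays below 0.1 OD even in its far tail,
  while true nuclear staining peaks at 0.4–1 OD.
* the background rule: a positive pixel is kept only if at least
  `neighborMin = 2` of its 8 neighbors are positive (single pass; the
  output is always a subset of the input — idempotence is not guaranteed
  and not claimed).

Touching cells are split by watershed on the negated Euclidean distance
transform, seeded by h-maxima with $h = 0.3 \cdot \max(\text{distance})$;
objects below `minCellAreaPx = 20` px (≈ 17 µm² at 0.92 µm/px, smaller than
any nucleus) are discarded. The neighbor rule is applied to the mask
*before* watershed labelling, because it is defined on pixels, not objects;
running it after labelling would re-merge split cells' borders.

The score is $100\,n_{DAB^+}/(n_{DAB^+}+n_{hema^+})$. Whether such a
"ratio of DAB+ to hematoxylin+ cells" should denominate by hematoxylin
cells alone or by all cells is genuinely ambiguous in practice; both
conventions are implemented (`denominator = "all"` default, `"hema"` by
flag) and the default treats hematoxylin-only cells as the marker-negative
population, which matches the rendering model where DAB+ cells carry no
counterstain. A core with zero detected cells is flagged undefined — never
scored 0.

## Spatial immune density

Cell centroids are placed as unit impulses and convolved (zero-padded FFT)
with an isotropic Gaussian kernel. The default SD is physical:
σ = 186 µm (204 px at 0.92 µm/px). The calibration behind that choice is
that a circle of area 1 mm² centred on a kernel holds
$1 - \exp(-A/(2\pi\sigma^2)) = 0.98995 \approx 99\%$ of its mass
(`gaussianCircleMass(1, 0.186)`).

Zero padding means densities attenuate near borders instead of wrapping;
summary statistics are therefore restricted to pixels ≥ 2σ from the border.
The percent map is $100\,\rho_{DAB}/\rho_{hema}$ on valid pixels; the
overall percentage pools densities (ratio of sums), so it equals the global
cell-count ratio rather than a mean of noisy pixel ratios. Validity
requires the denominator density to reach a floor, by default 10 % of the
slide-median hematoxylin density — an automatic surrogate for manually
excluding damaged, cell-poor regions; an explicit exclusion mask is also
accepted, and masking restricts without renormalizing retained values.

Multisector scores (2–3 cores per tumor) are pooled over all unordered
within-patient core pairs (ordered by core index) and summarized by Pearson
R with a two-sided t-based p ($df = n_{pairs} - 2$; r is reported without p
below 3 pairs). Pooling all pairs, rather than first-versus-rest, uses all
the information a 3-core patient carries; the alternative changes n but not
the estimand under exchangeable cores.

## MR features

Volumes are voxel counts × voxel volume (mm³ → cm³); a warning is raised
above 5:1 spacing anisotropy. Foci are connected components of the
enhancing compartment under 26-connectivity (the most permissive choice —
"interconnected voxels" without qualification; 6 and 18 available, and the
test suite pins the case where they differ). Location percentages classify
each voxel of the *main tumor mass* by its co-registered atlas code. The
main mass is enhancing + necrosis by default — the tumor proper, excluding
edema, which can extend far beyond it; an `enhancing`-only flag exists
because segmentation protocols differ. Where a merged atlas would give a
voxel both a lobar and a deep code, the deep code wins: deep location is
the prognostically targeted composite (corpus callosum, periventricular
regions, basal ganglia, thalamus, brainstem, cerebellum). Registration is a
precondition (identical grids are asserted), never performed.

## Cohort clustering

Missing entries (in practice: a few performance-status values and immune
scores from cores lost during processing) are imputed by chained equations
with a random-forest learner: mean initialization, then each incomplete
column regressed on all others (ranger, 100 trees, fixed seed, single
thread for determinism), cycling until the largest change falls below
$10^{-3}$ column SDs or 10 iterations. Ordinal columns are snapped back to
their grids (ECOG to 0–4). Imputation runs on the pooled table by default —
with n ≈ 74 the strata are too small to waste rows — with a flag to
stratify. Missingness is assumed MCAR, which matches the known mechanism
(cores floating off is unrelated to the patient).

Clustering uses eleven numerical/ordinal features fixed at diagnosis: deep
location %, enhancing/necrotic/edema volumes, number of foci, age, ECOG,
and the CD3/CD45ro/CD68/FoxP3 scores. Treatment variables are excluded so
clusters are not confounded by therapy choice; lobar location variables
other than deep are excluded as strongly interdependent compositional
shares that would dominate a Euclidean metric. ECOG enters the z-scored
matrix as a number (required by Euclidean Ward) but is tested ordinally.
Z-scoring uses the sample SD (ddof = 1) within the stratified sub-cohort.

Ward minimum-variance clustering runs via `hclust(method = "ward.D2")` on
Euclidean distances (heights on the distance scale, non-decreasing; an
exhaustive greedy-Ward oracle pins the behaviour for n ≤ 6 in the tests).
The per-sex cluster count is a parameter (defaults 3 female / 3 male, the
male cut yielding two main clusters plus a small immune-driven satellite);
when unset, k is chosen by the largest relative gap in merge heights
between 2 and 6. Clusters below `minClusterSize = 4` are flagged excluded —
too small to characterize — but never reassigned. Retained clusters are
characterized by one-way ANOVA (numerical) and Kruskal–Wallis (ordinal)
with unadjusted p-values (the analysis is exploratory) plus a
Benjamini–Hochberg column.

## Survival analysis

The survival cohort is restricted to immunocompetent patients who received
first-line chemotherapy; rows with either flag missing are excluded with a
warning. Kaplan–Meier estimation and log-rank tests wrap the survival
package; the median is the earliest time with $S(t) \le 0.5$ and is NA
("not reached") when the curve never crosses 0.5.

Cutoffs for numerical/ordinal variables are found by exhaustive scan over
midpoints of consecutive sorted unique values, subject to `minLeaf = 5` per
side, maximizing the log-rank statistic (first maximum in ascending order
on ties). This is the first split of a survival tree, made explicit. The
resulting statistic is *maximally selected*: its nominal p-value is
anti-conservative and is used only for ranking and screening, with that
inflation measured (not corrected) in the test suite. The univariable
screen computes each stratum's own cutoff (female, male, all — strata
differ, so shared cutoffs would blur exactly the sex-specific signal of
interest) and selects a variable when its log-rank p < 0.1 in any stratum.

The multivariable model is a Cox proportional-hazards fit (Efron tie
handling — continuous times with rounding produce ties) with backward
elimination: repeatedly drop the highest-p term while that p ≥ 0.1. The
0.1 retention threshold is chosen so that a term with p = 0.091 is
retained, matching the convention of keeping borderline terms visible in
exploratory models. Variables can enter dichotomized at their cutoff
(e.g. age > 60, ECOG > 1) or continuous per unit (immune scores per
percentage point, volumes per cm³). Hazard ratios are $e^\beta$ with Wald
95 % CIs; elimination order is recorded, and with fewer than 5 events per
term a warning is raised.

The female-vs-male comparison table uses Welch t-tests for numerical
variables, Mann–Whitney U for ordinal (exact enumeration for untied
samples of ≤ 20 per group, normal approximation with continuity and tie
correction otherwise), and two-sided Fisher exact tests on 2×2 counts for
nominal variables, with mean ± SD / median (IQR) / n (%) descriptives.

## What the generators emulate — and what they do not

`simulateTile` renders elliptical nuclei (axis ratio ≤ 1.4, random
orientation, Gaussian-blurred edges with σ = 1 px — hard disks would make
Otsu degenerate) at planted stain amplitudes (hema 0.8, DAB 0.9 OD), mixed
through the canonical stain basis with additive channel OD noise
(SD 0.02) and 8-bit quantization. Placement forbids contact unless an
overlap allowance is set, and an infeasible packing raises an explicit
error. The default 0.92 µm/px corresponds to a 10× core export in which
204 px span 186 µm; tile size and counts are configurable. Not emulated:
scanner colour profiles, stain-intensity gradients, tissue folds, nuclear
texture, out-of-focus blur. Passing recovery tests therefore shows the
*algorithmic* chain is correct and well-calibrated on its own image model,
not that the fixed thresholds transfer to arbitrary scanners.

`simulateMultisector` draws per-core positive fractions hierarchically
(patient mean, SD `betweenPatientSd`; core deviation, SD `withinPatientSd`),
so the expected pooled pair correlation is
$\sigma_b^2/(\sigma_b^2+\sigma_w^2)$ — the knob used to plant regimes from
perfectly reproducible cores to pure within-tumor heterogeneity.

`simulateCohort` plants per-sex Gaussian clusters over the eleven
clustering features with proportions honored exactly (deterministic counts,
shuffled order), realistic treatment-flag prevalences, and survival times
from an exponential proportional-hazards mechanism
$h = h_0 e^{x^\top\beta}$ (default $h_0 = 0.05$/month, median ≈ 14 months
at β = 0) with exponential administrative censoring rate-matched to the
requested censoring fraction and MCAR masking of ECOG and immune scores.
Default sizes are 41 female / 33 male. True cluster labels and uncensored
event times travel in hidden `.cluster`/`.eventTime` columns. Not
emulated: non-proportional hazards, informative censoring, correlated
missingness, measurement error in MR features.

`simulateSegmentationCase` plants spherical foci on a voxel grid with a
slab-based lobar atlas plus a central deep box; ground-truth volumes, focus
counts (geometric merge of overlapping same-compartment spheres) and the
atlas layout are attached as attributes. Real lesions are not spheres; the
geometry only needs to exercise counting, volumetry and overlap logic.

## Numerical choices and degenerate inputs

* Constant OD map → Otsu undefined → empty mask with warning.
* Zero detected cells → score flagged undefined (NA), never 0.
* Zero-variance feature → dropped from z-scoring with a warning.
* Singleton cluster → left out of ANOVA/KW tests, logged.
* Constant survival variable → "no admissible split", flagged.
* No covariate surviving elimination → explicitly empty Cox model.
* FFT convolutions use zero padding; tiny negative round-off densities are
  clipped to 0.
* Per-stage seeds derive from one user seed via a fixed stage-name hash,
  kept below $2^{31}$, so toggling one stage never shifts another's stream.

## Problem sizes

The test suite and acceptance script size their simulations to run on one
CPU in minutes: 20 scored tiles of 360² px at 100 cells each for IHC
recovery; 512² density grids at 4 µm/px for the kernel calibration;
n = 2000 for Kaplan–Meier consistency; 1000 null replicates for log-rank
type-I error; 100 replicates of n = 300 for Cox recovery of a planted
HR = 4.4; 20 replicates of n = 200 for change-point recovery; cohorts of
40 + 33 for clustering recovery. These sizes hold the Monte-Carlo error
well inside each check's tolerance.

## Known limitations

* Stain vectors are configuration, not estimated from the image; strongly
  deviating scanners need their own matrix.
* The maximally-selected cutoff inflation is measured, not corrected; the
  univariable screen is a candidate filter, not an inference.
* With ~30–40 events per stratum, backward-eliminated Cox models are
  exploratory; no internal cross-validation is attempted at these sizes.
* The atlas-overlap logic assumes pre-registered inputs on one grid;
  registration error propagates directly into location percentages.
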