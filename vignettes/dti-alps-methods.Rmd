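---
title: "DTI-ALPS: model, semi-automatic ROI procedure and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DTI-ALPS: model, semi-automatic ROI procedure and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpsdti)
```

## The measurement model

Diffusion MRI measures, per voxel and gradient direction $g$ at b-value
$b$, the signal $S = S_0 \exp(-b\, g^\top D g)$, where $D$ is the
symmetric positive-definite diffusion tensor (mm²/s). Taking logs makes
the model linear in the six unique tensor elements plus $\log S_0$;
`fit_tensor()` solves this system per voxel by ordinary least squares or,
by default, by one-pass weighted least squares with weights equal to the
squared predicted signal — the standard correction for the
heteroscedasticity that the log transform induces on additive noise. The
estimator and the use of both shells are configurable (`method`,
`b_max`) because clinical reports rarely state either; the default fits
all volumes of the multi-shell acquisition with WLS. Restricting to the
lower shell (`b_max = 1000` say) gives a fit free of the high-b
kurtosis bias at the cost of fewer measurements.

From the eigendecomposition $D = \sum_i \lambda_i e_i e_i^\top$
(eigenvalues sorted descending and clamped at zero) we derive mean
diffusivity $\mathrm{MD} = \bar\lambda$, fractional anisotropy

$$\mathrm{FA} = \sqrt{\tfrac{3}{2}}\,
  \frac{\sqrt{\sum_i (\lambda_i - \bar\lambda)^2}}{\sqrt{\sum_i \lambda_i^2}},$$

defined as 0 in the all-zero limit, and the colour-FA map with channels
$\mathrm{FA}\cdot|e_{1,c}|$ (red = x, green = y, blue = z).

## The ALPS index and the semi-automatic procedure

In the periventricular geometry the perivascular spaces run along x,
perpendicular to z-oriented projection fibres and y-oriented association
fibres. The ALPS index contrasts x-diffusivity with the diffusivities
perpendicular to both the fibres and the perivascular axis:

$$\mathrm{ALPS} =
  \frac{(D_{xx}^{\mathrm{proj}} + D_{xx}^{\mathrm{assoc}})/2}
       {(D_{yy}^{\mathrm{proj}} + D_{zz}^{\mathrm{assoc}})/2}.$$

The diffusivities are *tensor elements in the scanner frame*, not
eigenvalues: the method is defined on axis-aligned diffusivities, and
`extract_diffusivities()` averages them over the ROIs. The index is
dimensionless, invariant under common rescaling of the four inputs and
under global $S_0$ rescaling of the raw signal.

`run_alps()` chains the semi-automatic steps:

1. **Channel isolation** — inside the operator's rectangle, each colour
   channel is thresholded at its 95th percentile (percentile computed by
   linear interpolation between order statistics, R type 7) *over the
   rectangle*, not the whole brain: the thresholding exists to isolate
   the fibre systems within the delimited search area. A voxel enters the
   projection mask only if blue is also its dominant channel (and
   likewise green for association); dominance ties go to projection, so
   the masks are disjoint. Channels whose values never exceed numerical
   noise (1e-6) raise a "no anisotropic tissue" error.
2. **Peak search** — the maximum-value voxel of the relevant channel
   within the mask; ties are broken lexicographically by (x, y, z) so
   results are deterministic.
3. **ROI placement** — a circular, single-slice (2D) ROI of 5 mm
   diameter centred on each peak. Membership uses the *world-mm*
   centre-to-centre distance through the affine, boundary inclusive:
   with 2.5 mm voxels an exclusive rule would degenerate to a single
   voxel, which cannot be what a 5 mm circular ROI denotes. ROIs at the
   volume edge are clipped with a warning.
4. **Extraction and index** — ROI means of $D_{xx}, D_{yy}, D_{zz}$ and
   the ratio above.

Analyses default to the left hemisphere; right-sided analysis is
implemented but off by default because shunt hardware is conventionally
right-sided and its susceptibility artefacts contaminate that hemisphere.
One rectangle may serve both fibre systems; the default workflow supplies
one per system, in which case only the matching channel is required to
contain anisotropic tissue in its rectangle.

### Coordinate conventions

All R-level voxel coordinates are 1-based, following R array semantics
(and packages such as oro.nifti); world coordinates are obtained by
applying the NIfTI affine to the 0-based index, so geometry matches the
NIfTI RAS+ convention exactly. All ROI distances are computed in world
mm, never in raw index units, so anisotropic voxels would be handled
correctly.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `percentile` | 95 | — | channel threshold inside the rectangle |
| `roi_diameter_mm` | 5 | mm | circular ROI size |
| `hemisphere` | left | — | right side carries shunt artefacts |
| `b0_threshold` | 50 | s/mm² | any value below the first shell is equivalent here |
| `method` | WLS | — | robust standard choice for log-linear fits |
| `b_max` | none | s/mm² | optional shell restriction |
| signal floor | `1e-4 * S0` | signal | avoids $-\infty$ logs under noise without touching clean data |

## What the synthetic data emulate

`phantom_spec()` builds a two-slab field: a projection slab with tensor
$\mathrm{diag}(d_x, d_\perp, d_\parallel)$ (principal axis z) and an
association slab with $\mathrm{diag}(d_x, d_\parallel, d_\perp)$
(principal axis y), in an isotropic background. Both slabs share the
perivascular x-diffusivity, so the ground-truth index is exactly
$d_x / d_\perp$. Defaults ($d_x = 0.75\times10^{-3}$,
$d_\perp = 0.6\times10^{-3}$, $d_\parallel = 1.6\times10^{-3}$ mm²/s,
$S_0 = 100$, 2.5 mm isotropic voxels on a 40×40×20 grid) give
physiological white-matter diffusivities and a true index of 1.25.
The acquisition mirrors the clinical protocol: one b0 plus 30 directions
at b = 711 and 61 at b = 2400 s/mm². Scanner direction tables are
vendor-specific and unpublished, so directions are placed quasi-uniformly
by a Fibonacci sphere. Noise is Rician,
$\sqrt{(S+\varepsilon_1)^2 + \varepsilon_2^2}$ with Gaussian
$\varepsilon$, the correct model for magnitude MR images; a Gaussian
option exists for debugging.

`phantom_rectangles()` insets the search rectangles two voxels from the
slab edges. This mirrors how an operator draws the search region well
inside the fibre bundle, and it has a numerical role on an idealised
phantom: slab voxels all tie at the maximum channel value, the
lexicographic tie-break then lands on the rectangle corner, and an
un-inset rectangle would centre the ROI on the slab boundary where it
straddles background.

The cohort simulator draws each subject's trajectory across timepoints
from a multivariate normal with the published per-group/timepoint means
and SDs (responders n = 15, non-responders n = 6, controls n = 8;
follow-up imaging in 9 responders) and an exchangeable within-subject
correlation. The correlation is not reported clinically; the default of
0.7 was chosen once as a plausible test–retest correlation for a derived
MRI index and is exposed as a parameter. This is the simplest
construction with a controllable paired correlation, which is all the
paired tests need.

**What passing tests do not show.** The phantoms are homogeneous,
axis-aligned, artefact-free and noise-stationary. Real data add crossing
fibres, oblique tracts, partial volume with CSF, motion and eddy
residuals, and spatially varying coil noise; recovery within 2% at
SNR 30 on the phantom bounds the estimator's statistical error, not those
systematic effects. Likewise the cohort simulator reproduces summary
moments, not the unknown joint distribution of patient covariates.

## Statistical layer

Two-sample and paired comparisons gate on the Shapiro–Wilk test at
$\alpha = 0.05$ (the level is not stated clinically; 0.05 matches the
overall significance threshold): normal samples get a pooled-variance
Student t (paired t for within-group contrasts), otherwise Mann–Whitney U
or Wilcoxon signed-rank. The rank tests use the exact null distribution
for small untied samples (both n ≤ 20 two-sample; ≤ 25 non-zero
differences paired) and the tie-corrected normal approximation beyond;
zero differences are dropped before signed ranking (Wilcoxon's original
treatment; the Pratt variant was considered and rejected to match common
clinical software defaults). All p-values are two-sided.

`summary_ttest()` recomputes unpaired comparisons from published
mean/SD/n triples with the pooled-variance form; pooled rather than Welch
is the default because only the pooled form reproduces the published
FDR-adjusted baseline footnotes (0.0004 and 0.0018) from the group
summaries, with the Benjamini–Hochberg family taken as the three baseline
pairwise comparisons — the unique family assignment consistent with those
printed values. Welch remains available via `welch = TRUE`.
`bh_adjust()` delegates to the standard step-up implementation and is
property-tested against the cumulative-minimum formula. Spearman
correlations use midranks for ties, exact permutation p for n ≤ 9
without ties.

Degenerate inputs are handled explicitly: zero-variance samples cannot be
gated and fall to the rank branch with a warning; two identical constant
samples compare with p = 1, constant samples with different values with
p = 0; all-zero paired differences give p = 1 with a warning; constant
inputs make the rank correlation undefined and raise an error.

## Numerical choices

* Percentiles: linear interpolation between order statistics (type 7),
  the R default, stated here because mask membership depends on it.
* Signals ≤ 0 are floored at $10^{-4} S_0$ (per-voxel b0 estimate)
  before the log; clean data are unaffected.
* Negative eigenvalues are clamped to zero before FA/MD, keeping FA in
  [0, 1].
* Eigenvector sign is fixed by making the largest-magnitude component
  positive — cosmetic (colour FA takes absolute values) but
  deterministic.
* ROI boundary inclusive with a 1e-9 mm tolerance against floating-point
  ties at exactly one radius.
* The WLS normal equations are assembled for all voxels with two matrix
  products; only the 7×7 solves loop.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full pipeline on
40×40×20-voxel phantoms (32,000 voxels, 92 volumes) for the headline
recovery checks — noise-free for the four target indices
{0.8, 1.0, 1.25, 1.5} and 20 Rician seeds each at SNR 30 — and on a
compact 30×30×12 phantom where a unit test only needs the mechanics.
These sizes were chosen to make a single-subject analysis complete in
seconds while keeping ROI geometry (5 mm ROIs on 2.5 mm voxels)
identical to the clinical setting. The type-I error check uses 2000
null replicates of the 15-vs-8 design, bounding the Monte-Carlo SE of
the rejection rate at about 0.005.

## Known limitations

* Single-tensor model only; no kurtosis or multi-compartment fits, so
  the high-b shell biases diffusivities slightly downward in real
  tissue (exposed via `b_max` for users who want a low-b fit).
* No brain extraction: the mask is an input, with a simple
  signal-threshold fallback.
* No atlas-based automatic rectangle placement or slice selection — the
  rectangles are operator (or phantom-spec) input by design.
* DICOM, NIfTI-2 and gradient dialects other than FSL's are out of
  scope, as is any DWI preprocessing (motion/eddy/distortion
  correction); inputs are assumed corrected.
* The right-hemisphere path shares all code with the left but no
  clinical interpretation is offered for it.
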