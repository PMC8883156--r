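---
title: "Material discrimination with oddity tasks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Material discrimination with oddity tasks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matodd)
```

## Overview

`matodd` implements the analysis pipeline of a large-scale material
discrimination study: observers view three or four object images and pick
the odd one, where the odd image differs along one of six material
dimensions — gloss contrast (GC), gloss distinctness-of-image (GD),
opaque–translucent (OT), gold–plastic (MP), silver–glass (MG), and
glossy–painted (GP, spatially inconsistent specular highlights). The
package covers the whole chain: perceptual gloss parameterization,
procedural stimulus synthesis, simulation-based sensitivity (d′)
estimation, compressed color texture statistics, and regression of
sensitivity on feature distances.

## Gloss parameterization

The Ward reflectance model has parameters ρd (diffuse reflectance), ρs
(specular energy) and α (specular lobe spread). Its perceptual
reparameterization uses contrast gloss
c = (ρs + ρd/2)^(1/3) − (ρd/2)^(1/3) and distinctness-of-image gloss
d = 1 − α. The GC task varies ρs from 0 to 0.12 in steps of 0.02 at
ρd = 0.416; the resulting contrast values, truncated to three decimals,
are:

```{r}
trunc(contrast_gloss_grid(task_grids()$GC) * 1000) / 1000
```

(The grid's full-precision values are used internally; the quoted values
are their 3-decimal truncations.) The inverse conversion is closed form
(`perceptual_to_ward()`), and `eval_ward()` evaluates the BRDF pointwise
with δ taken as the angle between the half vector and the surface normal
— the printed model equation leaves δ implicit, and this is the standard
Ward convention.

## Synthetic stimuli

The stimulus generator stands in for a physically based renderer; the
analysis pipeline consumes only images and responses, so a proxy whose
image statistics move monotonically along each material dimension is
sufficient and runs on a desktop in seconds. Its fidelity limits are
deliberate: no global illumination, no real light probes, no volumetric
scattering.

* **Geometry**: five bumpy spheres, reproducible from seeds: a
  low-frequency/crater surface, bandpass noise, sine-wave modulation, and
  two Perlin-style multi-octave surfaces. Noise is expressed as seeded
  cosine sums, so surfaces are continuous functions of position and can
  be sampled under any of the five 36°-step poses.
* **Illumination**: six parametric proxies (directional lights plus
  ambient, distinct color temperatures and backgrounds). Proxies 1–3 are
  mutually similar and serve illumination condition 2; proxies 4–6 are
  mutually dissimilar and serve condition 3; condition 1 uses a single
  proxy with four poses.
* **Materials**: GC varies ρs in the Ward specular term; GD/GP realize
  DOI as a highlight blur with kernel width proportional to α = 1 − d;
  OT attenuates a backlight/background term with optical density
  proportional to the scale parameter (exponential in the sphere chord
  length); MP and MG are per-pixel linear blends of two endpoint shading
  models. Off-grid parameters raise an error listing the valid grid.
* **Inconsistent highlights (GP)**: the specular-only layer is rendered,
  remapped over the object by a polar mapping with a seeded random
  rotation/offset and a tiling factor (default 2, configurable — the
  repeat count of the original construction is not specified), added to
  the diffuse-only render, and then histogram-matched per channel to the
  consistent render. The matching is rank-based, so the output's pixel
  multiset equals the reference's exactly.

One fidelity limit worth stating: consistent highlights in the proxy are
position-locked to the diffuse shading (their intensities correlate, and
the displacement destroys this on every geometry), but the
*gradient-orientation* alignment between highlight and shading layers is
measurable only on the smoother geometries; for the roughest bump fields
it sits at floor even for consistent renders. The tests therefore assert
the value correlation per object and the orientation coherence as an
aggregate across objects.

## Synthetic observers

Observers follow the differencing rule for the m-alternative oddity
task: internal responses are equal-variance Gaussian draws, the target
shifted by d′, and the observer picks the sample farthest from the mean
of the remaining ones (equivalently, farthest from the grand mean). The
ground-truth link from parameter distance to d′ is linear per task, with
slopes fixed once so each difficulty grid spans roughly d′ 0–3: 40 for
GC and GD (distance in the parameter units), 0.35 for OT (distance in
log2 density), 3.2 for MP and MG (blend weight), and a constant 1 for GP
(the inconsistency is present or not; its DOI parameter does not change
the target/non-target difference). Crowd observers are attenuated by a
factor 0.7, lapse probability is 0.02, and each observer carries a
mean-preserving log-normal ability factor per task (SD 0.3 on the log
scale, 1.0 for GP) — the wide GP spread emulates the large individual
differences characteristic of highlight-consistency judgments. These
values are the package's fixed study conditions.

What passing tests on this synthetic corpus do show: the estimation and
regression machinery recovers planted quantities (sensitivities,
attenuation slopes, feature supports) from data with realistic structure.
What they do not show: agreement with human observers on real rendered
images, which requires the original behavioral dataset.

## Sensitivity estimation

`simulate_oddity_pc()` simulates the psychometric function pc(d′) by
Monte Carlo (default 10^5 trials per point, fixed seed; the decision rule
and trial count are configurable). `pc_to_dprime()` corrects a perfect
proportion to 1 − 1/(2N), then inverts a monotone shape-preserving
(Hyman-filtered spline) interpolant of the simulated psychometric
function by bisection; proportions at or below chance (1/m) map to
d′ = 0 rather than extrapolating negative sensitivity. The Monte-Carlo
function is verified against an independent quadrature oracle: for m = 3
the differencing rule reduces analytically to a single interval in the
third variable, leaving a smooth two-dimensional integral.

Laboratory aggregation computes d′ per observer and reports the mean
± SEM (sample SD / √n); crowd aggregation pools all observers' single
judgments into one proportion per condition. Unequal repetition counts
per observer are accepted.

## Texture features

Images are center-cropped to 128 × 128 (floor-on-top/left margins),
converted to CIE L\*a\*b\* against the XYZ of a matte white sphere
rendered under the same illumination proxies, and decomposed with a
complex steerable pyramid (4 scales × 4 orientations, frequency-domain,
circular boundary handling, no subsampling). Per channel, a feature
registry selects 32 statistics: 4 marginal moments, the highpass
variance, 4 near-lag autocorrelations of the cumulative lowpass (one per
scale), 16 subband magnitude means, 4 within-scale cross-orientation
magnitude correlations and 3 adjacent-scale magnitude correlations. The
exact published reduction table lives in another paper's supplement; this
registry is a documented equivalent of the same statistic families and
can be swapped without touching the rest of the pipeline. Variants:
`color_means` (3), `color_stats` (12), `ps_gray` (32), `ps_color` (96),
and `ps_gray_plus_color` — the printed parameter count for the combined
condition (48) does not equal 32 + 12, so the package implements it as a
configurable union (44 with defaults) and logs, rather than asserts, its
length.

Statistics of a constant plane are defined as 0 wherever a variance
normalization would divide by zero. Crops of object images are not
stationary; the circular boundary is nevertheless used because all
images share the same framing, so boundary effects are common to all
conditions.

The scalar condition distance is the mean over unordered image pairs of
the Euclidean distance between per-feature z-scored vectors (z-scored
against the full corpus; without standardization the pixel means would
dominate). The regression instead uses per-feature distances — the mean
pairwise absolute difference of each feature — so the model can weight
features.

## Regression

One row per task condition (dimension × object × illumination condition
× difficulty); the row's stimulus set is the anchor images plus the
difficulty's target images. Splits are stratified by task with a 4:1
ratio (largest-remainder allocation; strata under 5 rows are pooled with
a warning). The `color_means`/`color_stats` conditions use OLS; the PS
conditions use an L1 path (glmnet) controlled to exactly 18 nonzero
coefficients by bisection on λ with exact refits; when several λ achieve
support 18, 5-fold cross-validation inside the training split picks the
winner (`lambda_rule = "cv_min"`; a largest-λ rule is also provided,
since the original λ control is not fully specified). If the path jumps
over 18, the nearest support below is used and logged. Features are
standardized by glmnet on the training rows only; test R² is computed
about the test mean and can be negative. The study design uses 10,000
resampled splits; the analysis drivers default to 500 and the pipeline
smoke tests to tens, which leaves the distribution medians stable to the
precision discussed.

On a synthetic corpus where only higher-order statistics carry signal,
the condition ordering matches the study's ranking (color means worst,
PS color best). On the rendered proxy corpus itself the ranking is
weaker: the proxy manipulations move marginal statistics along with the
higher-order ones, so the 3-parameter condition is not as hopeless as on
real data, and with ~66 conditions the 96-feature lasso pays an
overfitting cost. The drivers report this honestly rather than tuning
the corpus.

## Numerical choices

* All randomness flows from a master seed; per-image and per-stage seeds
  are derived by string hashing (kept below 2^31).
* The psychometric lookup uses common random numbers across the d′ grid,
  is forced monotone (cummax) and cached per design.
* Energy checks integrate the Ward lobe numerically over the outgoing
  hemisphere; grazing directions (cos θ ≤ 0) are rejected.
* 8-bit encoding rounds after gamma-2.2 compression; histogram matching
  operates on the quantized images, which is what makes multiset
  equality exact.

## Known limitations

* The proxy renderer is not photometric; absolute d′ values on its
  images are not comparable to the original study's, only the
  machinery's recovery behavior is.
* GP exists only under illumination condition 1 (matching the original
  design, where histogram matching across different illuminations would
  introduce background cues).
* The quadrature oracle covers m = 3; the m = 4 chance level is checked
  against its binomial error instead.
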