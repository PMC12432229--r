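---
title: "Mapping coastal driftwood deposits: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping coastal driftwood deposits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(driftmapr)
```

# The problem

Stranded driftwood accumulates along Arctic coastlines in berms (shoreline-
parallel ridges) and mats (areal carpets). Mapping these deposits over
thousands of kilometres of coast from multispectral satellite imagery raises
a chain of methodological problems: multi-scene imagery must be harmonised
into annual composites; a per-pixel classifier must find sparse, small, thin
targets against spectrally similar beach sand; annual detections must be
fused into temporally stable deposits; and the resulting maps feed spatial
statistics (hotspots, group contrasts, source attribution, distance decay)
whose behaviour should be verified before they are trusted on real data.

`driftmapr` implements that chain end to end and couples it to a synthetic
coastal-scene generator with known ground truth, so every stage — and the
pipeline as a whole — is testable without any external data.

# The synthetic scene generator

`landscape_config()` / `generate_landscape()` build a projected, metric
coastal tile: a sinusoidal shoreline with sea above and land below, a sand
band along the shore, vegetation inland, river channels at configured mouth
positions, a gently sloping elevation model, a coast-parallel road and a few
buildings, and the driftwood itself.

The deposit model encodes the structure the downstream analyses assume:

* **Source attribution.** Each deposit is assigned to a river mouth with
  probability proportional to the mouth's catchment `forest_fraction` — only
  forested catchments deliver wood.
* **Distance decay.** The alongshore distance from the assigned mouth is
  drawn `Exponential(decay_scale_km)`, signed at random, and resampled until
  it falls on the coast. The default scale of 112 km puts just over 83% of
  deposit area within 200 km of a source mouth
  (`1 - exp(-200/112) = 0.832`).
* **Setting-dependent sizes.** Sizes are lognormal per setting with mean
  1,024 m² in deltaic zones (within `delta_radius_km` of a mouth), 2,670 m²
  in coastal cluster zones (within `cluster_radius_km`), and 1,031 m² in the
  background; log-scale spreads of 1.1–1.3 give the heavy right tails that
  coastal wood surveys report. Expected counts come from
  `cluster_density_per_km2` (default 0.85) and `background_density_per_km2`
  (default 0.16) applied to the area of the coastal deposition band.
* **Shapes.** A Bernoulli draw makes each deposit an elongated
  shoreline-parallel ellipse (berm, aspect 4–8) or a compact blob (mat,
  aspect 1–1.6). The stored polygon is *pixel-exact*: it follows the pixel
  boundaries of the deposit's rasterisation at truth resolution, so its
  shoelace area equals pixel count x pixel area identically.
* **Remobilisation.** With probability `remobilization_prob` (default 0.79)
  a deposit does not persist through all years; non-persistent deposits
  appear in `n_years - 1` of the years (for the default three-year setting:
  roughly one deposit in five is seen in all three years and the rest in two
  of three — which is exactly the regime in which the 0.6 presence
  threshold keeps a deposit).
* **Individual logs.** Small elongated polygons (roughly 1–8 m²) below the
  satellite minimum mapping unit. They enter class maps only at metre-scale
  resolution (`build_class_map(..., include_logs = pixel_size <= 1)`),
  mirroring the fact that a 3 m sensor cannot label features smaller than a
  pixel; they are also naturally lost wherever they cover no pixel centre.

Scenes are rendered as class spectra plus Gaussian noise, per scene and per
band distorted by a multiplicative gain and additive offset — the radiometric
jitter that histogram matching must remove. A coarse (30 m) jitter-free
reference composite and a metre-scale aerial render of the same truth
complete the data universe.

**Separation versus saturation.** When the summed alongshore footprint of
all deposits stays below 60% of the coast length, deposits are nudged apart
so they do not overlap; past that occupancy, nudging a dense packing would
pile deposits up sequentially and destroy the exponential distance
structure, so the generator leaves draws where they fall and lets deposits
merge into larger agglomerations.

**What the generator does not emulate:** clouds, sea ice, radiative
transfer, sensor PSFs, geolocation error, mixed pixels beyond linear
mixing by area, and any real coastline geometry. Passing tests therefore
demonstrate the *correctness of the machinery* and the *recoverability of
the designed statistical structure*, not performance on real imagery.

# Compositing

Annual composites are built by histogram-matching every scene to the coarse
reference (monotone quantile mapping per band, 255 empirical quantile knots
with linear interpolation) and merging overlapping scenes by the per-pixel
medoid — the observation minimising the summed Euclidean distance to all
other valid observations at that pixel. The medoid never invents spectra;
with a single contributor it is that value. Elevation is appended as a fifth
band, bicubically resampled (Keys kernel, a = -0.5) when grids differ; the
kernel reproduces linear ramps exactly away from edges.

The merge rule (medoid across contributing scenes) is a declared choice:
given scenes that have already been matched to a common reference, the
medoid is the natural robust blend and is exact in the single-contributor
case.

# Segmentation

The classifier is a compact U-Net: encoder levels with two 3x3 convolutions
each (dilation rate 2 by default — a larger receptive field at an unchanged
parameter count), batch normalisation and ReLU after every convolution,
2x2 max-pooling between levels, nearest-neighbour upsampling with skip
concatenation in the decoder (undilated), and a 1x1 convolution with a
sigmoid head. It is implemented directly in R — im2col convolutions backed
by BLAS, hand-derived backward passes (the input gradient is computed as a
transpose convolution with the flipped kernel), and Adam — and its gradients
are verified against finite differences in the test suite.

Training minimises the **Tversky loss**
`1 - (TP + eps) / (TP + alpha FP + beta FN + eps)` with soft counts. The
defaults `alpha = 0.3, beta = 0.7` penalise missed driftwood more than false
alarms, which suits the extreme class imbalance of sparse deposits; with
`alpha = beta = 0.5` the loss reduces exactly to Dice (a tested identity).
`eps = 1e-6` makes an all-empty prediction of an all-empty truth lossless.

Supporting machinery follows standard practice: areas are split
60/20/20 into train/validation/test; patches are sampled fully inside
areas; augmentation offers flips, random crop, linear and gamma contrast,
patch normalisation, Gaussian blur, piecewise-affine and perspective warps
(geometric ops applied identically to image and mask, the mask via nearest
neighbour; photometric ops to the image only); training keeps the
best-validation checkpoint and aborts on non-finite loss. Model inputs are
standardised per band before training and prediction — reflectance and
elevation live on very different scales and the first convolution
conditions poorly without it.

Prediction tiles the composite with `patch_size` patches at a 2% overlap
(stride `patch - floor(0.02 * patch)`, last patch snapped to the edge). Each
patch is binarized at 0.5 and overlapping pixels combine by union: a pixel
is driftwood if *any* contributing patch detects it. The probability raster
keeps the per-pixel maximum for diagnostics.

At desk scale the defaults are 64 px patches, two levels, eight base
filters, and around 10–25 epochs on a few dozen patches (minutes on one
CPU); the full-size configuration (512 px patches, deeper encoder, bicubic
3 m to 1 m input upsampling via `upsample_factor = 3`) is the same code.

# Fusion and filtering

Per pixel, the presence probability is the fraction of years with a
detection among years with a valid observation (never-observed pixels stay
nodata). Deposits are extracted by a seeded dual threshold: 8-connected
components of pixels at probability >= 0.5 (the shape threshold) become
deposits only if they contain a seed pixel at >= 0.6 (the presence
threshold). For three annual layers the attainable probabilities are
{0, 1/3, 2/3, 1}, so presence requires detection in at least two years —
the regime the remobilisation model is built around. 8-connectivity merges
diagonal log chains, matching the visual continuity of berms.

Three filters then apply, in a fixed order that the removal log records:
deposits with water fraction strictly above 0.2 (against a water mask built
from pixels flagged water in strictly more than 20% of observations);
deposits intersecting roads or building footprints; deposits with more than
5 interior rings (a deposit with exactly 5 holes survives). Vectorisation is
pixel-exact: polygon area equals pixel count times pixel area, interior
rings are counted from enclosed background components (4-connected, the
topological dual of the 8-connected foreground).

# Spatial statistics

Deposits aggregate onto a hexagonal grid whose *cell size* is the incircle
diameter (10 km by default) — on hexagons queen- and rook-contiguity
coincide, so the 6 edge neighbours carry row-standardised weights. Area is
split among cells at pixel fidelity; counts follow the centroid.

Global Moran's I uses the standard cross-product statistic with a
permutation pseudo-p `(1 + exceedances) / (1 + permutations)` (999
permutations by default). The local (Anselin) statistic uses conditional
permutation — the focal value held fixed, neighbours drawn from the
remaining values — with quadrant labels from the signs of the standardised
value and its lag, and hotspot clusters as contiguous high-high cells below
`alpha = 0.002`. For thin coastal study regions the analysis grid should be
restricted to the coastal strip (`grid_subset()`): open-water rows carry
structurally empty cells that dilute the field.

Group contrasts use a Mann-Whitney U on midranks with an exact two-sided
p by full enumeration whenever `choose(n + m, n)` is small enough (ties
handled by the midrank deviation), else a normal approximation with tie and
continuity corrections. The Bayesian companion is BEST — t likelihoods per
group, vague normal priors on means (SD = 1000 pooled SD), uniform priors on
SDs over (pooled/1000, pooled x 1000), shifted-exponential prior (mean 29)
on the normality parameter — sampled with JAGS (3 chains, convergence
checked by split-chain PSRF < 1.1). Because BEST alone yields no Bayes
factor, BF10 is a Savage-Dickey ratio on the standardised mean difference:
the posterior density at zero from a normal approximation to the posterior,
the prior density at zero by seeded Monte Carlo under the model priors; the
analytic JZS two-sample factor is computed alongside as a cross-check. The
95% HDI of the raw mean difference is reported, and — because a difference
of heavy-tailed group means is often better read multiplicatively — the HDI
of the log ratio of means is reported alongside when both posteriors are
positive, clearly labelled; the package does not assert which scale a given
published interval used.

Rank correlations use Spearman's rho (Pearson on midranks; exact p by full
permutation enumeration for n <= 8, else the t approximation). The Bayesian
analogue rank-transforms both variables and places a grid posterior over the
correlation using Jeffreys' approximate sampling density of r given rho with
a uniform (stretched-beta, kappa = 1) prior; BF10 is the Savage-Dickey ratio
at rho = 0 and the HDI is the 95% highest-density set of the grid. Perfect
rank correlation is a boundary case: the posterior concentrates at the grid
cap (|rho| = 0.9999), yielding an honest "overwhelming evidence" answer
rather than a numerical failure.

Catchments are vertical strips split at inter-mouth midpoints; a deposit in
a non-forested catchment is reassigned — at the catchment level — to the
forested catchment with the nearest coastal outlet along the shoreline.
Deposit-to-mouth distances are straight-line in the projected plane (the
along-coast graph is used only for catchment reassignment). The
cover-versus-distance correlation is computed on deposit cover binned by
distance (10 km bins by default): a cumulative curve is monotone by
construction, so the decaying *per-bin* cover is the quantity whose negative
rank correlation is meaningful, while the cumulative curve supplies
`fraction_within(r)`.

# Evaluation

Predictions are compared against a high-resolution reference segmentation —
in synthetic studies, the pixel-exact truth at aerial resolution, which
resolves the sub-MMU individual logs — by aggregating both into 512 m square
cells (origin aligned to the raster grid) and regressing predicted on
reference area: r², free-intercept slope (the zero-intercept slope is
reported alongside), and the overall relative bias
`100 (sum pred - sum ref) / sum ref`, also recomputed with sub-100 m²
reference deposits excluded. Size-stratified bias bins reference deposits at
100 and 10,000 m², matches predictions to reference deposits by greatest
pixel overlap, and pools unmatched predictions into a commission line. On
synthetic scenes the omitted area concentrates in the sub-100 m² bin — the
logs below the mapping sensor's minimum mapping unit — reproducing the
qualitative error structure expected of a 3 m sensor against a metre-scale
reference.

# Study configurations and problem sizes

Three documented configurations cover the package's own studies:

* `desk_run_config()` — a 3.1 x 1.5 km tile at 3 m with a 1 m aerial
  reference, three mouths with graded forest cover, elevated densities
  (40 / 8 per km² of band, so a tile holds a few dozen deposits to train
  on), well-separated spectra, a 2-level U-Net on 64 px patches for 22
  epochs. A complete run takes several minutes on one CPU.
* `decay_study_config()` — a 1,200 km coast with a single central mouth and
  around 10,500 deposits (densities 60 / 29), truth rasters at 200 m,
  no imagery. With one source the nearest-mouth distance *is* the drawn
  distance, so the empirical area-weighted decay can be checked against the
  closed-form exponential CDF (the 600 km truncation shifts the 200 km
  fraction by under half a percentage point).
* `coastal_study_config()` — the same coast with six mouths of graded
  forest cover (0.9 down to 0.12) for correlation-sign and hotspot
  structure: with multiple sources 112 km apart, exponential leakage across
  catchment boundaries weakens but does not invert the forest-cover signal.

The elevated densities in these configurations are the deliberate
scaled-down counterpart of a continental study region: they put enough
deposits into a desk-scale extent for training and for distribution-level
measurement, while all *rule-type* constants (0.6 / 0.5 fusion thresholds,
20% water rules, 5 holes, 10 km cells, 512 m evaluation cells, alpha 0.002)
keep their documented values.

# Numerical choices and degenerate inputs

* Quantile mapping enforces strictly increasing knots by an epsilon ramp;
  values outside the source range clamp to the reference extremes.
* The medoid breaks ties by first occurrence; invalid observations are
  excluded per pixel, and a pixel with no valid observation is nodata.
* Confusion ratios with empty denominators (e.g. sensitivity with no
  positives) are NaN and listed in an `undefined` field rather than silently
  dropped.
* `extract_deposits` requires `t_shape <= t_presence`; empty rasters,
  all-background labels and zero-deposit landscapes propagate as empty
  tables and `no data` flags, never as errors.
* All randomness flows from one global seed through
  `derive_seed(seed, stage)` (a fixed integer hash), so stages are
  independently reproducible and rerunning a pipeline with the same seed
  reproduces deposits bit-for-bit.
* Rasters are exchanged as ESRI ASCII grids (one plain-text file per band
  plus a JSON sidecar naming bands and CRS tag); vector layers as GeoJSON;
  configurations and manifests as YAML.

# Known limitations

* The network trains on one CPU at desk scale; no GPU path is provided, and
  the full 512 px configuration is functional but slow in plain R.
* Training is mildly stochastic beyond the seed only through BLAS reduction
  order; in practice repeated runs with one seed reproduce losses to
  rounding.
* The synthetic evaluation compares against year-one truth: deposits absent
  that year but stable across later years appear as commission, slightly
  inflating the positive bias of an otherwise accurate model.
* Spherical geometry, tides, storm-surge dynamics and wood volume are out
  of scope; all distances are planar metres.
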