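---
title: "Methods: models, estimators, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5,
                      fig.height = 4)
library(rmquant)
```

rmquant quantifies the in vitro behaviour of the minimal Rec114–Mei4
trimerization-and-DNA-binding (RM-TDB) module across four assay families:
AFM height maps of protein–DNA complexes, confocal images of nucleoprotein
condensates, EMSA titration tables, and photon-count series from
optical-trap scan movies. Every analysis stage is paired with a seeded
synthetic generator so that each estimator can be validated against known
ground truth. This vignette records the models behind the generators, the
estimators, and the numerical decisions that are not obvious from the
function documentation.

## Synthetic generators

### 2D worm-like chains

`sample_wlc_chain()` draws DNA backbones from the two-dimensional
worm-like-chain ensemble appropriate for molecules that equilibrate on the
mica surface before imaging. The chain is a polyline of `n_segments`
equal-length segments; successive turning angles are Gaussian with variance
$\ell / L_p$ (segment length over persistence length). Because
$\langle\cos\Delta\theta\rangle = e^{-\sigma^2/2}$ for a Gaussian angle,
this variance yields the 2D tangent-correlation decay

$$\langle \cos\theta(s) \rangle = e^{-s/(2L_p)},$$

the standard result for surface-equilibrated DNA (the 3D decay has
$e^{-s/L_p}$ instead; a convention that used variance $\ell/(2L_p)$ would
produce $e^{-s/(4L_p)}$ and is inconsistent with the 2D closed form, which
is why the $\ell/L_p$ variance is used). The polyline length equals the
requested contour length *exactly* by construction, which is what makes the
chain usable as a length oracle. Closed (plasmid-like) chains use a
Gaussian bridge on the turning angles (total turning $2\pi$) followed by an
iterative end-gap closure that preserves every segment length.

Defaults: persistence length 50 nm (dsDNA), rise 0.383 nm/bp so a 1000-bp
substrate measures 0.383 µm, 200 segments (1.8–1.9 nm per segment for the
substrates studied, well below the pixel size at which chains are
rendered).

### AFM scene rendering

`render_afm_scene()` builds a height map in three steps, in this order:

1. chains are stamped as 1-pixel ridges of height `dna_height` (2.5 nm
   pre-broadening, the physical diameter of B-DNA rounded up for tip
   compression effects) and convolved with an isotropic Gaussian of sigma
   `psf_sigma` (2 nm) standing in for tip broadening — the rendered
   apparent ridge height of ~0.5 nm matches what tapping-mode scans of DNA
   on mica show;
2. protein particles are added as 2D Gaussian bumps *after* the
   convolution, normalised so each bump integrates to its requested volume
   in closed form ($V = 2\pi\sigma^2 h_0$); the particle footprint is
   specified as-imaged, so the generator provides an exact analytic volume
   oracle;
3. Gaussian background noise (sd 0.05 nm, typical mica roughness plus
   instrument noise at this scan size) is added last.

What the generator does *not* emulate: scan-line artefacts, tip asymmetry,
sample drift, or height saturation. These affect real scans but none of the
estimators under test claims robustness to them.

### Condensate, titration, and decay generators

`render_condensate_scene()` renders the idealised condensate geometry the
morphometry assumes — a dense disc (core) inside a dimmer annulus (halo) on
a low background, identical in the protein and DNA channels, with
independent per-channel Gaussian noise. 100 nm/pixel matches the confocal
scans being emulated. `render_foci_scene()` renders multi-focus fields for
the thresholded foci counting used in DNA-driven condensation assays.

`simulate_titration()` generates Hill isotherms
$f(c) = c^n/(c^n + C_{50}^n)$ with optional additive noise clamped to
$[0,1]$; `simulate_decay()` / `simulate_decay_movie()` generate photon
counts around $b + I_0 e^{-kt}$ with Poisson noise by default (counts are
Poisson), or Gaussian/no noise for exactness tests.

All generators route randomness through an internal `with_seed()` so that
every draw is a pure function of (parameters, seed) and never perturbs the
session RNG.

## AFM estimators

### Background and segmentation

`estimate_background()` finds the mica plane by isodata (iterative
midpoint) thresholding. When the two classes are well separated, the
background statistics are the mean and sd of the lower class. When they are
not — the histogram is effectively unimodal because the foreground is
sparse — the estimate falls back to the median and scaled MAD of the whole
map. The fallback matters: the whole-map *mean* is biased upward by exactly
the foreground volume divided by the scan area, which propagates directly
into volume estimates.

`segment_molecules()` thresholds at $h_b + k_\sigma \sigma_b$ (default
$k_\sigma = 2$) and labels 8-connected components. The threshold statistics
come from the raw map, but the comparison is made on a lightly smoothed
copy (Gaussian sigma 1 px, mask generation only) so single-pixel noise
excursions do not serrate molecule boundaries; heights used for volumetry
are never smoothed. Components below `min_area` are dropped and components
touching the image border are excluded (their contours would be truncated).

A note on connectivity: the component labeller in the underlying imaging
library is 4-connected, which shatters diagonal pixel runs. For ordinary
blobs this is benign, but for 1-pixel skeletons it is fatal (every diagonal
step becomes its own "segment" with two spurious free ends). rmquant
therefore wraps it with a union-find pass that restores 8-connectivity and
uses that everywhere.

### Skeleton tracing and contour length

`trace_skeleton()` thins the molecule mask with the Zhang–Suen algorithm,
then removes staircase-corner pixels left by thinning (any pixel whose
skeleton neighbours form a single 8-connected component is redundant and
deleted, sequentially), prunes spur branches shorter than `prune_len`
pixels, and decomposes the skeleton into segments between junction
clusters.

The contour length is the Euclidean length of the *coordinate-smoothed*
ordered pixel path (moving average, window 5 px). The naive alternative —
summing orthogonal/diagonal pixel steps — overestimates digitized straight
lines by up to ~8% at 22.5°, an orientation-dependent bias that would
swamp the few-percent contour differences the assay is designed to detect.
Smoothing the pixel coordinates before measuring removes the staircase
while preserving real curvature at the 5-px scale (well below the 50 nm
persistence length at 1 nm/px). The raw step length is still reported as
`contour_length_steps_nm`.

Thinning retracts the skeleton from each molecule tip by about half the
local ridge width. The end-cap correction marches from each free skeleton
endpoint along the local backbone direction through the bilinearly
interpolated mask until it exits, and adds that distance minus the local
half-width (from the Euclidean distance map); for a 1-pixel-wide mask this
reduces to the textbook one-pixel-per-end correction.

Accuracy, verified in the test suite: noise-free and noisy straight rods
within 2% at all orientations, circles within 2% (flagged as cycles, no end
caps), and the sample mean over rendered worm-like chains within 5% of the
generating contour.

### Volumes, particles, stoichiometry

`integrate_volume()` computes $V = r_x r_y \sum (h_p - h_b)$ over the
molecule region *grown by a 4-pixel disc*. Growth is needed because the
segmentation threshold sits at the noise floor and clips the sub-threshold
skirt that tip broadening spreads around every molecule: for a Gaussian
bump the clipped tail at a 2-sigma-noise threshold is ~3% of the volume.
Four pixels (~2× the tip-broadening sigma) captures the skirt to well under
1%, and because heights are summed unclamped the grown ring contributes
only zero-mean noise.

`detect_particles()` finds bound proteins as pixel groups above
$h_b + 3 \times$ the apparent DNA ridge height (median skeleton height);
`classify_particles()` labels each particle `end` or `interstitial` by its
arclength distance to a free skeleton end (tolerance 20 nm, roughly the
particle footprint). `count_trimers()` implements the stoichiometry
estimate $V_d / (V_p N_p)$ with $V_p = MW/(\rho N_A)$ at the standard
protein density 1.44 g/cm³.

```{r stoichiometry}
count_trimers(stoichiometry_inputs(V_d = 303, V_p = 20.7, N_p_mean = 2.2))
```

`contour_length_stats()` groups molecules by bound-particle count and
reports group means, pairwise Student's t statistics (Welch optional), and
a Kruskal–Wallis test across groups.

## Condensate morphometry

`segment_condensate()` thresholds twice: Otsu on log intensity for the
whole condensate (log compression makes the three-level
background/halo/core histogram bimodal enough for Otsu), then mean + 2 sd
of the provisional halo pixels for the core. `core_radius()` converts core
area to the equivalent-disc radius $r = \sqrt{A/\pi}$.

`halo_thickness()` casts rays from the core centroid at 10° increments (36
rays) and measures, per ray, the distance between the core-boundary and
whole-boundary crossings, both located at subpixel precision by linear
interpolation of the bilinearly sampled mask; the condensate value is the
mean over rays. Rays that leave the image while still inside the condensate
are excluded; more than half excluded is an error rather than a biased
number. The test suite verifies that 36 rays agree with a 720-ray reference
to well within a tenth of a pixel.

`detect_foci()` thresholds at background mean + 2 sd. The default
background estimate is the median and scaled MAD of all pixels, which is
unbiased for a Gaussian background with sparse bright foci — estimates
derived from the lowest-intensity quartile alone are biased low by
construction (the mean of the lower quartile of a Gaussian sits 1.27 sd
below its centre) and would inflate focus counts. An explicit background
mask or `c(mean, sd)` can be supplied instead.

## EMSA titrations

`fraction_bound()` uses free-band depletion, $f = 1 - \text{free/total}$,
because gels of cooperative binders smear bound material over several
shifted species and the well. `c50()` locates the first upward crossing of
$f = 0.5$ per replicate and interpolates linearly; titrations that start
above 0.5 or never reach it raise classed errors
(`rmquant_presaturated_error`, `rmquant_unsaturated_error`) instead of
extrapolating. Replicates follow the reporting convention of the assay:
$n = 2$ as mean ± range (half of max − min), $n \ge 3$ as mean ± SD, and a
single experiment flagged as such.

```{r c50}
ip <- isotherm_params(c50_true = 90, noise_sd = 0, n_replicates = 1,
                      concentrations = seq(10, 1000, by = 10))
c50(simulate_titration(ip))
```

## Dissociation kinetics

`roi_trace()` averages photon counts in a fixed ROI per frame and
normalises to the first frame, making traces comparable across bridges with
different absolute protein loads (and invariant to detector gain).
`fit_dissociation()` fits $b + I_0 e^{-kt}$ by bounded nonlinear least
squares in linear space — log-linear regression is biased by Poisson noise
at low counts — with start values from a log-linear pre-fit and $k \ge 0$.
Non-decaying series short-circuit to $k = 0$ with a `flat` flag rather than
chasing an unidentifiable amplitude. On Poisson data at the default signal
level the estimator is unbiased with a per-trace spread of ~12%, so
measured rate dispersion across bridges substantially above that reflects
biology, not fitting noise.

`waiting_time()` is the automated surrogate for manually calling the
binding start: the first frame exceeding mean + 5 sd of the pre-binding
window. `focal_growth_profile()` averages normalised intensity against time
since detection and separates flat from growing profiles by the
terminal/initial ratio.

```{r decay, fig.alt = "Exponential decay fit to a simulated photon-count trace"}
dp <- decay_sim_params(k_true = 0.034, i0 = 50, background = 2, seed = 1)
mv <- simulate_decay_movie(dp, frame_size = 16)
fit <- fit_dissociation(roi_trace(mv, c(1, 16, 1, 16)))
autoplot(fit)
```

## I/O and the pipeline

`write_image()` stores height maps, images, and scan series as multi-frame
32-bit float TIFF. Values are affinely mapped to $[0,1]$ with the
scale/offset recorded in a YAML sidecar, because baseline TIFF readers do
not agree on out-of-range float samples; physical pixel sizes, frame
intervals, and channel names live in the sidecar too. `read_image()`
returns the typed object the sidecar declares and refuses to guess a pixel
size when none is available.

`run_pipeline()` chains the AFM stages (simulate → segment/trace/classify →
stoichiometry) under a validated `rm_config()`. Every random draw derives
from the single config seed, results carry a 12-character config hash, and
CSV outputs begin with a `# units:` line plus provenance comments. Problem
sizes in the shipped defaults (10 + 10 molecules on 512×512 scans) are
chosen so the full pipeline runs in well under a minute; they are analysis
choices of this package, not properties of the assays.

## Reproducibility

Every generator takes an explicit seed; repeated calls are bit-identical
and leave the session RNG untouched. The acceptance script
(`scripts/acceptance.R`) regenerates every target scene from scratch with
seeds derived from a single command-line seed.
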