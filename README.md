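# rmquant

Quantification toolkit for in vitro studies of the minimal Rec114–Mei4
trimerization-and-DNA-binding (RM-TDB) module: a 2:1 Rec114–Mei4
heterotrimer that binds DNA, bridges duplexes, and drives the assembly of
large nucleoprotein condensates. The package covers the four assay families
such studies rely on, and pairs every estimator with a seeded synthetic
generator so each stage is testable against known ground truth.

## What it measures

**AFM volumetrics and contour tracing** (`afm_*`, `trace_skeleton`,
`integrate_volume`, …). Height maps of protein–DNA complexes are
segmented above the mica background, thinned to 1-pixel skeletons
(Zhang–Suen), decomposed at branch points, and measured:

- contour length from the coordinate-smoothed skeleton path plus an
  end-cap correction (straight rods and circles recover truth within 2% at
  any orientation);
- molecular volume `V = rx * ry * Σ(h − h_b)` over the (grown) molecule
  region;
- bound-particle detection and end/interstitial classification;
- trimer stoichiometry `V_d / (V_p · N_p)` with `V_p = MW / (ρ N_A)`.

The worked example from the studied system: a bound-minus-free volume
difference of `V_d = 303 nm³`, a per-trimer volume of `20.7 nm³`, and an
average of `2.2` particles per molecule give `303 / (20.7 × 2.2) = 6.65` —
approximately seven trimers per binding site:

```r
count_trimers(stoichiometry_inputs(V_d = 303, V_p = 20.7, N_p_mean = 2.2))
#> # A tibble: 1 × 5
#>     V_d   V_p N_p_mean trimers_per_site trimers_rounded
#>   <dbl> <dbl>    <dbl>            <dbl>           <int>
#> 1   303  20.7      2.2             6.65               7
```

**Condensate morphometry** (`segment_condensate`, `condensate_morphology`,
`detect_foci`). Core radius by the equivalent-disc formula
`r = sqrt(A/π)`; halo thickness by 36 rays at 10° increments with subpixel
boundary interpolation; condensation foci counted and integrated above a
`mean + 2·sd` background threshold.

**EMSA titrations** (`fraction_bound`, `c50`). Fraction bound by free-band
depletion `1 − free/total`; the apparent affinity `C50` by linear
interpolation at the first upward crossing of 0.5, with replicate
aggregation following the assay convention (n = 2 → mean ± range,
n ≥ 3 → mean ± SD, n = 1 flagged).

**Single-molecule kinetics** (`roi_trace`, `fit_dissociation`,
`waiting_time`, `focal_growth_profile`). ROI photon-count traces from
optical-trap scan movies, normalised to the first frame; dissociation rates
by bounded nonlinear fitting of `b + I0·exp(−kt)`; waiting times to first
binding; focal growth profiles split into flat vs growing.

**Synthetic generators** (`sample_wlc_chain`, `render_afm_scene`,
`render_condensate_scene`, `simulate_titration`, `simulate_decay`). Seeded,
oracle-grade generators: 2D worm-like chains with exact contour length,
AFM scenes with analytically normalised particle volumes and a tip-broadening
PSF, disc + halo condensate scenes, Hill isotherms, Poisson photon decays.

## Worked example

Simulate a protein-bound DNA molecule as an AFM scan and measure it end to
end:

```r
library(rmquant)

# a 358 nm worm-like chain carrying two 145 nm^3 protein particles,
# rendered at 1 nm/pixel with tip broadening and background noise
ch <- sample_wlc_chain(wlc_params(contour_length = 358), seed = 4)
ch$x <- ch$x - mean(ch$x) + 256
ch$y <- ch$y - mean(ch$y) + 256
ps <- list(particle_spec(0.05, volume = 145, footprint_sigma = 4),  # near an end
           particle_spec(0.60, volume = 145, footprint_sigma = 4))  # interstitial
rp <- afm_render_params(image_size = 512, background_sd = 0.05, seed = 42)
hm <- render_afm_scene(list(ch), ps, rp)

bg <- estimate_background(hm)
bg
#> <background_model> h_b = 0.0009806 nm, sigma_b = 0.05094 nm (100% of pixels)

segs <- segment_molecules(hm, bg)
kept <- segs[segs$kept, ]
mol <- analyze_molecule(hm, kept$region[[which.max(kept$area_px)]], bg)
mol
#> <molecule_trace> label 1: contour 346.4 nm, 1 segment(s), 0 branch node(s)
#>   particles: 2

mol$particles[, c("particle", "volume_nm3", "position", "end_distance_nm")]
#> # A tibble: 2 × 4
#>   particle volume_nm3 position     end_distance_nm
#>      <int>      <dbl> <chr>                  <dbl>
#> 1        1       56.8 interstitial           146.
#> 2        2       42.0 end                     14.8
```

And a titration:

```r
tab <- simulate_titration(isotherm_params(c50_true = 90, noise_sd = 0.03,
                                          n_replicates = 3, seed = 7))
c50(tab)
#> C50 = 85.2 nM +/- 16 nM (mean +/- sd, n = 3)
```

`plot_height_map(hm, mol)`, `plot_titration()`, and `autoplot()` methods
for fits, traces, and morphometry objects provide quick visual checks.

## Design notes

Tabular data flows through tibbles with dplyr/purrr verbs, plotting through
ggplot2, and model objects expose `tidy()`/`glance()`; images and height
maps are lightweight matrix-backed S3 classes. Image I/O uses 32-bit float
TIFF with YAML sidecars carrying physical metadata. The methods vignette
(`vignettes/methods.Rmd`) documents the models behind the generators, the
estimators, and the numerical decisions (WLC angle variance, smoothed
contour metric, end-cap correction, volume-region growth, robust
background estimation, foci thresholding).
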