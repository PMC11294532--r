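---
title: "Estimating fractional tree cover from phenology-realigned composite series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fractional tree cover from phenology-realigned composite series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Fractional tree cover (FTC) is the percentage of a pixel's ground area
covered by tree canopy. At moderate resolution (250 m) most pixels are
mixtures of trees, herbaceous vegetation and bare ground, so FTC has to be
regressed from the temporal behavior of the pixel's spectral signal rather
than classified. The discriminating signal is phenological: tree canopies
flush and senesce quickly and hold a **sustained NDVI plateau** through the
middle of the growing season, while grasses and crops green up and brown
down gradually, tracing a **rounded, parabola-like curve**. Late spring and
late summer — about six weeks before and after the growing-season midpoint —
are where the two curve families separate most.

That contrast is only usable if all pixels are looked at in the same
phenological frame. Growing seasons start at very different calendar dates
across latitudes and hemispheres, so each pixel's annual series of 46
eight-day composites is first **realigned**: the midpoint of its growing
season is detected on a multi-year mean NDVI curve and the whole annual
series is circularly rotated so that the midpoint lands on composite 23
(day of year 185–192, the center of the calendar year). After realignment
just twelve numbers — NDVI, red and SWIR 2.1 µm reflectance at four phases
(annual NDVI maximum, annual NDVI minimum, and the fixed composites 17 and
29, i.e. DOY 137–144 and 233–240) — summarize the pixel-year, and a
feedforward network maps them to percent tree cover.

## Pipeline stages and their parameters

### Preprocessing

Composites flagged cloud, snow or water are set to fill. NDVI is
`(NIR − red)/(NIR + red)` clipped to [−1, 1]. The NDVI series is then made
gap-free and smoothed toward its **upper envelope**, because residual cloud
and shadow contamination biases optical greenness downward, never upward.

The smoother works on the 46-composite circle: gaps are bridged by circular
linear interpolation, the series is projected onto its first **16 Fourier
harmonics**, observations falling more than **0.05 NDVI** below the fit are
discarded as cloud-dark outliers, milder negative residuals are raised to
the fit, and the loop repeats until the largest capping adjustment is below
**0.005 NDVI** (at most 10 passes). Two properties motivated the harmonic
projection over a penalized spline:

* on gap-free input the fit is a **circulant linear operator**, so
  smoothing commutes *bit-exactly* with circular rotation of the input —
  the realignment invariance tests can then demand bit-identical results
  rather than results within a tolerance;
* a projection is exactly **idempotent**, so re-smoothing already-smooth
  data is a no-op.

The harmonic order was fixed at 16 by requiring that a noise-free
double-logistic tree curve (logistic rate 2 per composite, the steepest
seasonal transition the generator produces) is reproduced within 0.01 NDVI
everywhere; lower orders visibly clip the plateau shoulders. The 0.05
dark-outlier margin is large enough that projection ripple (< 0.01 on
realistic curves) never triggers it, and small enough that a single
cloud-contaminated composite (typically 0.1–0.4 NDVI dark) is caught in the
first pass. Red, NIR and SWIR series are only gap-filled by circular linear
interpolation, not envelope-smoothed: reflectance outliers are two-sided,
and the features read these bands at phases located on the smoothed NDVI.
Pixels with fewer than **8 clear composites** are unusable: 8 points
support only a crude seasonal shape and anything below that is
extrapolation. The 500 m SWIR band is co-registered to the 250 m grid by
nearest-neighbor duplication of each coarse cell into its 2×2 fine cells.

### Growing-season detection and realignment

The reference curve is the per-composite mean of the smoothed NDVI over all
available years (detection is done **once per pixel** and the resulting
shift applied to every year, so inter-annual feature differences reflect
the surface, not re-detection jitter). Its amplitude (max − min) routes the
pixel:

* **amplitude ≥ 0.2** — seasonal branch: maximal *circular* runs of
  composites above the half-amplitude threshold are found (circularity
  handles Southern-Hemisphere seasons that straddle the new year); with
  several runs the one with the highest mean daytime land-surface
  temperature wins, or the longest run (ties to the earliest start) when no
  LST is available; the midpoint is the central composite of the winning
  run, `start + floor((len − 1)/2)` — a deterministic tie rule for
  even-length runs.
* **amplitude < 0.2** — evergreen branch: the midpoint is the circular mean
  of the composite indices of the 18 highest reference NDVI values (ties
  broken toward earlier composites; exact half-composite means round toward
  the smaller index). Below amplitude 0.02 the curve carries no usable
  timing signal and the shift defaults to zero (midpoint 23).

Realignment is a circular rotation by a whole number of composites — the
data's native resolution. No interpolation means rotation is a permutation:
band sums, minima, maxima and value multisets are exactly conserved, and a
pixel simulated with a known integer phenology shift realigns to the
bit-identical series.

### Training references from categorical maps

Categorical forest maps at finer resolution are aggregated to fractional
cover (percent of tree-labeled subcells per 250 m cell; cells with under
half their subcells valid become nodata). Several products are combined
into the per-pixel mean `TC_RefMean` and the per-pixel mean absolute
deviation `MAE_Ref`. Training pixels are dropped when `MAE_Ref` exceeds
10 % (strictly — the boundary is kept), when the year has fewer than 25
clear composites, when a seasonal pixel's growing season is shorter than 12
composites (96 days, the nearest whole-composite reading of "three
months"; evergreen pixels are exempt since they have no run), or when the
land cover is water, permanent snow/ice or barren. `MAE_Ref` is computed
**per pixel**: a per-map regional error could not drive a per-pixel
exclusion. Because targets pile up at 0 % and 100 %, those two integer bins
(round-half-up binning) are down-sampled to caps under a fixed seed; all
other bins are kept in full.

### The regressor

The network is fixed at 12–400–200–100–50–25–1 with ReLU activations and a
linear output clipped post hoc to [0, 100] — clipping keeps the gradient
path simple and only the value range is prescribed. The training recipe is
this package's own: per-feature z-score standardization, targets scaled to
[0, 1], mean-squared-error loss, Adam (initial rate 1e-3 for the full-size
network), mini-batches of 1024, at most 100 epochs, early stopping with
patience 5 on a 10 % validation split, and **plateau decay** — the learning
rate halves after every 3 consecutive epochs without validation
improvement. The decay step matters for small training sets, where a fixed
step size leaves the optimizer orbiting the optimum instead of settling
into it; He-normal initialization and all random draws derive from one
seed, so training is reproducible. Finally, predicted maps set pixels whose
annual maximum NDVI is below 0.35 to 0 % cover (strict `<`): surfaces that
never green up are non-tree by construction, whatever the regressor
extrapolated.

The annual-minimum phase is located as the argmin of the smoothed realigned
NDVI. The phase locator is deliberately the simplest deterministic choice;
snow-brightened winters can displace it, which is one reason winter-heavy
pixels are filtered from training by the clear-observation rule.

### Validation

Validation samples drawn by stratified random sampling are weighted by the
inverse inclusion probability `ω_i = K_h / k_h` (stratum population over
sample size), and

* `MAE = Σ ω|pre − ref| / Σ ω`,
* `RMSE = √(Σ ω(pre − ref)² / Σ ω)`,
* `ME = Σ ω(pre − ref) / Σ ω`.

The agreement regression (ordinary least squares of reference on
prediction) and its R² (squared Pearson correlation) are reported
unweighted alongside the weighted error metrics — a deliberate split, since
a weighted R² admits several inequivalent definitions. Range subsets (e.g.
the 15–95 % band that removes the dominant pure bins) select on the
**reference** value, boundaries included. Product intercomparison uses the
per-pixel mean difference over shared valid years, dividing by the count of
years actually valid at that pixel rather than the nominal period length.

## What the synthetic scenes do and do not emulate

The generator builds each pixel as a two-endmember linear mixture:
double-logistic NDVI endmembers for tree (steep rates, plateau) and
herbaceous (shallow rates, parabola) vegetation, red/SWIR reflectance
decreasing affinely with greenness, and NIR derived so the endmember NDVI
is self-consistent. **Reflectance mixes linearly; NDVI is computed after
mixing** — the physically defensible order, and the source of the mild
nonlinearity the network must invert. Per-pixel integer phenology shifts,
Gaussian reflectance noise, i.i.d. per-composite cloud gaps and a seasonal
LST curve complete the scene. Truth fractions default to integer percent so
that quota-based subcell labeling (`round(f·F²/100)` tree subcells per
cell, seeded placement) lets zero-error aggregation recover the truth
*exactly*, which turns the aggregation-closure property into an exact test.
Pseudo high-resolution categorical products add per-product
omission/commission noise; the last product also suppresses tree labels
below a 30 % "tall dense" threshold, mimicking products that only map tall
closed canopy.

Not emulated: radiative transfer, BRDF and sun-sensor geometry, snow
phenology, spatially correlated clouds, geolocation error and real product
co-registration artifacts. Passing the synthetic suite therefore
demonstrates the pipeline's internal correctness — realignment invariance,
aggregation closure, recoverability of a known mixing law under noise and
gaps — not accuracy on real satellite archives, which depends on error
sources the generator deliberately leaves out.

## Verification problem sizes

The package's own verification runs at desk scale: the end-to-end
parameter-recovery experiment uses a 64×64 scene (4096 pixels, reflectance
noise 0.01, cloud probability 0.1), a 75/25 pixel split and the full-size
network; the noise-free mixing-inversion check trains on 45,000 synthetic
mixtures and scores 5000 held-out ones; the metric-equivalence property
checks 1000 random weighted tables against a loop oracle at 1e-12. These
sizes were chosen so every property that can be exact is tested exactly and
every stochastic property has comfortable margin over its threshold.

## Known limitations

* Single-year scenes exercise the multi-year averaging path trivially; the
  reference-curve code accepts any number of years, but inter-annual
  stability of the features is only as good as the realignment-once design.
* The evergreen midpoint relies on small NDVI ripples; under heavy noise it
  degrades to the identity shift, which is also its degenerate-amplitude
  default.
* The GeoTIFF codec reads/writes the uncompressed, pixel-interleaved
  subset of TIFF this pipeline produces; it is not a general TIFF reader.
* Training uses plain MSE with no regularization beyond early stopping;
  with very unbalanced or very noisy references the histogram balancing
  caps are the only defense against degenerate fits.
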