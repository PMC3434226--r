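---
title: "Mapping mitochondrial cytochrome redox state from Raman hyperspectral images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping mitochondrial cytochrome redox state from Raman hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanredox)
```

## The measurement and the model

Green (532 nm) excitation falls inside the Q/β absorption bands of heme
proteins, so live-cardiomyocyte Raman spectra are dominated by resonance
scattering from hemes: the b- and c-type cytochromes of respiratory
complexes II/III and cytosolic myoglobin. Two facts make a semi-quantitative
redox readout possible:

* **Reduced hemes dominate.** Oxidized cytochromes scatter roughly an order
  of magnitude more weakly than reduced ones, so the 750 cm⁻¹ (heme
  breathing, mainly c-type) and 1125 cm⁻¹ (mainly b-type) band intensities
  track the *amount of reduced cytochromes*, not the total pool.
* **Oxymyoglobin provides an internal reference.** The ν10 band at
  1640 cm⁻¹ comes from oMb only (it vanishes on deoxygenation, shifting to
  1603 cm⁻¹). When the amount and conformation of oMb are constant, the
  ratios I750/I1640 and I1125/I1640 cancel focus and concentration effects
  and become comparable across cells and cell regions; I750/I1125 reads the
  balance between the c- and b-type pools.

The pipeline implements that readout for rectangular hyperspectral maps
(one spectrum per pixel on a shared wavenumber axis): per-pixel baseline
subtraction, cell masking, band-averaged intensity and ratio images,
self-organizing-map (SOM) clustering of the pixel spectra, per-cluster
bootstrap summaries with Kruskal–Wallis/Dunn statistics, and a separate
normalization and lag/decline analysis for single-spot H₂O₂ time courses.

Because no public hyperspectral data exist for this experiment, the package
ships a first-class synthetic generator whose phantoms are *calibrated* so
that their noiseless band ratios equal the published per-cluster values;
every end-to-end claim the package makes is a parameter-recovery statement
on those phantoms.

## Baseline subtraction

Autofluorescence appears as a broad, smooth pedestal under sharp Raman
lines. `subtract_baseline()` uses iterative modified-polynomial fitting:
fit a polynomial (default order 5, orthogonal basis, shared across all
pixels of a map), clip the working spectrum to `min(y, fit + s)` where `s`
is the residual standard deviation, and repeat until the fitted baseline
stops changing (tolerance 1e-6 of the spectrum maximum, cap 100
iterations). The `+ s` term is the essential numerical choice: clipping at
the bare fit makes the polynomial sink to the *lower envelope* of the noise
band and ride the broad hump formed by the overlapping 1585/1603/1640 cm⁻¹
lines, which we measured to inflate I750/I1640 by about 7% even on
noiseless input; noise-aware clipping keeps the residual ratio bias at the
1–2% level and converges in ~70 iterations. The decomposition is exact
(`corrected + baseline` reproduces the input bit-for-bit), corrected values
are *not* clipped at zero (so band means stay unbiased), and a converged
column is frozen so a spectrum gets the same baseline whether it is fitted
alone or inside a map.

Cell masking is scale-free by construction: a pixel is "cell" when its
summed corrected intensity over 1400–1700 cm⁻¹ exceeds 25% of the 99th
percentile of the per-pixel sums. A quantile rule was chosen because
absolute counts depend on exposure and focus; multiplying the whole cube by
any positive constant leaves the mask unchanged.

## Band quantification

A band is a window `center ± 8 cm⁻¹`; the default quantifier is the window
*mean* of the corrected intensities, for images and ratios alike. The
published analysis describes band-averaged images but "ratios between
peaks" without defining "peak"; we use one consistent quantifier because it
keeps ratios comparable to the calibrated phantom ground truth and is more
noise-robust than a per-pixel maximum (the two agree within 5% for isolated
narrow lines on a fine axis — a property test). Ratio pixels with a
non-positive denominator are flagged invalid and excluded from every
summary rather than imputed.

## SOM clustering

Pixel spectra (baseline-corrected, restricted to 600–1800 cm⁻¹, *not*
per-spectrum normalized — absolute intensity is what isolates dim boundary
pixels) are clustered with a self-organizing map: 6 units on a 1-D chain,
plain Euclidean distance, random initial attribution of pixels to units
(seeded), prototypes updated as neighborhood-weighted member means with a
Gaussian neighborhood whose radius decays linearly 2 → 0 over the first 10
iterations. After the neighborhood vanishes the procedure is literally
"reattribute each spectrum to its nearest prototype until no more than 1%
change in one iteration" — the published convergence rule, asserted exactly
as configured, with the per-iteration reassignment trace kept in the
result. Ties break to the lowest unit index; a unit emptied during the
plain phase is reseeded on the worst-fit spectrum (otherwise prototypes can
collapse onto each other and merge well-separated groups). With the
neighborhood radius forced to zero throughout, the fit reduces to
Lloyd-style batch k-means, which the tests hold against a brute-force
partition-search optimum on instances of at most 12 pixels × 3 channels.

Six units against three interior compositions is deliberate surplus,
mirroring the published choice of N = 6 interpreted as four categories (two
rod regions, one round region, boundary). In the phantoms the surplus units
are absorbed by the partial-volume edge pixels, whose large intensity
spread makes them the most profitable place for extra prototypes — the same
mechanism that produced the low-intensity "boundary" cluster in the real
maps.

## Statistics

Cluster summaries are means with seeded percentile-bootstrap 95% CIs
(10,000 resamples). Group comparisons use the tie-corrected Kruskal–Wallis
test (χ² approximation, k−1 df; the all-identical degenerate case returns
H = 0, p = 1 by convention) followed by Dunn's pairwise z statistics on
mean ranks with pooled tie-corrected rank variance and Bonferroni
adjustment — the conservative default customarily bundled with Dunn's test;
the source analysis names no adjustment. How the published CIs were
computed is unknowable from the text; the percentile bootstrap is our
declared choice (distribution-free, scale-free). Pixels are treated as
independent observations, as the source analysis implicitly does; under
spatial autocorrelation this inflates significance — a documented
limitation, not corrected here.

## The synthetic generator

Components are sums of Lorentzian lines (half-width 6 cm⁻¹) at the
assignment-table positions; within-component relative amplitudes are free
phenomenological parameters fixed once in the shipped library, because only
between-band ratios matter downstream and those are set by calibration.
Constraints honoured by construction: reduced:oxidized cytochrome c
integrated intensity = 10 (configurable); oMb has the 1640 cm⁻¹ line and no
750/1125 lines; dMb lacks 1640 and carries the 1603 cm⁻¹ deoxygenation
marker; dMb/metMb carry only minor 750/1125 components. The resting
mixture holds myoglobin at 7× the total cytochrome concentration (the
literature lower bound) with 20% of each cytochrome pool reduced, which
puts the dithionite-reduction response at ~5.5× on the 750/1125 bands
(published: at least 3–4×).

`calibrate_region_concentrations()` inverts the linear mixing model — a
2×2 linear solve on the same render-and-quantify path the pipeline uses —
so that a region's noiseless I750/I1640 and I750/I1125 equal requested
targets to machine precision, erroring with the binding constraint when a
target would need a negative concentration.

**An internal inconsistency in the published table.** For any single
mixture, per-pixel arithmetic forces
I750/I1125 = (I750/I1640)/(I1125/I1640), and per-pixel noise can only
*inflate* a mean ratio. The published rod columns violate this:
0.47/0.42 = 1.12 against a printed 0.89 (center), 0.38/0.40 = 0.95 against
1.05 (periphery, ordering reversed). The three rows cannot all be
reproduced by any homogeneous mixing model. The shipped presets therefore
match the I750/I1640 and I750/I1125 rows exactly and let I1125/I1640 be
implied (≈0.53 center, ≈0.36 periphery, ≈0.19 round — the round column is
internally consistent). The corresponding acceptance check on the center
I1125/I1640 value is left failing on purpose: it records the discrepancy
instead of hiding it.

Phantom geometry: the rod cell is a rectangular footprint (default
20 × 40 px map, 1 µm/px) with a 1-px partial-volume edge (per-pixel
brightness uniform on 0.3–0.7 of the region value, emulating the laser spot
overlapping the cell boundary), a 2-px subsarcolemmal periphery rim, and an
interfibrillar center; the round cell is a disc with a single interior
composition, per the published finding that round cells show no internal
spectral separation. Relative region brightness is 1 / 0.9 / 0.7
(center/periphery/round). Noise is additive Gaussian with
σ = √(signal + 100) per channel — a shot-noise proxy — on top of an
exponentially decaying fluorescence pedestal (~30% of the strongest peak,
amplitude jittered ±10% per pixel); the counts scale (10⁴ counts for the
strongest line) reflects a CCD well at 15 s line exposures. All randomness
is seeded; a phantom is a deterministic function of (spec, seed).

The H₂O₂ simulation renders the resting single-spot mixture with the
cytochrome pool flat for a 10 min lag and then declining exponentially to
40% at 20 min, the oMb amplitude to 70% — the published ~60% / ~30%
end-point declines with the cytochrome loss twice the oMb loss. The decline
multiplies the *whole* cytochrome pool (reduced and oxidized), reflecting
irreversible oxidative damage to the heme structures; a reduced-only
decline cannot reach a 60% band loss while a constant oxidized pool keeps
scattering. Sampling every 2.5 min is a declared choice (the published
figures do not print their spacing); control drift defaults to zero. The
lag estimator — the latest time at which the mean t0-normalized series is
still ≥ 0.9 — is likewise our own definition of what the published figures
eyeball; the threshold is configurable and the estimate moves by at most
one sampling interval between 0.9 and 0.85 on defaults.

## What the phantoms do and do not show

Passing recovery tests on these phantoms demonstrates that the pipeline's
estimates are unbiased at realistic signal-to-noise under the linear mixing
model, that the clustering recovers planted spatial structure, and that the
statistics behave nominally (the Kruskal–Wallis type-I error is held at
0.05 ± 0.02 under a simulated null). They do not exercise: non-linear
detector response, cosmic-ray spikes, wavenumber miscalibration, spatially
correlated noise or focus drift, overlapping-band deconvolution, or
biological heterogeneity within a region — real maps have all of these, and
the boundary cluster of a real cell is a mixture, not a scaled copy, of its
neighbors' spectra.

## Problem sizes and seeds

The shipped analyses use the published map sizes (20 × 40 and 20 × 60 px,
600–1800 cm⁻¹ at 1 cm⁻¹), 10 replicate cells per time-course condition,
10,000 bootstrap resamples, and 2,000 null simulations for the type-I-error
property; the SOM convergence rule is 1% with a 500-iteration cap. Every
stochastic stage takes an explicit seed, and rerunning any stage with the
same configuration reproduces its output bit-for-bit.
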