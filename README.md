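# ramanredox

Semi-quantitative mapping of mitochondrial cytochrome redox state in live
cardiomyocytes from resonance Raman hyperspectral images.

Under 532 nm excitation, the Raman spectrum of a cardiomyocyte is dominated
by heme scattering. Reduced b- and c-type cytochromes of respiratory
complexes II/III carry the 750 and 1125 cm⁻¹ bands, and oxidized forms
scatter ~10× more weakly, so those band intensities track the *reduced*
pools; oxymyoglobin contributes the ν10 band at 1640 cm⁻¹ and serves as an
internal reference. The pipeline computes, per pixel of a hyperspectral
map,

I₇₅₀/I₁₆₄₀, I₁₁₂₅/I₁₆₄₀, I₇₅₀/I₁₁₂₅

on baseline-corrected spectra (noise-aware iterative modified-polynomial
fitting, order 5), masks cell pixels with a scale-free quantile rule,
clusters the masked spectra with a self-organizing map (6 units, Euclidean
distance, random initial attribution, convergence when ≤1% of spectra
change cluster per iteration), and reports per-cluster ratio means with
seeded percentile-bootstrap 95% CIs plus Kruskal–Wallis/Dunn statistics.
A second entry point normalizes single-spot H₂O₂ time courses to their
pre-treatment values (or point-wise to the 1640 cm⁻¹ reference) and
estimates the lag and end-point declines of the band intensities.

Because the original cell data are not deposited, the package ships a
synthetic generator — a Lorentzian heme component library with
rod/round-cell phantom geometries — whose region concentrations are
*calibrated* so the noiseless band ratios equal the published per-cluster
values; all end-to-end validation is parameter recovery on those phantoms.
See the methods vignette (`vignettes/raman-redox-mapping.Rmd`) for the
model, the numerical choices, and a documented internal inconsistency in
the published ratio table.

## Worked example

```r
library(ramanredox)

ph  <- make_cell_phantom(phantom_spec("rod"), seed = 1)   # 20 x 40 px rod cell
res <- run_map_analysis(ph$map, pipeline_config(som = som_config(seed = 1)))
match_clusters_to_regions(res$clusters, ph$truth)
#>          region cluster  coverage
#>      rod_center       6 0.7544643
#>   rod_periphery       3 1.0000000
subset(res$summaries$r750_1640, cluster %in% c(6, 3))
#>   cluster   n      mean        lo        hi reliable
#> 3       3 160 0.3841284 0.3836635 0.3845971     TRUE
#> 6       6 169 0.4755564 0.4751266 0.4759734     TRUE
```

The interfibrillar center cluster recovers a mean I₇₅₀/I₁₆₄₀ of 0.476 and
the subsarcolemmal periphery 0.384 — the phantom's calibrated ground truth
is the published 0.47 and 0.38, so the full pipeline (baseline, mask, SOM,
bootstrap summary) reproduces the planted redox contrast to ~1%. The same
run yields I₇₅₀/I₁₁₂₅ of 0.898 (center) and 1.066 (periphery), and a
round-cell phantom gives an interior I₇₅₀/I₁₆₄₀ of 0.192 — the ~50% drop
relative to the rod regions that distinguishes energetically compromised
round cells.

```r
sim <- simulate_h2o2_course(h2o2_spec(), seed = 3)
tc  <- run_timecourse_analysis(sim$treated, sim$control)
round(100 * tc$declines$treated)   #  750 1125 1640
#>   750 1125 1640                  #   60   61   30
tc$lag
#> [1] 10
```

The simulated oxidative-stress course declines ~60% on the cytochrome
bands at 20 min — twice the oMb-band decline — after a 10 min lag, which
the threshold-crossing lag estimator recovers exactly.

The same analyses, written as a narrative workflow that exchanges
instrument-style long-format text files, live in `analysis/`
(`01_simulate_phantoms.R`, `02_map_analysis.R`, `03_timecourse_analysis.R`;
run in order from the repository root; tables land under `results/`).

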