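# mcti — tissue oxygenation and blood volume from multispectral images

`mcti` (Monte Carlo tissue imaging) estimates physiological parameters —
oxygenation *s* (the fraction of oxygen-bound hemoglobin) and blood volume
fraction *v*<sub>hb</sub> — from multispectral reflectance images of the kind a
multispectral laparoscope records during surgery. Monitoring these
parameters indicates whether an anastomosed bowel segment or a
transplanted organ is adequately perfused.

The inverse problem (band reflectances → physiology) is solved by
simulation-based learning:

1. **Forward model.** Tissue is an *n*-layer slab; each layer carries
   {*v*<sub>hb</sub>, *s*, *a*<sub>mie</sub>, *b*, *g*, *n*, *d*}. Hemoglobin is the only
   visible-range absorber:

   μ<sub>a</sub>(λ) = *v*<sub>hb</sub> · *c*<sub>hb</sub> · (*s*·ε<sub>HbO₂</sub>(λ) + (1−*s*)·ε<sub>Hb</sub>(λ)) · ln 10,

   with reduced scattering μ′<sub>s</sub>(λ) = *a*<sub>mie</sub>(λ/500 nm)<sup>−*b*</sup> and
   μ<sub>s</sub> = μ′<sub>s</sub>/(1−*g*). Diffuse reflectance spectra are computed with a
   multi-layered Monte Carlo photon-packet simulation (MCML-style C++
   kernel: Henyey–Greenstein scattering, Fresnel boundaries, Russian
   roulette), validated against an independent implementation and the
   classic slab benchmark (R<sub>d</sub> = 0.0974 for μ<sub>a</sub>=10, μ<sub>s</sub>=90 cm⁻¹,
   g=0.75, d=0.02 cm).
2. **Camera adaptation.** Spectra are integrated over a band system
   (r<sub>k</sub> = Σ<sub>λ</sub> b<sub>k</sub>(λ) r(λ)); zero-mean Gaussian noise with σ = r<sub>k</sub>/SNR
   models camera and motion nuisances; features are normalized
   ℓ1 → −log → ℓ2 so constant illumination changes cancel.
3. **Inversion.** A random forest (10 trees, depth 9, min 10 samples per
   leaf) jointly predicts (*s*, *v*<sub>hb</sub>) per pixel. SVR and k-NN comparators,
   and the training-free modified Beer–Lambert linear fit as baseline, are
   included, along with an in-silico robustness suite (noise sweeps,
   domain switch, sample-size curves) and a synthetic phantom generator
   that exercises the full imaging path (dark/flatfield correction,
   specular masking, per-pixel maps, ROI time series).

## Worked example

```r
library(mcti)

table  <- default_extinction_table()          # hemoglobin extinction, c_hb = 120 g/L
ranges <- load_model_ranges("colon")          # three-layer colon tissue model
grid   <- seq(470, 680, 10)                   # 22 wavelengths (nm)
bands  <- boxcar_band_system(470, 680, 10, 10, grid)

# forward-simulate labeled reflectance spectra (desk-sized here)
train <- simulate_labeled_dataset(ranges, 300, grid, table, n_photons = 2e3, seed = 1)
test  <- simulate_labeled_dataset(ranges, 100, grid, table, n_photons = 2e3, seed = 2)

# train the forest on normalized features with SNR-10 noise, then evaluate
report <- method_comparison(train, test, bands, snr = 10,
                            methods = c("rf", "beer_lambert"),
                            hp = rf_hyperparams(seed = 1), seed = 3, table = table)
print(report[, c("method", "target", "median_abs_error", "q25", "q75")], digits = 3)
#>         method target median_abs_error   q25   q75
#> 1           rf      s            10.35 5.640 15.70
#> 2           rf   v_hb             0.87 0.443  1.58
#> 3 beer_lambert      s            10.49 4.235 16.88
```

Errors are median absolute deviations in percentage points with
interquartile bounds. At this deliberately tiny scale (300 training
samples, 2×10³ photons) the forest only ties the Beer–Lambert baseline on
oxygenation — accuracy improves steadily with training samples and
photons (see the vignette's problem-size discussion) — while already
estimating blood volume fraction to under 1 pp, which the linear baseline
cannot estimate at all.

Per-pixel estimation on an image stack, after flatfield correction and
specular masking:

```r
corrected <- flatfield_correct(image)             # (stack − dark)/(flatfield − dark)
keep <- corrected$valid_mask & !specular_mask(corrected$reflectance)
map  <- estimate_map(corrected$reflectance, model, bands, valid_mask = keep)
```

`synthesize_phantom()` builds multispectral stacks with known ground
truth so this path is testable without camera data, and
`inst/cli/mcti.R` exposes `simulate` / `train` / `estimate` / `phantom`
subcommands for shell use.

The bundled extinction table
(`inst/extdata/hemoglobin_extinction_synthetic.csv`) is a synthetic
spline reconstruction of the standard published hemoglobin compilation
(see its header and the vignette); substitute a measured table with
`load_extinction_table(path)`.

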