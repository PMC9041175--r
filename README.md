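# vispec

A hardware-free computational stack for low-cost visible-range transmission
spectrophotometers of the kind built from a 288-pixel, 10-bit CMOS
line-sensor chip and a single warm-white LED. Everything such a device's
software has to do after the photons are gone — dark correction, frame
accumulation, single-beam absorbance, instrument characterisation, and
analytical calibration statistics — is implemented here against a **seeded
virtual instrument**, so the full pipeline can be developed, tested and
validated without any hardware on the bench.

Intended users: people building or validating open-hardware
spectrophotometers, and analysts who want reproducible, scriptable
absorbance/calibration workflows for bioanalytes (vitamin B12, phosphate,
enzyme-coupled H2O2 assays and similar).

## The model in brief

**Absorbance.** For sample frame *S*, blank (baseline) frame *B* and
optional dark frame *D*, per pixel *p*:

    A(p) = log10( (B(p) − D(p)) / (S(p) − D(p)) )

mapped to wavelength by a monotone polynomial pixel→wavelength calibration
and restricted to the 450–750 nm working range. Nonpositive corrected
signals give `NA` with a `nonpositive_signal` flag (never clamped); pixels at
the ADC full scale are flagged `saturated`.

**Virtual instrument.** Expected counts are
`dark_mean + scale(exposure) · slit_blur(source(λ) · T(λ))` with Beer–Lambert
transmission `T(λ) = 10^(−Σ εᵢ(λ) cᵢ l)`, a Gaussian 15 nm FWHM slit
function, additive Gaussian dark noise (RMS 11.5 counts by default), and
10-bit quantization with clipping. Identical seeds give byte-identical
frames.

**Figures of merit.** RMS dark noise (mean of per-pixel n−1 standard
deviations), dynamic range `(2^bits − 1)/RMS`, SNR `mean/sd` at the pixel
nearest a query wavelength (dB as `10·log10`), and wavelength accuracy as the
mean |Δλ| between measured and reference emission-peak maxima (argmax or
parabolic sub-pixel refinement).

**Calibration statistics.** Unweighted OLS of response on concentration;
`R² = 1 − SSE/SST`; `LOD = 3.3·S_d/b` and `LOQ = 10·S_d/b` where `S_d` is the
standard error of the intercept and `b` the slope; intra-/inter-day RSD
tables; inverse prediction with below-LOD/LOQ annotation; and a studentized
leave-top-level-out check for the end of the linear range.

## Worked example

```r
library(vispec)

# published vitamin-B12 series (3-24 ppm, read at 550 nm), shipped as a fixture
fit <- fit_calibration(example_series("b12"))
fit
#> <calibration_fit>
#>   A = 0.01074 + 0.007254 * c   (n = 6, dof = 4)
#>   se(intercept) = 0.006016, se(slope) = 0.0004033, residual sd = 0.007511
#>   R^2 = 0.988
#>   LOD = 2.7 ppm, LOQ = 8.3 ppm

# an unknown at A = 0.120
conc <- predict_concentration(fit, 0.120)
sprintf("c = %.2f ppm [%s]", conc, attr(conc, "annotation"))
#> "c = 15.06 ppm [ok]"

# characterise the (virtual) detector from 50 dark + 50 illuminated frames
m  <- instrument_model()
dk <- acquire_frames(m, 50, role = "dark",     seed = 42)
bl <- acquire_frames(m, 50, role = "baseline", seed = 43)
fom_report(dk, bl, m$calibration, snr_lambda = 540)
#> <fom_report>
#>   RMS dark noise: 11.48 counts (10-bit ADC)
#>   dynamic range:  89.1 (19.5 dB)
#>   SNR @ 540 nm:  49.0 (17 dB) [ok]
```

The fit reproduces the published validation figures for this device class
(R² 0.988, LOD 2.7 ppm, LOQ 8.3 ppm); the simulated detector reproduces the
characterised dark-noise RMS (11.5 counts) and hence the dynamic range of
89. The SNR at 540 nm depends on the source model's intensity at that
wavelength, here roughly half maximum.

## Command line

```sh
Rscript inst/cli/vispec simulate  --config instrument.json --out frames/ --seed 7 --n 50 --role dark
Rscript inst/cli/vispec absorb    --sample s.csv --baseline b.csv --dark d.csv --out abs.csv --at 550
Rscript inst/cli/vispec fom       --frames frames/ --out fom.json
Rscript inst/cli/vispec calibrate --input inst/extdata/b12_calibration.csv --out fit.json
Rscript inst/cli/vispec monitor   --config instrument.json --at 550 --n 100 --seed 7 --out readings.csv
```

All stochastic commands require an explicit `--seed`; every artifact embeds
the seed and a config hash, so outputs are exactly regenerable.

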