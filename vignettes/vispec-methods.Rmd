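---
title: "vispec: methods, defaults and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vispec: methods, defaults and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(vispec)
```

## Scope and the measurement model

`vispec` models the data path of a miniature single-beam transmission
spectrophotometer: a warm-white LED shines through a 10 mm cuvette onto a
grating and a 288-pixel CMOS line sensor read out by a 10-bit ADC. The
device itself measures three kinds of frames — dark (no light), baseline
(blank: source through the empty path) and sample — and everything else is
computation. This package implements that computation and replaces the
hardware with a seeded simulator so the whole chain is testable.

The absorbance of a sample frame $S$ against a baseline $B$ with dark $D$
is, per pixel $p$,

$$A(p) = \log_{10}\frac{B(p) - D(p)}{S(p) - D(p)},$$

the standard single-beam definition $A = -\log_{10} T$ with the blank as
the reference intensity. Device-class software of this kind typically does
not publish its formula; we adopt this one as the only defensible choice for
a transmission instrument with a re-measurable blank. Provenance metadata on
every `absorbance_spectrum` records which frames (and how many accumulated
repeats) produced it, supporting the recommended practice of re-measuring
the baseline periodically.

Three numerical policies follow from honesty about noise at low signal:

* **Nonpositive corrected signals are undefined, not clamped.** If
  $S - D \le 0$ or $B - D \le 0$ the point is `NA` with flag
  `nonpositive_signal`. Clamping to a small positive number would silently
  bias every downstream statistic (RSD at low absorbance is large *because*
  the signal is noisy — that must stay visible).
* **No dark frame means $D = 0$.** The sensor has no shutter, so a dark
  measurement requires turning the source off; when it is omitted the
  residual dark offset biases low absorbances toward zero. This is a
  documented limitation, not an error.
* **Accumulation averages counts before the log.** Whether accumulation
  should average before or after the log transform is genuinely open for
  this device class; averaging counts first is the variance-optimal choice
  for additive detector noise and is what `accumulate()` does, exclusively.

Frames of unequal exposure are never combined implicitly: expected counts
scale linearly with exposure time, so combining them is a unit error, and
`dark_correct()`/`accumulate()` refuse.

## Pixel-to-wavelength calibration

Line-sensor chips ship factory-fitted polynomials from pixel index to
wavelength; the pitch is not constant. The default map is a fifth-order
polynomial over pixels 0–287 chosen so that

* the map is strictly increasing and covers 340 nm (the chip's lower limit)
  up to the near-infrared end of the chip's range,
* the adjacent-pixel step across the 450–750 nm working range stays within
  1.5–3.0 nm and averages ≈ 2.2 nm, matching the published per-peak steps
  (2.09–2.34 nm) for this sensor family.

We prioritised reproducing the working-range pixel pitch over hitting the
nominal 850 nm upper chip limit exactly (the default map tops out near
893 nm); everything above 750 nm is outside the working range and never used
for absorbance. Real units should load their own factory coefficients
(`wavelength_calibration()`, `read_calibration_json()`).

Single-wavelength queries (`absorbance_at()`) use linear interpolation
between the two bracketing grid points: the optical resolution (15 nm FWHM)
is much coarser than the ≈ 2.2 nm pixel pitch, so higher-order interpolation
cannot add information. An exact grid hit returns the stored value; an
undefined bracketing point yields `NA` with flag `undefined_neighbor`.

## The virtual instrument: a stated world

The simulator is the fixture generator for every other module, so its
defaults are fixed once, from the characterised operating conditions of the
reference device class, and are not tuned afterwards:

| parameter | default | why |
|---|---|---|
| pixels / ADC | 288 px, 10 bit (full scale 1023) | sensor family geometry |
| dark RMS | 11.5 counts | published dark-noise characterisation |
| dark mean | 30 counts | typical ADC offset for this sensor class (repository choice) |
| slit FWHM | 15 nm Gaussian | stated spectral resolution; line shape unstated, Gaussian assumed |
| reference exposure | 200 µs | exposure used in the published characterisation |
| source | 450 nm/20 nm blue band + 560 nm/120 nm phosphor band, amplitudes 1 : 0.55 | warm-white LED; ratio puts 550 nm at ≈ half maximum, the documented operating point |
| peak counts | 950 at reference exposure | ≈ 93 % of full scale: bright but unsaturated, ≈ 500 counts at 540–550 nm |
| path length | 1.0 cm | standard 10 mm cuvette |

Acquisition computes expected counts as
`dark_mean + (exposure/200 µs) · peak_counts · blur(source·T)/max(blur(source))`,
adds Gaussian noise of sd `dark_rms`, rounds, and clips to the ADC range.
Noise is a single additive Gaussian: the published characterisation reports
only dark-noise RMS and a per-pixel SNR, both of which this model
reproduces. A Poisson shot-noise term can be switched on
(`detector_model(shot_noise = TRUE)`) but is off by default so the stated
noise figure is the whole noise budget. The true emission curve of the
reference LED exists only as a figure, so the two-band source is a
repository choice, not a measured spectrum.

What the simulator deliberately does **not** emulate: stray light,
wavelength-dependent quantum efficiency, temperature drift, cuvette Fresnel
losses, and absolute radiometry. A green test therefore establishes that the
*computational* chain is correct under the stated noise model — not that a
physical unit meets these numbers.

Concentration units (ppm, µM, mmol/L) are opaque labels throughout; the
package never converts between them, mirroring how such assays are reported.

## Figures of merit: conventions

* Standard deviations use the $n-1$ denominator throughout.
* RMS dark noise is the mean over pixels of the per-pixel sd across frames.
* Dynamic range is the raw ratio $(2^{bits}-1)/\mathrm{RMS}$. Datasheet
  practice for this device class labels that raw ratio "dB" (1023/11.5 "="
  89 dB) while using $10\log_{10}$ for SNR (77.6 → 19 dB, not the
  $20\log_{10}$ amplitude convention, which would give 37.8). That labeling
  is internally inconsistent, so `dynamic_range()` and `snr()` always return
  **both** the raw ratio and the $10\log_{10}$ dB value and let the reader
  pick the convention.
* SNR at a query wavelength uses the **nearest pixel**, not interpolation —
  the natural reading of "the signal at 540 nm" for a pixelated sensor. A
  zero sample sd returns an infinite ratio with flag `zero_noise` rather
  than an error (it is the honest limit for constant frames).
* Peak localisation defaults to `argmax` on the pixel grid: peak-position
  differences below half an adjacent-pixel step are not resolvable, and the
  grid method is what the half-step reasoning in published wavelength
  accuracy analyses assumes. Parabolic sub-pixel refinement through the
  maximal pixel and its two neighbours is available; on a boundary maximum
  it falls back to argmax with flag `boundary_fallback`. On noiseless
  15 nm-blurred Gaussian lines the parabolic error is below 0.1 nm
  (verified numerically in the test suite).

## Calibration statistics

`fit_calibration()` is unweighted OLS (no weighting scheme is documented for
this device class), with blank (zero-concentration) points included when
present. The detection limits are

$$\mathrm{LOD} = 3.3\,S_d/b, \qquad \mathrm{LOQ} = 10\,S_d/b,$$

with $S_d$ the OLS standard error of the intercept,
$S_d = s\sqrt{1/n + \bar{x}^2/S_{xx}}$, $s^2 = SSE/(n-2)$. Published
validation tables for this device class are reproduced **only** by this
assignment (3.3 → LOD, 10 → LOQ, the ICH-style convention with
LOQ/LOD = 10/3.3); the accompanying running text in at least one source
swaps the two labels, which its own tables contradict. We follow the tables
and the convention. The 10/3.3 ratio between LOQ and LOD is exact by
construction and asserted to machine precision in the tests.

One shipped fixture (`example_series("peroxidase")`, the H2O2/HRP assay) has
published R²/LOD/LOQ that cannot be recomputed from its printed values under
any documented fitting choice (all levels: R² 0.991, LOD 17.0; linear region
only: R² 0.997, LOD 6.3 — neither matches the printed 0.995/1.9/5.9). It is
therefore shipped as a worked-example fixture only and asserted nowhere; its
top level (264 µM) is a natural demonstration for `linear_range_check()`.

Precision follows the standard validation grouping: **intra-day** RSD is the
RSD over replicates within a day, averaged across days; **inter-day** RSD is
the RSD over day means. Levels with one replicate (or one day) are flagged
`NA` for the affected column and excluded from the column average. RSD is
undefined at zero mean and flagged rather than computed. Where an "Average"
row spans levels with unequal day counts, the per-level RSDs are averaged as
they stand — the most defensible reading of a table format that does not
specify further.

`linear_range_check()` refits without the highest level and computes the
externally studentized residual of that level's mean response under the
reduced fit ($t$-distributed with $n-2$ degrees of freedom under the null).
The default threshold 3 gives a false-positive rate below 5 % for designs
with ≥ 5 retained points; with very few levels the $t$ tails are fat and the
threshold is conservative in the other direction — the threshold is
configurable for that reason.

Reporting rounds R² to 3 decimals and LOD/LOQ to 1 decimal and RSD to 2, the
conventions of published validation tables; unrounded values are always
carried alongside.

## Interchange formats and the CLI

Frames, absorbance spectra and calibration series travel as UTF-8/LF CSV
with `# key=value` header metadata; calibration maps and instrument configs
as JSON with coefficients lowest-order first. Integer counts round-trip
losslessly; reals are written with 6 significant digits. The CLI
(`vispec_cli()`, launcher in `inst/cli/`) exposes `simulate`, `absorb`,
`fom`, `calibrate` and `monitor` — the last reproducing the
"continuous measurement at one wavelength" operating mode — and refuses any
stochastic operation without an explicit `--seed`; artifacts embed the seed,
a config MD5 and the package version. A serial-port device emulator was
considered and dropped: no wire protocol is documented for the reference
hardware, so an invented one would test nothing (the CSV contract is the
interchange boundary instead).

## Numerical choices and degenerate inputs

* Slit blur is an FIR Gaussian kernel truncated at ±4σ on a 0.5 nm grid with
  edge padding; it conserves total signal to well under 1 % away from range
  edges (tested against direct quadrature).
* A perfect (zero-residual) calibration line is legitimate input: R² = 1 and
  LOD = LOQ = 0, with `summary.lm`'s perfect-fit warning suppressed at that
  one call site.
* Nonpositive slope: the fit is returned, LOD/LOQ are `NA` with flag
  `not_applicable` (a colourimetric assay with decreasing response should be
  re-parameterised, not silently given negative limits).
* Entirely unusable baselines (every pixel at or below dark) abort
  absorbance computation with an error, since no pixel can be referenced.
* Parabolic peak refinement with a non-concave triple (plateau maxima) falls
  back to argmax with a flag instead of extrapolating a vertex.

## Known limitations

* The additive-Gaussian noise model understates noise at high signal if the
  real detector is shot-noise limited; the toggle exists but is off in the
  stated world.
* Wavelength accuracy against a *real* reference spectrograph cannot be
  established here — the RGB fixture tests recovery of *simulated* truth
  only, to grid resolution.
* `monitor` simulates drift-free samples; kinetics (time-varying
  concentration) can be composed from the building blocks but has no
  dedicated generator.
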