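---
title: "Amplitude-mode-model dispersion analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplitude-mode-model dispersion analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RamanAMM)
```

## The model

Resonance Raman spectra of conjugated polyenes such as psittacofulvins
are dominated by the backbone C–C and C=C stretching bands. In a sample
containing a distribution of chromophores — conformers with different
effective conjugation lengths, or pigment molecules coupled through
π–π contact — each excitation wavelength preferentially enhances the
sub-population whose electronic absorption it matches. Long-conjugation
chromophores absorb at lower energy and vibrate at lower wavenumber, so
the *apparent* band centers drift upward as excitation energy rises.
The amplitude mode model (AMM) quantifies this drift without resolving
individual sub-populations. For each dispersing mode the squared
frequency ratio $(\tilde\nu_{nR}/\tilde\nu_{0R})^2$ is formed, where
$\tilde\nu_{0R}$ is the band position at the lowest excitation energy
used (the reference) and $\tilde\nu_{nR}$ its position at excitation
energy $E_L$. The product over the dispersing modes equals twice the
effective electron–phonon coupling constant,
$\prod_n (\tilde\nu_{nR}/\tilde\nu_{0R})^2 = 2\bar\lambda$, and the
dispersion rate

$$D = \frac{\Delta \prod_n (\tilde\nu_{nR}/\tilde\nu_{0R})^2}{\Delta E_L}$$

is estimated as the ordinary-least-squares slope of the per-excitation
products on excitation energy. A single chromophore gives $D = 0$;
strongly interacting, planarized systems give large $D$.

Assumptions worth keeping in mind: the model treats band centers only
(intensities and widths carry resonance information the AMM ignores);
the product regression assumes the drift is approximately linear in
$E_L$ over the measured range; and the reference point enters every
ratio, so an error at the reference excitation propagates into the
whole series.

### Units and diagnostics

`fitDispersion()` regresses on the cm⁻¹ energy axis by default and
reports the slope on both axes: `D_cm` (units cm, i.e. per cm⁻¹ of
excitation energy) and `D_eV` = `D_cm` × 8065.544 (units eV⁻¹).
Dimensional analysis of the defining ratio — a dimensionless quantity
over an energy — fixes these units; published values for comparable
systems occasionally print other unit strings for the same numbers.
R², the slope *p*-value (two-sided *t*, *n* − 2 degrees of freedom) and
the significance flag are invariant under the axis choice, which is why
either axis may be used for the computation. No multiple-testing
correction is applied across bands: the per-band regressions are
descriptive companions to the single product-rule test.

"Model fit error" is implemented as $100 \cdot \mathrm{SE}(D)/|D|$, the
relative precision of the slope. This is a standard relative-error
measure and reproduces the qualitative behaviour expected of dispersing
versus non-dispersing samples (a few-percent error when the trend is
strong; far above 100 % when $D$ is indistinguishable from zero). When
$|D|$ is numerically zero the quantity is undefined and reported as
`NA`.

The sample-related significance flag compares each band's center range
across the series against a 3 cm⁻¹ threshold: multi-laser set-ups with
per-window calibration are typically accurate to ≤ 3 cm⁻¹ in the blue
and better in the red, so smaller shifts cannot be attributed to the
sample. The threshold is an argument (`shiftThreshold`), not a
constant.

### Which bands enter the product

By default the product runs over the two pigment bands (`CC`, `CC2`) —
the strongest bands and the only ones that disperse in this system.
`fitDispersion()` accepts any list of `BandTrack`s, so additional modes
can be included where they demonstrably disperse.

## Preprocessing

The chain mirrors common practice for feather spectra and is applied in
the order crop → smooth → baseline → normalize:

| stage | default | notes |
|---|---|---|
| crop | 900–1800 cm⁻¹ | contains the doublet, the keratin bands, and two peak-free margins |
| Savitzky–Golay | window 11 pts, order 3 | `signal::sgolayfilt`; reproduces cubics exactly, endpoints by the built-in truncated-window fit |
| baseline | AsLS, λ = 10⁵, p = 0.01, ≤ 50 iterations | Whittaker smoother with asymmetric weights; polynomial (order 3, iteratively clipped) as alternative |
| normalization | (I − min)/(max − min) | exact 0/1 bounds, idempotent |

The smoothing and baseline defaults are this package's choices: typical
robust settings for ~1 cm⁻¹-gridded spectra, all exposed as arguments.
An AsLS fit that hits the iteration cap attaches a
`convergence_warning` attribute instead of failing, since a slightly
unconverged baseline is still usually usable and the caller should
decide.

Two workflow variants interleave averaging differently: the
multi-feather survey normalizes replicates before averaging, while the
excitation-series workflow averages raw replicates and normalizes the
mean (replicates within one excitation share acquisition conditions, so
their raw mean is meaningful; across feathers it is not). Both are
available; `runSurvey()` and `runDispersion()` apply the matching
default.

## Peak localization and credibility gates

`findBand()` takes the grid maximum in the window (ties resolved to the
lower wavenumber, for determinism) and refines it with the parabola
through the maximum and its two neighbours; on noiseless symmetric
peaks the refinement error is far below half the grid spacing. The
alternative `lorentzian_ls` method fits a Lorentzian plus linear offset
by Levenberg–Marquardt (`minpack.lm`), initialized at the grid maximum,
and falls back to the parabolic estimate (flagged `fallback_argmax`)
when the fit fails. A maximum on the window edge is flagged `edge` and
never treated as a located band.

Peak height is measured above the local linear trend of the window.
The signal-to-noise ratio divides that height by a robust noise level:
1.4826 × MAD of the window residuals after removing a short (7-point)
running median. The running-median detrend matters: it makes the noise
estimate insensitive to the band's own smooth profile, so broad bands
in narrow windows are not penalized.

`detectPsittacofulvin()` declares a spectrum pigmented only when both
doublet bands are interior maxima with SNR ≥ 5 **and** FWHM ≥ 6 cm⁻¹.
The width gate is physical: polyene stretching bands are ≳ 10 cm⁻¹
wide, while the sharp maxima that survive smoothing of a noisy
keratin-only spectrum have widths near the smoothing kernel
(~4 cm⁻¹). Without the gate, smoothed white-feather spectra are
misclassified often (the smoothing also shrinks the high-frequency
noise floor that the SNR denominator measures); with it, the
false-detection rate on simulated white feathers drops to the
percent level while pigmented spectra are detected essentially always.

Excluding particular excitations (pre-resonant lines at the ends of the
absorption envelope, or lines with known artefacts) is a per-run
configuration recorded in the `BandTrack`, not a hard rule:
`defaultExclusions()` provides the set {351, 785 nm pre-resonant;
448 nm spurious} used in replication runs.

A note on labels: the keratin windows are identified by wavenumber
(`keratin_1006` … `keratin_1670`) rather than by amide-band names,
because the common literature labels for the 1240/1670 cm⁻¹ pair are
not used consistently; the wavenumbers are unambiguous.

## The synthetic generator

The generator exists so that every stage of the analysis can be tested
closed-loop against exact ground truth. `simulateSpectrum()` sums
Lorentzian bands (the standard Raman line shape) at configured centers,
optional first overtones at twice the pigment centers, a polynomial
baseline, a broad Gaussian emission background, and i.i.d. Gaussian
noise with a seed that never touches the caller's RNG stream.

Three dispersion mechanisms are available:

* **none** — a single chromophore; the yellow-like condition.
* **linear** — pigment centers move linearly with excitation energy at
  per-band slopes $s_b$; for small shifts the implied dispersion rate
  has the closed form $D \approx 2\sum_b s_b/\tilde\nu_{0,b}$, which
  `linearConfig(D_true)` inverts (splitting the rate equally between
  the two bands) to produce calibration fixtures with a known target.
* **ensemble** — the red-like condition: a mixture of chromophore
  sub-populations, each with band centers, an absorption maximum and a
  Lorentzian resonance width Γ. The apparent center at excitation
  energy $E_L$ is the resonance-weighted mean
  $\sum_i w_i \Gamma^2 / ((E_L - E_{abs,i})^2 + \Gamma^2) \cdot c_i$
  (normalized), which reproduces the qualitative physics: whichever
  member is closest to resonance dominates the spectrum.

The red-like preset uses three equally weighted members with C=C
centers 1524/1534/1544 cm⁻¹, C–C centers 1131/1137/1143 cm⁻¹,
absorption maxima at 680, 500 and 380 nm and Γ = 2200 cm⁻¹. These are
calibration choices, not measured values: the absorption maxima bracket
the krypton/solid-state excitation range (648–375 nm) so the apparent
centers rise monotonically across the whole series, the C=C spread
produces a ~16 cm⁻¹ tracked range, and the resulting dispersion rate
(~3.4 × 10⁻⁶ cm ≈ 2.8 × 10⁻² eV⁻¹) sits in the regime reported for
moderately interacting conjugated systems. The quantitative mapping
from conjugation length to band position and absorption energy is
outside the model's scope, so the ensemble is explicitly synthetic.

Default acquisition noise is σ = 0.02 on unit-height bands (SNR ≈ 50);
the yellow-like preset lowers SNR and adds an emission amplitude of 0.5
(centered 1300 cm⁻¹, width 900 cm⁻¹ — a featureless hump, as emission
is judged only qualitatively). A hue panel of 26 records (6/7/7/6 per
hue) with a +4 cm⁻¹-per-hue-step trend and 2 cm⁻¹ scatter emulates a
survey of the magenta→yellow gamut.

What the generator does **not** emulate: cosmic-ray spikes, wavenumber
miscalibration between instruments, detector etaloning, resonance
intensity profiles, non-Lorentzian (Fano or Voigt) line shapes, and any
spatial correlation of noise in hyperspectral grids. Passing tests
therefore demonstrate the correctness of the estimators under the
stated statistical model, not robustness to every instrument artefact.

## Numerical choices and degenerate inputs

* Interpolation is linear only (no splines), to avoid ringing next to
  narrow bands; extrapolation is refused.
* Descending wavenumber axes are silently reversed; duplicate
  wavenumbers are an error (ambiguity, unlike ordering, cannot be
  resolved silently).
* An exactly flat product response reports $D = 0$ with `NA` R²/p/fit
  error rather than relying on floating-point residue.
* Zero variance in excitation energy is a singular design and errors.
* A constant spectrum cannot be 0–1 normalized (error), and fewer than
  3 included excitations cannot support a dispersion fit (error).
* `ensembleBandCenter()` falls back to the population weights, with a
  flag, if every resonance factor underflows.
* The product at the reference excitation is exactly 1 by construction,
  and `D_eV`/`D_cm` = 8065.544 is asserted by the class validity to
  10⁻⁹ relative.

## Problem sizes used by the test-suite and acceptance script

Single spectra are 901 points (900–1800 cm⁻¹ at 1 cm⁻¹). Excitation
series use the 13 standard laser lines with 3 replicates; null-law and
recovery properties use 100 seeds each, with the recovery study run at
the track level (10 excitations spanning 15 400–26 700 cm⁻¹, 0.5 cm⁻¹
center jitter, D_true = 3.5 × 10⁻⁶ cm). Hyperspectral fixtures are
8 × 8 grids. These sizes make the whole suite run in well under a
minute while keeping every statistical claim testable; all of them
scale up through the same interfaces.

## Known limitations

* The analyzer tracks one peak per window; overlapping sub-bands are
  not deconvolved, and overtones are generated but deliberately ignored
  by the analysis.
* The AMM product-rule slope is a descriptive coupling measure; no
  attempt is made to extract microscopic electron–phonon parameters
  from it.
* The emission index is an operational background level, not a
  calibrated fluorescence quantum yield.
* With ~10 excitation points the slope's standard error — and hence the
  fit-error percentage — is itself uncertain; treat small differences
  in fit error between samples as qualitative.
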