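# RamanAMM

Amplitude-mode-model analysis of resonance Raman frequency dispersion in
pigmented feathers.

## The problem

Parrot feather colours from magenta to yellow are produced by
psittacofulvins — linear conjugated polyenal pigments. An *in situ* Raman
spectrum of a pigmented barb shows two strong bands from the conjugated
backbone, the C–C stretch near 1130–1145 cm⁻¹ and the C=C stretch near
1525–1550 cm⁻¹, on top of fixed β-keratin matrix bands (1006, 1240, 1450,
1670 cm⁻¹). When the sample hosts a *distribution* of chromophores with
different effective conjugation lengths, tuning the excitation wavelength
into different parts of the absorption band resonance-enhances different
sub-populations, and the apparent band positions shift with excitation
wavelength. This shift — **frequency dispersion** — is diagnostic of
chromophore diversity (conformational disorder, molecule–molecule
interactions); a single chromophore shows none.

RamanAMM is for spectroscopists who want to quantify that dispersion from
excitation-series measurements. It implements the amplitude mode model
(AMM) bookkeeping: for each tracked vibrational mode, the ratio of its
wavenumber at excitation energy *E<sub>L</sub>* to its value at the lowest
excitation energy used (the reference, ν̃₀ᴿ), and the product rule

∏ₙ (ν̃ₙᴿ / ν̃₀ᴿ)² = 2λ̄,

where 2λ̄ is the effective electron–phonon coupling constant at that
excitation energy. The **dispersion rate**

D = Δ∏ₙ(ν̃ₙᴿ/ν̃₀ᴿ)² / ΔE<sub>L</sub>

is the ordinary-least-squares slope of the product against excitation
energy, reported both per cm⁻¹ of excitation energy (units cm) and per eV
(units eV⁻¹; the two are tied by 1 eV = 8065.544 cm⁻¹), with R², the
two-sided slope *p*-value, and a model fit error defined as
100·SE(D)/|D|. Band shifts larger than 3 cm⁻¹ across the series (the
combined spectral and calibration resolution of typical multi-laser
set-ups) are flagged as sample-related.

Around that core the package provides:

* S4 containers (`RamanSpectrum`, `ExcitationSeries`, `RamanHyperMap`,
  `BandTrack`, `DispersionFit`) with plain-text delimited I/O;
* the standard preprocessing chain — crop to 900–1800 cm⁻¹,
  Savitzky–Golay smoothing, asymmetric-least-squares or polynomial
  baseline correction, 0–1 normalization, replicate averaging;
* band localization (parabolic argmax refinement or Lorentzian least
  squares), doublet detection against keratin-only (white) spectra, and
  band tracking across an excitation series with recorded exclusions;
* band-sum hyperspectral maps (±50 cm⁻¹ sum filters at ~1140 and
  ~1540 cm⁻¹) and a per-pixel emission index;
* a hue-trend summary (Spearman rank correlation of band position with
  the magenta < red < orange < yellow hue scale) for multi-feather
  surveys;
* a synthetic-data generator (`simConfig()`, `simulateSpectrum()`,
  `simulateSeries()`, `simulateHuePanel()`, `simulateHypermap()`) whose
  outputs carry exact ground truth, so the whole chain is testable
  end to end without any instrument data.

## Worked example

Simulate a red-like feather region — a three-member chromophore ensemble
whose apparent band centers shift with excitation energy — measure it at
the 13 standard laser lines in triplicate, preprocess, and fit the AMM
with the usual exclusions (351 and 785 nm pre-resonant, 448 nm spurious):

```r
library(RamanAMM)

sim    <- simulateSeries(redLikeConfig(noiseSd = 0.02, seed = 1),
                         replicates = 3)
series <- ExcitationSeries(lapply(sim$series@spectra,
                                  function(s) normalize01(smoothSavgol(s))))
res    <- runDispersion(series, exclude = c(351, 448, 785))
res$fit
#> Amplitude-mode-model dispersion fit
#>   n = 10 excitations; bands: CC, CC2
#>   D = 3.443e-06 cm  (2.777e-02 eV^-1)
#>   product regression: R2 = 0.987, p = 8.33e-09
#>   fit error: 4.1%
#>   max band shift: CC 9.65, CC2 16.20 cm-1; sample-related (> 3 cm-1): yes
```

The C=C band walks 16.2 cm⁻¹ across the excitation series and the
product-rule values climb linearly with excitation energy — the signature
of multiple chromophores. The fitted D = 3.44 × 10⁻⁶ cm matches the
generator's exact truth (3.4438 × 10⁻⁶ cm) to 0.1%. The first
per-excitation products (reference 648 nm, where the product is exactly
1):

```r
head(ammProducts(res$fit), 4)
#>   excitation_nm  E_invcm     E_eV  product
#> 1           648 15432.10 1.913336 1.000000
#> 2           594 16835.02 2.087276 1.005771
#> 3           568 17605.63 2.182820 1.009935
#> 4           532 18796.99 2.330530 1.014967
```

A yellow-like region (single chromophore over an emission background)
run through the same pipeline gives |D| two orders of magnitude smaller
and `significant = FALSE`. For measured data, point `runDispersion()` at
a manifest of spectrum files, or start from an externally fitted peak
table with `readPeakTable()` + `tracksFromTable()` + `fitDispersion()`.

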