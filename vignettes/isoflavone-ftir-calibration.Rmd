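---
title: "Methods: FT-IR multivariate calibration of soy isoflavone glycosides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FT-IR multivariate calibration of soy isoflavone glycosides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirquant)
```

## The problem and the model

Soy supplements owe their activity to three isoflavone glycosides —
daidzin, genistin and glycitin — whose mid-IR bands overlap with each
other and with the carbohydrate-dominated extract matrix. No single band
can be integrated; instead the whole fingerprint region is regressed on
concentration by partial least squares with one response (PLS1).

The physical assumption is Beer–Lambert linearity: absorbance at every
wavenumber is linear in the concentrations of all absorbing components,
so a preprocessed spectrum `x` relates to a property `y` (mg of analyte
per 500 µl extract aliquot — the package's fixed concentration unit)
through a linear functional. PLS1 estimates that functional from
calibration data by extracting latent variables that maximize covariance
with `y`. Fitting is NIPALS with the weight vector of each component given
in closed form by the deflated `X'y`, so no iteration, tolerance or random
initialization exists anywhere in the fit; models are bit-reproducible.
Columns are mean-centered but not variance-scaled: spectral variables
share units, and row-wise SNV already handles scale distortions. This is
standard chemometric practice for spectra.

## Preprocessing operators and their defaults

Applied in recipe order, default `offset → savgol(9, 3, 1) → snv →
select_regions`:

* **Offset correction** subtracts each spectrum's mean intensity,
  completing baseline removal even for narrow sub-regions.
* **Linear anchor baseline** (optional) subtracts the line through the
  spectrum's values at user-chosen anchor wavenumbers. It is the
  documented, deterministic replacement for the interactive baseline
  tools of commercial instrument software, whose algorithms are
  unpublished; anchors default to the grid endpoints.
* **Savitzky–Golay** smoothing/derivatives over a 9-point window. The
  window width is the one fixed methodological constant of the workflow;
  the polynomial order is not specified anywhere authoritative, and cubic
  is chosen as the common chemometric default that supports first and
  second derivatives. Derivatives are returned in physical units (per
  cm⁻¹ to the derivative power). Edge points are computed with asymmetric
  polynomial fits rather than truncated — the matrix keeps its shape — but
  the `(window−1)/2` edge columns at each end are flagged and excluded
  from the PLS design by default, so filter transients never enter
  calibration. Derivatives require a uniform grid; non-uniform input is an
  error directing the user to grid alignment first.
* **SNV** standardizes each spectrum to mean 0, sample standard deviation
  1 (n−1 denominator — either convention is defensible; one must be
  pinned for reproducibility and the tests pin this one). It removes
  multiplicative scatter from particle-size and dispersion effects.
  Constant spectra cannot be scaled and raise an error naming the sample.
* **Region selection** keeps the union of inclusive `(high, low)`
  wavenumber windows in original column order. The classic windows are
  2000–650 cm⁻¹ and the tighter 1500–980 / 1500–900 cm⁻¹ fingerprint
  cuts; which window pairs with which analyte is a package default
  (total → 2000–650; daidzin, glycitin → 1500–980; genistin → 1500–900)
  and freely configurable — the pairing is an artifact choice, not an
  established fact.

Step order is configurable per recipe; the default puts the
noise-amplifying derivative before SNV (so SNV normalizes the derivative
scale) and the region cut last (so edge effects fall outside kept
windows).

## Model selection and quality metrics

`cross_validate()` computes, for every latent-variable count 0..max,
held-out predictions pooled over folds and one SEP per count:

* **SEP** uses denominator `n` (not n−1). No authoritative formula
  exists; `n` is pinned and documented so reported values are
  unambiguous.
* The **scheme** defaults to leave-one-out, deterministic and the classic
  choice at calibration sizes of a few hundred samples; k-fold is
  available but demands an explicit seed. Every fold is refit from
  scratch, and the held-out predictions at `k` components are exactly
  (bit-level) those of a model fit with `n_lv = k` — a property the test
  suite verifies against a brute-force refit loop.
* `select_optimal_lv()` takes the smallest LV count attaining the
  minimal SEP; ties break toward fewer latent variables (parsimony =
  robustness; extra components mostly model noise).
* **Figures of merit** — SEP%, explained variance (R²·100) and Pearson r
  — are computed on the cross-validated predictions, not on training
  reconstructions. Reconstruction metrics flatter the model; CV metrics
  estimate prediction. Whether commercial packages report one or the
  other is ambiguous, so the honest default is CV with
  `training_metrics = TRUE` adding the training-set figures.
* The **quantification gate** is strict: `SEP% < 15` yields `QUANTIFY`,
  `SEP% ≥ 15` yields `ESTIMATE_ONLY`. Models above the gate are still
  returned — they remain usable for rough estimation — but are labelled.

Negative predicted concentrations are returned unclipped with a
`below_zero` flag: clipping would bias SEP and hide diagnostics. Note the
flag can fire on samples whose true content is zero, where an exact
method predicts ±ε.

## What the simulator emulates — and what it does not

`sim_design()` encodes a standard-addition campaign: an extract with
fixed base levels measured unspiked, spiked with single standards
(volumes of a 0.244 mg mL⁻¹ stock; `spike_mass()` converts µl to mg), and
as two-analyte fractions with one analyte removed (emulated by zeroing
the concentration — only the concentration structure matters to
calibration, not the chromatography that would produce such fractions).
Spectra are Beer–Lambert mixtures of invented band sets distorted by
additive linear baseline drift, a multiplicative scatter factor and
Gaussian noise; one mandatory seed derives all per-sample streams.

The default study-scale design (`default_paper_like_design()`) totals 335
samples as 5 replicate series × (10 base + 3 × 18 spike volumes + 3
fractions). The composition within that total, the band positions and
widths, the base levels (0.025 / 0.048 / 0.012 mg per 500 µl), the grid
(4000–650 cm⁻¹ at 2 cm⁻¹) and the distortion magnitudes (drift intercept
±0.02 AU, slope ±10⁻⁵ AU/cm⁻¹, scatter ±3 %, noise SD 0.002 AU) are all
artifact choices at plausible FT-IR magnitudes — no pure-component
spectra or instrument settings are published for this problem.

Two generator choices deserve emphasis:

* **Amplitude regime.** Analyte bands contribute a few hundredths of an
  absorbance unit atop a matrix background an order of magnitude larger.
  This is the realistic minor-component situation of a supplement
  extract, and it is also the regime in which SNV is benign: the row
  standard deviation is dominated by the (constant) matrix, so dividing
  by it is approximately a global rescaling and Beer–Lambert linearity
  survives. If analyte signal were made comparable to the matrix, SNV
  itself would become a concentration-dependent nonlinearity — a real
  effect practitioners know, but not the regime this calibration
  emulates.
* **Test sets stay in the calibration domain.** `generate_test_set()`
  draws each composition as a random convex combination of design
  concentration points. Uniform independent per-analyte draws would
  produce totals up to about twice the calibration maximum, and
  evaluating a calibration model outside its calibrated range tests
  extrapolation, which no calibration promises.

Consequently, passing tests show that the *pipeline* recovers known
linear ground truth under realistic distortion magnitudes; they cannot
show that real soy extracts are as linear, that real band overlap is as
resolvable, or that real reference (HPLC) values are error-free. An
optional `reference_noise_sd` perturbs the reported reference values to
study that last effect separately from method error.

## Problem sizes and numerical notes

The shipped analyses and tests use the 335-sample design with `max_lv =
12` and LOO selection (≈10 s per analyte), a 60-sample held-out set, a
15-sample miniature for exactness checks (noiseless, drift- and
scatter-free, where centered rank is exactly 3 and LOO SEP at 3 LVs
vanishes to machine precision), and a 10-seed × multi-level interferent
sweep on ~25-sample campaigns. Rank-deficient fits stop extracting
components when the residual covariance norm falls below 10⁻¹² of its
initial value and record the count actually used. The interferent sweep
degrades mean SEP% as amplitude rises, the mechanism by which foreign
isoflavones (e.g. red-clover admixtures) push IR-predicted contents away
from declarations; degradation plateaus once the interferent direction is
fully expressed in the calibration set.

## Declared-vs-predicted reporting

`compare_to_declared()` converts per-aliquot predictions to per-dose
contents with an explicit, user-supplied conversion factor — the bridge
from "mg per 500 µl extract aliquot" to "mg per capsule" depends on
extraction mass and dilution and is never guessed — and reports each
preparation as a percentage of its declaration with a configurable
conformity band (default ±20 %; no authoritative numeric band exists, and
the default separates rough conformity from the large deviations
attributed to interfering admixtures).

## Known limitations

* Band sets are synthetic; no claim is made that they resemble the true
  mid-IR spectra of the three glycosides beyond position-in-fingerprint
  and mutual overlap.
* The linear anchor baseline is a substitute for unpublished interactive
  baseline algorithms; recipes tuned against instrument software will not
  transfer verbatim.
* No outlier diagnostics (leverage, Q residuals), no bias/slope
  correction, no replicate-aware CV, no PLS2/O-PLS variants.
* JCAMP-DX support is the AFFN subset (XYDATA `(X++(Y..Y))`, XYPOINTS);
  compressed SQZ/DIF/DUP encodings and proprietary binary formats are out
  of scope.
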