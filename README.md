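# ftirquant

Chemometric quantification of the soy isoflavone glycosides **daidzin,
genistin and glycitin** (and their total) in complex supplement extracts
from mid-infrared (FT-IR/ATR) spectra.

Soy-based food supplements declare only their total extract content, not
the individual isoflavones that carry the estrogenic activity. HPLC can
quantify them but needs slow, laborious sample preparation. An attractive
alternative is to record a single ATR-IR spectrum of the dried extract and
read the concentrations off a multivariate calibration — even though the
three glycosides' bands overlap heavily with each other and with the
carbohydrate-rich extract matrix. This package implements that workflow
end to end for people building or auditing such calibrations: spectral
preprocessing, PLS1 regression, cross-validated model selection with a
quality gate, prediction, and declared-versus-predicted reporting —
together with a synthetic spectral generator so the whole pipeline can be
exercised and validated against known ground truth without proprietary
instrument data.

## The method

Calibration relates a preprocessed spectral matrix `X` (n samples × p
wavenumbers) to a single property `y` (mg of analyte per 500 µl extract
aliquot) by **PLS1**: latent variables `t_a = X w_a` are extracted to
maximize covariance with `y` (NIPALS, deterministic weights `w ∝ X'y`,
deflation per component), giving the regression vector
`b = W (P'W)^{-1} q` and predictions `ŷ = ȳ + (x − x̄)' b`.

Preprocessing before PLS, in order: offset correction (subtract each
spectrum's mean intensity), 9-point Savitzky–Golay first derivative
(per-cm⁻¹ scaling, edge columns flagged and excluded), standard normal
variate (per-spectrum standardization against multiplicative scatter), and
restriction to fingerprint windows (2000–650, 1500–980, 1500–900 cm⁻¹).

Model complexity is chosen at the minimum of the **SEP curve**: for each
LV count, leave-one-out cross-validation pools held-out residuals and

```
SEP = sqrt( Σ (ŷᵢ − yᵢ)² / n )          (mg per 500 µl)
```

A model is admitted for quantification only when SEP is strictly below
**15 % of the property mean**; otherwise it is flagged `ESTIMATE_ONLY`.
Explained variance (R²·100) and Pearson r are reported on the
cross-validated predictions.

Because no public spectra exist for this problem, the package ships a
simulator that emulates a standard-addition (spiking) calibration
campaign: Beer–Lambert mixtures of overlapping analyte band sets over an
extract-matrix background, plus baseline drift, multiplicative scatter,
Gaussian noise and an optional red-clover-like interferent; the default
design generates 335 samples with exact ground truth.

## Worked example

```r
library(ftirquant)

design <- default_paper_like_design(seed = 1)   # 335-sample spiking design
cfg    <- pipeline_config(design = design, max_lv = 12)
res    <- run_calibration(cfg, quiet = TRUE)
do.call(rbind, lapply(res, function(x) as.data.frame(x$report)))
```

```
  analyte n_samples n_lv      sep sep_percent variance      r       qc
  daidzin       335    4 0.001675       4.168    99.70 0.9985 QUANTIFY
 genistin       335    4 0.001228       1.953    99.85 0.9992 QUANTIFY
 glycitin       335    5 0.001467       5.358    99.77 0.9988 QUANTIFY
    total       335    5 0.001808       1.386    99.78 0.9989 QUANTIFY
```

Each row is one calibrated property: the chosen number of latent
variables, the cross-validated SEP in mg per 500 µl and as a percentage of
the property mean, explained variance and correlation, and the verdict of
the 15 % gate — here all four models quantify. Predicting an independent
simulated test set recovers the true concentrations:

```r
test  <- generate_test_set(design, n = 60, seed = 104730)
preds <- run_prediction(lapply(res, `[[`, "model"), test$set)
sep_percent(sep(test$truth$total, preds$total), test$truth$total)
#> 1.30          # held-out SEP% for total isoflavones (R² 0.995)
```

The numbered scripts under `analysis/` run the same study as a narrative
workflow (simulate → calibrate → predict/report → interference sweep) and
write their tables under `results/`.

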