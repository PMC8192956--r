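# valvespectra

Chemometric analysis of FTIR-ATR spectra of decellularized heart-valve
scaffolds, asking whether freeze-drying, dried storage, and chemically
induced oxidative damage (H₂O₂ or FeCl₃) leave a detectable spectral
fingerprint — and whether individual specimens can be classified into their
treatment group from the spectrum alone. The intended users are tissue-bank
and biomaterials researchers running vibrational-spectroscopy quality
control on processed scaffolds.

## What it computes

**Derivative band-ratio biomarkers**, per specimen, with one-way ANOVA +
Tukey HSD letters across the six treatment groups (control, freeze-dried,
stored 4 °C, stored 37 °C, H₂O₂, FeCl₃) in three tissue layers (leaflet,
intima, externa):

- I(ν_sy CH₂)/I(ν_sy CH₃) — peak intensities of the inverted Savitzky–Golay
  second derivative (21-point window, cubic) near 2850 and 2870 cm⁻¹, from
  the vector-normalized 2900–2830 cm⁻¹ region;
- A(νCO)/A(δNH) — baseline-corrected amide-I/amide-II areas integrated over
  1709–1591 and 1592–1520 cm⁻¹ of the original spectrum;
- I(β-sheet)/I(α-helix) — inverted-second-derivative peak intensities near
  1630 and 1650 cm⁻¹.

**PCA** of vector-normalized spectral regions (scores, sign-fixed loadings,
explained-variance fractions) and **LDA** on the PC scores, with
leakage-free leave-one-out cross-validation (PCA+LDA refit per fold).

**A feed-forward neural network** — input = vector-normalized
1800–900 cm⁻¹ region, two hidden layers of 128 ReLU units, softmax output
f(x) = max(0, x), σ(z)ⱼ = exp(zⱼ)/Σₖ exp(zₖ) — trained with Adam on the
categorical cross-entropy and evaluated by LOOCV. Results are summarized as
a confusion matrix (rows = true, columns = predicted), one-vs-rest
sensitivity = TP/(TP+FN)×100, specificity = TN/(TN+FP)×100,
PPV = TP/(TP+FP)×100 and NPV = TN/(TN+FN)×100 with Clopper–Pearson 95 %
confidence intervals, and a chord-diagram edge list.

**NBT-formazan staining quantification** from masked micrographs
(mean 8-bit gray level, normalized so the reference group scores 1 and
darker, more-stained tissue scores above 1).

**A synthetic-spectrum generator** emulates the six-group design (Gaussian
band mixtures with treatment-specific amplitude multipliers and a
measurement-noise model) so the whole pipeline is testable end to end; no
measured spectra ship with the package.

## Worked example

```r
library(valvespectra)

set <- generate_dataset(n_per_group = 6, layers = "leaflet", seed = 42)
ratios <- band_ratio_table(set)
group_comparison(ratios$ch2_ch3, ratios$treatment, feature_name = "ch2_ch3")
#> <group_comparison> ch2_ch3: ANOVA p = 1.601e-18
#> # A tibble: 6 × 5
#>   group            n  mean     sd letters
#>   <chr>        <int> <dbl>  <dbl> <chr>
#> 1 control          6  1.22 0.0925 b
#> 2 freeze_dried     6  1.17 0.0501 b
#> 3 stored_4C        6  1.24 0.0234 b
#> 4 stored_37C       6  1.22 0.0391 b
#> 5 H2O2             6  1.79 0.0507 a
#> 6 FeCl3            6  1.20 0.0466 b
```

H₂O₂-damaged tissue shows an elevated CH₂/CH₃ ratio (letter "a"), while
control, freeze-dried, stored and FeCl₃ groups are statistically
indistinguishable on this marker (shared letter "b") — lipid-chain
oxidation raises the CH₂ signal, and freeze-drying/storage do not.

```r
res <- run_loocv(set, config = ann_config(seed = 1, epochs = 200))
res
#> <loocv_result> ann, 36 folds, accuracy 38.9%
#>               predicted
#> true           control freeze_dried stored_4C stored_37C H2O2 FeCl3
#>   control            0            2         1          3    0     0
#>   freeze_dried       2            0         2          2    0     0
#>   stored_4C          2            1         1          2    0     0
#>   stored_37C         2            1         2          1    0     0
#>   H2O2               0            0         0          0    6     0
#>   FeCl3              0            0         0          0    0     6
```

Both oxidative-damage groups reach the maximal diagonal entry of 6 — every
H₂O₂ and FeCl₃ specimen is classified correctly (100 % sensitivity,
specificity and PPV for those classes), while the four storage-related
groups are mutually confusable, exactly the pattern expected when
freeze-drying and storage barely alter the fingerprint. `class_metrics()`
attaches the exact binomial intervals (6/6 → [54.1 %, 100 %]) and
`chord_export()` emits the edge list for chord-diagram rendering.

`run_full_analysis(run_config(out_dir = "out"))` runs all of the above from
one configuration and writes CSVs plus a JSON manifest with artifact
hashes; `inst/scripts/valvespectra-run.R` is a command-line wrapper around
it.

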