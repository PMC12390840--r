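# feocproxy

Organic carbon co-precipitated within iron (oxyhydr)oxide crystal lattices
(**Fe-OC**) quantitatively records the dissolved organic carbon (DOC) it
precipitated from: the Fe-OC loading tracks the DOC/Fe(III) mole ratio of
the parent solution, and the carbon-isotope offset between substrate and
co-precipitate (Δ¹³C = δ¹³C_DOC − δ¹³C_Fe-OC) shrinks to zero as that
ratio grows. Marine iron ooids — sand-sized grains of concentric goethite
or haematite laminae that form on agitated continental shelves — preserve
this signal over geologic time. `feocproxy` is an R implementation of the
full proxy pipeline for palaeoceanographers and biogeochemists: it
calibrates the co-precipitation relationship, screens ooids for in-situ
organic carbon, and inverts geologic Fe-OC records into relative marine
DOC concentration and δ¹³C_DOC histories.

## The model

**Calibration.** Per mineral (goethite, haematite) and DOC end member
(M-DOC: marine eukaryote analogue; C-DOC: cyanobacterial leachate; FA:
terrestrial fulvic acid), loadings follow a Freundlich sorption isotherm
and isotope offsets a dual-exponential decay in the DOC/Fe(III) ratio *x*:

    L(x) = k_F · x^(n_F),   0 < n_F ≤ 1
    Δ¹³C(x) = a₁·exp(−x/x₁) + a₂·exp(−x/x₂),   x₁, x₂ > 0

Both are fitted by constrained nonlinear least squares (profiled linear
parameters, deterministic multi-start for the multimodal dual
exponential), with sandwich covariances and RMSE/r² diagnostics.

**Inversion.** For a sample of age *t* with end-member fractions
f(t) = (f_M, f_C, f_FA) on the simplex, the mixture forward model is
L(x) = Σᵢ fᵢ·Lᵢ(x) and, by carbon mass balance,
Δ(x) = Σᵢ fᵢ·Lᵢ(x)·Δᵢ(x) / L(x). A Monte Carlo scheme draws calibration
parameters from their fit covariances and observations from their
measurement errors, inverts each drawn loading by bisection (the mixture
is strictly increasing in *x*), normalizes to the modern reference ratio
computed from actively forming ooids in the same draw, and reports

    [DOC]* = x / x_modern            (relative DOC concentration)
    δ¹³C_DOC = δ¹³C_Fe-OC + Δ(x)

as per-sample medians with 95% credible intervals. Mixing scenarios
include single end members, a "rise of algae" step (C-DOC → M-DOC at
780 Ma), "Proterozoic active eukaryotes" (even M/C mixture before
541 Ma) and a free mixture found by minimizing propagated uncertainty.

**Screening.** Raman spectra are cropped to 300–1800 cm⁻¹, smoothed
(Savitzky–Golay, order 3, window 5), baseline-subtracted (iterative
first- or third-order polynomial) and classified by the integrated band
ratio I₁₄₅₀₋₁₇₀₀/I₁₂₀₀₋₁₄₅₀ against a conservative threshold (the
maximum ratio over known Fe-OC-free pixels); the 1590 cm⁻¹ G-band marks
organic carbon. DOC substrates are characterized by spectral slopes
(a_λ = a_ref·e^(−S(λ−λ_ref))), slope ratio S_R = S₂₇₅₋₂₉₅/S₃₅₀₋₄₀₀,
SUVA₂₅₄, fluorescence index and FDOM peak metrics. A radiocarbon helper
converts fraction modern to uncalibrated age (−8033·ln Fm).

Every generator in the package is paired with known ground truth, so
parameter recovery, inversion round trips and credible-interval coverage
are all testable end to end.

## Worked example

```r
library(feocproxy)

## calibrate from a (synthetic) co-precipitation experiment
tab <- generate_coprecip_table(default_truth(), experiment_design(), seed = 7)
cal <- fit_calibration_set(tab)
head(fit_quality_report(cal), 4)
#>    mineral endmember    curve   rmse    r2 n_points rmse_pass r2_pass
#> 1 goethite     C-DOC  loading 0.0119 0.985       93      TRUE    TRUE
#> 2 goethite     C-DOC delta13c 0.1972 0.997       93      TRUE    TRUE
#> 3 goethite        FA  loading 0.0156 0.990       93      TRUE    TRUE
#> 4 goethite        FA delta13c 0.1817 0.997       93      TRUE    TRUE

## invert a 100-sample ooid record generated from a known three-state
## DOC history ([DOC]* = 1 / 0.05 / 1, breaks at 540 and 1000 Ma)
scn <- scenario("rise_of_algae")
rec <- generate_record(true_history(), default_truth(), scn, seed = 11)
rr  <- reconstruct_record(rec, cal, scn, mc_config(n_draws = 10000, seed = 3))
head(rr[, c("sample_id", "age", "doc_star", "doc_star_lo", "doc_star_hi", "d13c_doc")], 3)
#>     sample_id age doc_star doc_star_lo doc_star_hi d13c_doc
#> 1 Modern-A_01   0    0.999       0.825        1.15    -20.4
#> 2 Modern-A_02   0    1.021       0.880        1.22    -20.3
#> 3 Modern-B_01   0    1.132       0.986        1.35    -19.7

bins <- bin_record(data.frame(age = rr$age, value = rr$doc_star))
bins[bins$bin_lo %in% c(0, 600, 700), ]
#>   bin_lo bin_hi mineral n  mean     sd
#> 1      0    100     all 7 1.009 0.0595
#> 6    600    700     all 4 0.050 0.0048
#> 7    700    800     all 8 0.059 0.0120
```

The all-RMSE-pass quality report shows the fitted curves meet the
loading (≤ 0.09 wt%) and isotope (≤ 1.3‰) error bounds; the modern bin
sits at [DOC]* ≈ 1 by construction of the modern reference, and the
Neoproterozoic bins recover the generating 95% DOC drop (mean ≈ 0.05)
within measurement scatter.

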