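---
title: "Methods: calibrating and inverting the iron oxide Fe-OC proxy for marine DOC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrating and inverting the iron oxide Fe-OC proxy for marine DOC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feocproxy)
```

## The proxy in one paragraph

Iron (oxyhydr)oxides entrap dissolved organic carbon (DOC) in their
crystal lattice as they precipitate. The entrapped loading (Fe-OC, wt%)
rises with the DOC/Fe(III) mole ratio *x* of the parent solution, and the
isotope offset between substrate and co-precipitate,
Δ¹³C = δ¹³C~DOC~ − δ¹³C~Fe-OC~, decays to zero as *x* grows. Marine iron
ooids — concentric goethite/haematite grains forming at or above wave base
— carry these signals through geologic time. Given laboratory calibration
curves per mineral and DOC end member, a measured ooid (loading, δ¹³C)
pair can therefore be inverted to the DOC/Fe(III) ratio, normalized
against actively forming modern ooids to a relative concentration
[DOC]\*, and corrected to δ¹³C~DOC~.

## Calibration model

Per (mineral, end member) pair we fit, on the linear loading scale so the
RMSE is in wt%:

* **Loading**: $L(x) = k_F\,x^{n_F}$ with $k_F > 0$ and $0 < n_F \le 1$
  (Freundlich isotherm: concave, monotone, vanishing at $x \to 0^+$).
  For fixed $n_F$ the optimal $k_F$ is linear, so the fit profiles
  $k_F$ and minimizes over $n_F$ alone: a 0.01-step scan followed by
  bounded refinement to tolerance $10^{-12}$, with the boundary value
  $n_F = 1$ checked explicitly and flagged when binding. The bound is
  enforced inside the optimization, not by post-hoc clipping.
* **Isotope offset**:
  $\Delta(x) = a_1 e^{-x/x_1} + a_2 e^{-x/x_2}$ with $x_1, x_2 > 0$,
  which forces convergence to zero at high $x$. This objective is
  multimodal in the decay scales, so the fit runs 16 deterministic
  starts on a $4 \times 4$ log-spaced $(x_1, x_2)$ lattice spanning
  one-third of the smallest to three times the largest observed $x$,
  profiling the (linear) amplitudes at every step, then polishes the
  best optimum by Nelder–Mead at relative tolerance $10^{-15}$. Decay
  scales are reported in canonical order $x_1 \le x_2$; when
  $x_1 \approx x_2$ (log-ratio below $10^{-3}$) the curve is flagged as
  effectively single-exponential rather than treated as an error.

Parameter uncertainty lives on the internal parameterizations
$(\log k_F, n_F)$ and $(a_1, a_2, \log x_1, \log x_2)$. For the loading
fit we use a heteroscedasticity-consistent sandwich covariance:
replicate loading scatter has both an absolute floor and a component
proportional to the loading, and a homoscedastic estimate demonstrably
undercovers the prefactor. For the offset fit the measurement error is
dominated by a constant instrument reproducibility, so the usual
$\hat\sigma^2 (J^\top J)^{-1}$ estimate is used.

The default selection policy keeps only the geologically preserved
`-Fh/PC-ads.OC` fraction and excludes syntheses at 95 °C or pH 11.5,
whose signals diverge from the environmentally relevant ensemble.
Retained conditions are pooled into one curve per pair — the calibration
signals are consistent across environmentally relevant temperature, pH,
concentration, duration, iron source and addition timing, so
per-condition curves would only dilute the data. Quality flags default to
RMSE ≤ 0.09 wt% (loading), ≤ 1.3 ‰ (Δ¹³C) and r² ≥ 0.83, the bounds a
well-behaved calibration should meet; all are configurable. We fit Δ¹³C
against $x$ (not $\log x$); the alternative is a one-line change and was
not adopted because the dual exponential is already expressed in $x$.

## Mixture forward model and inversion

DOC is treated as a mixture of three molecularly distinct end members —
M-DOC (marine eukaryote analogue), C-DOC (cyanobacterial leachate), FA
(terrestrial fulvic acid) — with time-varying simplex fractions
$f^i(t)$. The mixture loading is the fraction-weighted sum
$L(x) = \sum_i f_i L_i(x)$. The mixture offset uses carbon-mass weights,
$\Delta(x) = \sum_i f_i L_i(x) \Delta_i(x) / L(x)$: each end member
contributes isotopically in proportion to the carbon it actually
delivers, which is what mass balance dictates for a "weighted average" of
isotope signals. All end members are assumed to share one δ¹³C~DOC~ at
any instant, so δ¹³C~Fe-OC~ = δ¹³C~DOC~ − Δ(x).

Because every $L_i$ is strictly increasing, the mixture is too, and
inversion is a one-dimensional root-finding problem solved by bisection
on $\log x$ to relative tolerance $10^{-10}$ (52 fixed halvings of the
default six-decade bracket). Observations outside the loading range of
the bracket $[10^{-4}, 10^{2}]$ clamp to the nearer bound with a flag
rather than extrapolating a power law far beyond its three-decade
calibration support.

### Scenarios

* single end members (`M_only`, `C_only`, `FA_only`) bracket the
  solution range;
* `rise_of_algae`: C-DOC before 780 Ma, M-DOC after, as a step with an
  optional linear ramp of configurable width (the transition shape is
  genuinely unknown; a step is the minimal assumption and the ramp the
  obvious sensitivity handle);
* `proterozoic_active_eukaryotes`: an even M/C mixture before 541 Ma
  ("at least half" eukaryotic production read as one half), pure M-DOC
  after; the pre-step M fraction is a parameter;
* `unconstrained`: per-sample grid search over the simplex at step 0.05
  (231 candidates) minimizing the width of the [DOC]\* 95% interval.
  "Minimizing propagated error" does not pin down a functional; the
  central-interval width is the scheme's native uncertainty measure, so
  we minimize that, with ties broken toward smaller FA then smaller
  C-DOC fractions (prefer the marine, eukaryote-lean reading when the
  data cannot distinguish). All candidates share one set of draws
  (common random numbers), making the search deterministic.

Fulvic acid defaults to zero in the marine scenarios; it represents
terrestrial humics and is retained as an explicit override.

## Monte Carlo error propagation

Per draw: calibration parameters are sampled from their fit covariances
on the internal parameterizations (Cholesky sampling; $n_F$ truncated to
$(0,1]$, decay scales re-ordered $x_1 \le x_2$); observed loadings and
δ¹³C values are sampled from their Gaussian measurement errors (loadings
truncated above zero); each sample is inverted; and the modern reference
$x_\mathrm{modern}$ is the median inverted ratio of samples in the
[0, 100) Ma bin *of the same draw*, so [DOC]\* = $x / x_\mathrm{modern}$
carries the reference uncertainty too. The median across modern samples
of [DOC]\* is exactly 1 per draw, by construction. δ¹³C~DOC~ is
reconstructed as the drawn δ¹³C~Fe-OC~ plus the mixture offset at the
drawn ratio. Draws aggregate to medians and central 95% intervals.

Randomness is generated in canonical `sample_id` order, so results are
invariant to row order; everything is keyed to a single integer seed.
The default 10,000 draws on a 100-sample record run in seconds because
the bisection is vectorized across the full sample × draw array. A
`fixed_x` reference policy supports records without a modern anchor.

Record summaries use right-open 100 Myr bins anchored at 0 Ma (an edge
convention has to be chosen; right-open keeps the modern samples in the
first bin), arithmetic means with ±1σ, Welch's unequal-variance
two-tailed t-test for group comparisons (the robust default for the
unequal counts and variances of mineralogy sub-groups), and centred
±window/2 running averages on a regular grid with gaps reported as
missing.

## Raman Fe-OC mapping

Spectra are cropped to 300–1800 cm⁻¹, smoothed with a Savitzky–Golay
filter (order 3, window 5) and baseline-subtracted with an iteratively
clipped least-squares polynomial (order 1 or 3, chosen per scan by
configuration, no automatic selection): the polynomial is refit with
points above the current fit clipped down to it until convergence, so
bands sit on top of the estimated baseline instead of inflating it. A
pure polynomial input of the baseline order is annihilated exactly, and
the band ratio is invariant to adding any such polynomial to the raw
spectrum. The abscissa is centred and scaled before the normal equations
are formed, keeping a cubic fit well conditioned over the 1500 cm⁻¹
window.

The detection statistic is the ratio of trapezoidal integrals
$I_{1450\text{–}1700}/I_{1200\text{–}1450}$ — G-band window over an
Fe-OC-insensitive background window — with negative post-baseline
intensities floored at zero first (integrated intensity is physically
non-negative). A denominator that is zero or negligible relative to the
numerator (below $10^{-9}$ of it) marks a degenerate pixel: the ratio is
reported as 0 (no signal anywhere) or ∞ (signal with no background),
flagged, and never silently dropped. Classification uses the strict
inequality `ratio > threshold` with the threshold calibrated as the
maximum ratio over pixels known to be free of Fe-OC; conservatism means
a pixel exactly at the threshold classifies as absent. Haematite scans
are classified but flagged low-confidence, because the strong haematite
band near 1300 cm⁻¹ can mask the G-band — absence of detection in
haematite is not evidence of absence.

## DOC optical metrics

Spectral slopes fit $a_\lambda = a_\mathrm{ref} e^{-S(\lambda -
\lambda_\mathrm{ref})}$ with $\lambda_\mathrm{ref}$ fixed to the lower
bound of the fitted range — the reference wavelength is free in the
defining equation, and this choice makes $a_\mathrm{ref}$ the fitted
absorption at the range edge. The default fit is Levenberg–Marquardt on
the linear scale started from (and, for exactly exponential or flat
data, returned as) the log-linear regression estimate; `log_scale =
TRUE` exposes the regression estimate directly. S_R, SUVA₂₅₄ (linear
interpolation to 254 nm) and FI (nearest-grid intensities at Ex 370,
Em 470/520) follow their definitions. FDOM sums the five canonical peak
maxima (A, B, C, M, T), each searched in a ±10 nm box around the named
coordinates — real fluorophore peaks are broad, so a point lookup would
understate them; the box width is configurable because it is a choice,
not a community standard. Peak fractions are maxima over FDOM and are
reported missing when FDOM is zero. Instrument corrections (lamp,
inner-filter, Raman normalization) are assumed already applied upstream.

## What the synthetic generators emulate — and what they do not

The generators produce every input the pipeline consumes, with known
truth and seeded randomness:

* **Co-precipitation tables**: log-spaced ratios over 0.003–3 (three
  decades, 10 points/decade, 31 ratios), triplicate rows per condition,
  loading noise = 0.01 wt% absolute + 5% relative Gaussian (truncated at
  zero), δ¹³C noise 0.2 ‰ (typical instrument reproducibility). Default
  truth parameters put loadings in the ~0.03–0.5 wt% range geologic
  records occupy, with negative offset amplitudes of a few ‰ (modern
  marine DOC near −21 ‰ is lighter than modern ooid Fe-OC near −18 ‰,
  so Δ¹³C < 0). These magnitudes are documented stand-ins, not
  published values.
* **Geologic records**: 26 formations / 100 samples over 0–1650 Ma with
  a modern anchor, forward-modelled from a three-state [DOC]\* history
  (1 until 540 Ma, 0.05 through the Neoproterozoic to 1000 Ma, 1
  before) at $x_\mathrm{modern} = 1$, δ¹³C~DOC~ = −20 ‰ Phanerozoic /
  −38 ‰ Proterozoic, plus 0.01 wt% / 0.2 ‰ measurement noise.
* **Raman phantoms**: cubic baseline, three goethite-like bands below
  700 cm⁻¹, a 1590 cm⁻¹ G-band only where the organic mask is true, and
  Gaussian noise at a stated G-band-amplitude SNR.
* **Optical samples**: piecewise-exponential absorbance spliced at
  320 nm and anchored to the 254 nm absorbance, plus Gaussian EEM peaks
  on the standard 250–500 × 300–600 nm grids.

What passing tests on these data show is that the *pipeline* is correct
and statistically calibrated: noiseless inputs are recovered to
tolerance, round trips close, nominal 95% intervals cover truth at near
nominal rates. What they cannot show is fidelity to real systems: the
generators assume the fitted functional forms are exactly true, noise is
Gaussian and independent, end members are exactly three, DOC history is
piecewise constant, and diagenesis, detrital carbon, spatial
heterogeneity and mineral transformation biases do not exist. Real-data
conclusions inherit those assumptions from the proxy, not from this
package.

## Problem sizes and determinism

Test and acceptance runs use 558-row calibration tables, 50- and
100-sample records at 10,000 draws, a 20-seed coverage experiment
(1000 sample-intervals), 40 × 40 phantom maps, and 200-repetition
interval-coverage checks for the loading fit — sizes chosen so the whole
suite completes in a few minutes on one CPU while keeping Monte Carlo
acceptance margins far from their thresholds. Every stochastic step is a
pure function of (inputs, configuration, seed).

## Known limitations

* The inversion reports [DOC]\* relative to modern only; absolute
  concentrations would require the unknown Fe(II) flux, and ooids also
  capture labile DOC and possibly trace particulate carbon, so [DOC]\*
  is best read as a maximum.
* The calibration covariance is a local (Jacobian-based) approximation;
  strongly nonlinear posteriors at very small point counts are not
  captured.
* Threshold calibration formalizes "maximum over known negatives"; it
  reproduces the conservatism of expert per-scan thresholds but not
  necessarily their exact values, which depend on which pixels an
  analyst labels negative.
* The Δ¹³C mixing weights follow carbon mass balance; if real
  co-precipitation fractionates end members non-additively, the forward
  model inherits that bias.
* Fits assume independent residuals; replicate correlation within a
  synthesis batch would shrink effective sample sizes.
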