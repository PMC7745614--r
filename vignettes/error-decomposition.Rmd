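---
title: "Sample-specific prediction error for PCR calibration: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample-specific prediction error for PCR calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcruq)
```

## The calibration model

Spectroscopic calibration relates reference values $y$ (say, protein
content by a wet-chemistry method) to spectra $\mathbf{x}$ over $K$
wavelength channels through a linear law
$\mathbf{y} = \mathbf{1}b_0 + \mathbf{X}\mathbf{b} + \mathbf{e}$ with
$\operatorname{Var}(e) = \sigma^2$. Spectral channels are strongly
collinear, so the coefficients are estimated by principal component
regression: with column-centered calibration spectra and the singular value
decomposition $\mathbf{X} = \mathbf{U}\mathbf{S}\mathbf{P}^{\mathsf T}$,
the model is re-expressed in the orthonormal score basis,
$\mathbf{y} = \mathbf{1}g_0 + \mathbf{U}\mathbf{g} + \mathbf{e}$, and only
the first $A$ components are used for prediction. A new spectrum is
centered by the calibration means and projected onto
$\mathbf{P}\mathbf{S}^{-1}$ to give its score coordinates $\mathbf{u}$;
the prediction is $\hat y = \bar y + \sum_{a \le A} u_a \hat g_a$.

Because the score columns are orthonormal, the least-squares coefficients
are simply $\hat g_m = \mathbf{u}_m^{\mathsf T}\mathbf{y}_c$ and each has
variance $\sigma^2$. `fit_pcr()` estimates them for *all* retained
components, not only the $A$ used in prediction, because the bias estimate
below needs coefficients beyond $A$.

## The error decomposition

Conditioning on the calibration spectra, the expected squared prediction
error at score position $\mathbf{u}$ decomposes as

$$
E(\hat y - y)^2 \;=\; \sigma^2
\;+\; \underbrace{\frac{\sigma^2}{N} + \sigma^2 \sum_{a \le A} u_a^2}_{\text{estimation variance}}
\;+\; \Big({-}\sum_{m > A} u_m g_m\Big)^{\!2}.
$$

The first term is irreducible measurement noise in $y$; the second is the
variance of the fitted predictor — $\sigma^2$ times the score-space
leverage $1/N + \sum u_a^2$, smallest at the calibration centroid; the
third is the squared omitted-component bias, the systematic error a
truncated model makes for a sample with structure along components beyond
$A$. The bias is sample specific and sign carrying; across a prediction
population it looks like extra noise rather than a trend of $\hat y$
against $y$. `expected_squared_error()` returns all three pieces and their
total, and the decomposition identity is exact by construction (tested to
$10^{-10}$).

Two samples with equal predictions $\sum_{a\le A} u_a \hat g_a$ can have
arbitrarily different leverage and omitted-component coordinates, hence
different expected errors; the test suite constructs such pairs
explicitly.

### Plug-in estimators

The population quantities $\sigma^2$ and $g_m$ are unknown, so the package
uses:

* **Noise variance.** `estimate_sigma2()` returns the MSEC of a
  deliberately high-rank fit — 50 components by default — on the grounds
  that components that far out carry no systematic analyte information.
  The MSEC denominator is $N - A - 1$ (coefficients actually fitted plus
  the mean); the classical $N - K - 1$ convention is available via
  `denominator = "nvar"` where $K < N$ makes it feasible. When the data
  have rank below the request (synthetic low-rank spectra, for instance),
  the request is capped at rank − 1 with a warning.
* **Bias coefficients.** Far-out $\hat g_m$ are mostly noise
  ($\operatorname{SD} = \sigma$), so the bias sum uses only components up
  to `m_max_bias = 15` whose univariate slope against centered $y$ passes
  a two-sided $t$-test at `alpha = 0.01` (residual d.o.f. $N-2$; the
  degrees of freedom are a package convention, as is testing once per
  calibration rather than re-testing per candidate $A$). No
  multiple-testing correction is applied across the 15 tests — the gate is
  meant as a noise filter, not an inference procedure. Gating applies
  *only* to the bias sum; components $\le A$ always contribute to the
  prediction.

For full-rank predictors with $A = M$ and an empty bias range the formula
collapses to the classical least-squares result
$\sigma^2(1 + 1/N + \mathbf{x}^{\mathsf T}(\mathbf{X}^{\mathsf T}\mathbf{X})^{-1}\mathbf{x})$
via the identity $\sum_m u_m^2 = \mathbf{x}^{\mathsf T}(\mathbf{X}^{\mathsf T}\mathbf{X})^{-1}\mathbf{x}$;
`ols_expected_squared_error()` implements the right-hand side and the
equivalence is tested to $10^{-8}$.

## The synthetic scenario and what it does (not) show

No public dataset accompanies the methodology, so the package ships a
generator whose truth is fully known. `generate_loadings()` draws smooth
Gaussian-bump channel profiles and orthonormalizes them;
`simulate_dataset()` draws latent scores with strictly decreasing standard
deviations, centers and *exactly orthogonalizes* the calibration scores,
and rescales them to singular values $\mathrm{sd}_m\sqrt{N-1}$. With zero
spectral noise the centered calibration spectra then have exactly the SVD
$\mathbf{U}\mathbf{S}\mathbf{P}^{\mathsf T}$ in the generative basis (up
to the shared deterministic sign convention: the largest-magnitude element
of each loading column is positive), so generative coefficients and fitted
coefficients live in the same basis and the true conditional bias
$-\sum_{m>A} u_m g_m$ of every test sample is computable without
basis-matching heuristics. Reference values follow
$y = g_0 + \mathbf{u}\mathbf{g} + e$ in that basis.

The default scenario (`nir_truth()`) uses 85 channels (860–1028 nm at
2 nm), 15 components with score scale $1.5 \times 0.78^{m-1}$, five
dominant coefficients $(9, 8, 7, 6, 5)$, three minor informative ones
$(6.5, 6, 5.5)$ on components 6–8, $g_0 = 12$ and $\sigma^2 = 0.25$ —
protein-percent-like scales. Two deliberate design points:

* **Minor components must be detectable.** The univariate $t$-test's
  residual contains all *other* components' signal, so its detection
  threshold is roughly $2.6\sqrt{(\sum_j g_j^2 + N\sigma^2)/N} \approx 5$
  at these scales. Coefficients near that threshold are flagged only when
  their estimate fluctuates high, which inflates the flagged
  $|\hat g_m|$ (a winner's-curse selection effect) and visibly attenuates
  the estimated-versus-true bias slope. The minor coefficients were sized,
  by a design-stage power calculation, to clear the threshold with high
  probability, the regime in which a significance-gated bias estimate is
  meaningful at all. This is a property of the estimator worth knowing
  about in practice: coefficients marginally at the detection limit make
  the bias estimate systematically too large in magnitude.
* **A five-component model is the study object, not the optimum.** With
  informative components 6–8 present, cross-validation favors more than
  five components; fixing $A = 5$ creates exactly the omitted-component
  bias the decomposition is meant to quantify. The companion
  "strong-signal" scenario (`nir_truth(tail_signal = FALSE)`) has signal
  on the first five components only; there the leave-one-out curve
  (scanned over $A = 1..6$, just past the expected optimum) bottoms out at
  five in most seeds, and the average estimated squared bias falls
  monotonically as $A$ grows through the informative components while the
  variance term rises — the classic complexity trade-off.

What passing tests on this generator do **not** show: robustness to
instrument artifacts (scatter, baseline drift, wavelength shift), to
spectral measurement noise (the formulae assume errorless $\mathbf{x}$; a
`sigma2_x > 0` option exists for realism experiments but the oracle tests
keep it at zero), or to a prediction population unlike the calibration
(representativeness bias). The latter is only *diagnosed*, via
`leverage()` and squared spectral reconstruction residuals, never corrected.

## The Monte-Carlo oracle

`monte_carlo_expected_error()` estimates $E(\hat y - y)^2$ by brute force:
holding the calibration spectra fixed, it redraws the calibration
reference values from the generative law, refits the score regression,
predicts the sample at a fixed $\mathbf{u}$ (conditioning on the sample,
as the formula does), redraws that sample's own $y$, and averages the
squared error over replicates. It shares no code with the analytical
formula beyond the SVD, and agreement within three Monte-Carlo standard
errors at 5000 replicates — including at high-leverage and
high-omitted-component positions — is the repository's headline property
test.

## Validation protocol on a prediction set

When references exist for predicted samples, `agreement_report()` compares
estimated against observed quantities: mean difference, the two variances,
a Loess tendency of observed on estimated (tricube weights, span 0.5,
degree 2, no robustness iterations — `stats::loess` with direct surface
evaluation, neighbourhood $\lfloor \mathrm{span}\cdot n\rfloor$ points),
and one summary number: the straight-line slope of the Loess curve over
the central 90% of the abscissa. The central-90% restriction avoids
end-effect leverage of the local fit; an optional inclusion mask lets the
caller exclude aberrant samples from the smoothing while still obtaining
fitted values everywhere (no exclusion is applied by default, since any
exclusion rule is situation specific). A degenerate (constant) abscissa
yields `slope = NA` rather than an error. The observed variance generally
exceeds the estimated variance — observed bias contains random
fluctuation that the estimate, built from a handful of gated coefficients,
does not — so the variances are reported side by side rather than
compared to one.

The least-squares effect — shrinkage of $E(\hat y \mid y)$ toward the mean
with slope $\mathbf{b}^{\mathsf T}\Sigma_{xy}\Sigma_y^{-1}$, present even
with exactly known parameters — is provided by
`least_squares_effect_line()` with plug-in sample covariances (in score
space for a fitted model, where the slope reduces to the explained
variance fraction $\sum_{a\le A}\hat g_a^2 / \sum y_c^2$). It visualizes
why low reference values are overestimated and high ones underestimated;
no correction is attempted.

## Numerical choices

* Rank truncation at $10^{-10}$ times the leading singular value;
  centering caps the rank at $N-1$.
* SVD sign convention as above, making refits bitwise identical across
  platforms; the simulator applies the same convention to its generative
  loadings so recovered and generative bases agree including signs.
* Savitzky–Golay filtering (window 21, polynomial order 2, second
  derivative by default) returns only the valid interior region —
  `window - 1` channels are dropped rather than extrapolated, and the
  trimmed wavelength axis is carried along so calibration and prediction
  sets stay aligned. The derivative is per channel step; an even channel
  spacing only rescales the spectra, which the regression absorbs. The
  filter is exact on polynomials up to the fit order (tested on
  constants, lines and quadratics).
* Leave-one-out cross-validation refits centering, SVD and coefficients
  from scratch in every fold; no shortcut formulae, so the curve is
  unambiguous and testable against an independent naive loop. MSECV uses
  denominator $N$ exactly.
* One root seed per simulation with a fixed, documented draw order
  (calibration scores, calibration noise, test scores, test noise, then
  spectral noise last) so enabling spectral noise never shifts the other
  streams; all seeded helpers restore the caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script run the full protocol at the
scenario's native size (100 calibration and 423 prediction samples, 85
channels, 15 components; ten seeds for majority-vote properties; 5000
Monte-Carlo replicates per oracle comparison, 50000 for the centroid
check), which completes in well under a minute on a single core —
exhaustiveness here comes from the oracle structure, not from scale.

## Known limitations

* The bias estimate inherits the significance gate's selection effects:
  marginally detectable components attenuate the estimated-vs-true bias
  slope below one, and undetected ones leave bias unaccounted for.
* $\sigma^2$ from a high-rank MSEC is biased upward if genuinely
  informative components hide beyond the cap, and noisy when the residual
  degrees of freedom are few.
* Errors in the spectra themselves are not modeled; neither are
  prediction intervals with formal coverage — the package stops at the
  expected squared error, which is the quantity its validation protocol
  can actually check.
* PLS is out of scope; the decomposition applies to any orthogonal-score
  compression, but the variance algebra here relies on PCR's
  $y$-independent scores.
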