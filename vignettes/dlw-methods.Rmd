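---
title: "Models and methods behind dlwtee"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dlwtee}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlwtee)
```

## The measurement and the model

A doubly labelled water (DLW) experiment doses a subject with water enriched
in both ²H and ¹⁸O and follows the decline of the two enrichments in body
water over one to two weeks. Both labels leave the body with water; ¹⁸O
additionally exchanges with dissolved CO₂ and so is eliminated faster. The
difference between the two elimination fluxes therefore measures CO₂
production, and from it total energy expenditure (TEE) under free-living
conditions.

`dlwtee` assumes single-pool first-order kinetics for each isotope. With a
dose of $D$ g, of which an aliquot of $d$ g was diluted into $T$ g of water
of enrichment $\delta_T$ to give the measured diluted-dose enrichment
$\delta_{dd}$, the predicted enrichment at $t$ days post-dose is

$$\delta(t) = \frac{D\,T\,(\delta_{dd}-\delta_T)}{18.02\,N\,d}\,
  e^{-kt} + \delta_b,$$

where $N$ (mol) is the isotope's dilution space, $k$ (day⁻¹) its elimination
rate constant and $\delta_b$ the pre-dose (basal) enrichment. All
enrichments are in ‰ vs VSMOW. This is `enrichment_at()`; the constant
18.02 g mol⁻¹ is the molar mass of water.

Classically, CO₂ production is computed from the fitted $(N,k)$ pairs either
with natural (as-fitted) spaces,

$$ r_{CO_2} = \frac{k_O N_O - k_H N_H - 27.3\,(f_2-f_1)}{2 f_3 + 1.1\,(f_2-f_1)}
 \qquad \text{(Coward)},$$

or, after normalizing the spaces to a fixed ratio, with

$$ r_{CO_2} = \frac{k_O N_O - k_H N_H}{2 f_3 + 2.1\,(f_2-f_1)}
 \qquad \text{(Schoeller)}.$$

The fractionation factors default to $f_1 = 0.941$, $f_2 = 0.991$,
$f_3 = 1.037$. TEE follows from the modified Weir equation at a common
respiratory quotient RQ,

$$ \mathrm{TEE} = 22.4\left(\frac{15.48}{RQ} + 5.55\right) r_{CO_2}, $$

which at the default RQ = 0.85 makes TEE a constant 532.26 kJ per mol CO₂.
Some renderings of the Weir equation print the RQ term as a product
(`15.48·RQ`); only the quotient form reproduces the canonical factor of 532
at RQ = 0.85, so the quotient is what `weir_tee()` implements.

## Space-ratio normalization

Isotope dilution overestimates total body water — by about 4% for ²H
(exchange with labile hydrogen) and about 1% for ¹⁸O — so the two spaces
differ, with a physiological ratio $S = N_H/N_O \approx 1.03\text{–}1.04$.
Two fixed-ratio conventions are implemented:

* `normalize_spaces_schoeller()`: $N_H^c = (N_H + 1.03 N_O)/2$,
  $N_O^c = (N_H/1.03 + N_O)/2$, giving a corrected ratio of exactly 1.03;
* `normalize_spaces_iaea()`: the mean of the individually corrected pools
  ($N_H/1.041$, $N_O/1.007$) rescaled by each isotope's factor, giving
  $1.041/1.007 = 1.034$ (3 d.p.).

Because TEE is linear in the flux difference, normalizing from the natural
ratio $S$ to a target $S'$ shifts TEE by the closed form
$\lambda\,(S/S'-1)\,\tfrac{1}{2}(k_O + S' k_H)\,N_O$
(`normalization_tee_shift()`), with $\lambda$ the Weir factor times the
fractionation constant $\alpha_1$ below. The bracketed term is roughly the
mean isotope flux, nearly invariant in a population, so the shift is close
to linear in $S - S'$: normalization lowers TEE for subjects below the
target ratio and raises it above. Natural ratios outside 1.015–1.060 are
flagged (`S_outside_screen`) but not rejected; the band is a data-quality
screen, not a physical bound.

## The physiological re-parameterization

For Bayesian estimation the kinetic parameters are re-expressed through
four physiologically meaningful quantities:

$$ r_{CO_2} = \alpha_1 (k_O N_O - k_H N_H) + \alpha_2, \qquad S = N_H/N_O,$$
$$ R_W = \beta_1 k_H N_H + (1-\beta_1) k_O N_O + \beta_2, \qquad
   F = 1 - (\gamma_1 N_H + \gamma_2 N_O)/W,$$

with $W$ the body weight (kg), $R_W$ the water turnover (mol/day) and $F$
the body-fat fraction. The transformation constants are derived, not free:

* $\alpha_1 = 1/(2f_3 + 2.1(f_2-f_1))$, $\alpha_2 = 0$ under the Schoeller
  fractionation model (the default); a Coward-model alternative
  ($\alpha_1 = 1/(2f_3+1.1(f_2-f_1))$,
  $\alpha_2 = -27.3(f_2-f_1)\alpha_1$) is selected with
  `dlw_constants("coward")`.
* $\beta_1 = 1$, $\beta_2 = 0$: water turnover is taken as the ²H flux.
  Fractionation-corrected variants can be supplied as overrides.
* $\gamma_i = 18.02/(2 \cdot 1000 \cdot 0.732 \cdot r_i)$ with
  $r = (1.041, 1.007)$: total body water is the mean of the two
  space-corrected pools, converted mol → kg and divided by the hydration
  fraction of fat-free mass (0.732).

All six are fields of `dlw_constants()` and individually overridable, so
any variant fractionation model can be reproduced. The inverse map
(`kinetic_from_physio()`) is exact algebra:
$N_O = W(1-F)/(\gamma_1 S + \gamma_2)$, $N_H = S N_O$, and the two fluxes
$k_H N_H$, $k_O N_O$ recovered from $r_{CO_2}$ and $R_W$. The package tests
verify the round trip to 10⁻¹⁰ relative error across the prior support,
and the derived defaults reproduce published example kinetics to within
their printed rounding (≈0.2%).

## Classical estimation

Three fit flavours estimate the same curve under different error models:

* `fit_logarithmic()` — OLS of $\log(\delta(t)-\delta_b)$ on $t$
  (proportionate error; the traditional slope–intercept method);
* `fit_poisson()` — the same regression weighted by the excess enrichment
  (variance proportional to excess);
* `fit_exponential()` — Levenberg–Marquardt least squares on the
  untransformed ‰ scale (constant absolute error), initialized from the
  logarithmic fit. This matches the error structure of modern IRMS data
  and the Bayesian model's likelihood.

All three agree exactly on noise-free data. Points at or below basal are
excluded from log-scale fits with a warning rather than aborting — late
timepoints can cross baseline by noise alone. Duplicate timepoints are
averaged at read time. `propagate_error()` gives a first-order
(delta-method) CV for TEE from the per-isotope $(N,k)$ covariance matrices,
treating the two isotopes as independent; within an isotope the full fit
covariance (including the $N$–$k$ correlation) is used.

## The Bayesian model

The likelihood assumes independent Gaussian measurement error on each
enrichment, with fixed standard deviations of 2 ‰ (²H) and 0.5 ‰ (¹⁸O) by
default — the realistic precisions of the two instruments. Priors:

| parameter | prior | rationale |
|---|---|---|
| $r_{CO_2}$ | Uniform(0, 100) mol/day | vague; data-driven |
| $R_W$ | Uniform(0, 1000) mol/day | vague |
| $F$ | Uniform(0, 1) | vague |
| $S$ | Normal(1.035, sd 0.01) | strong physiological prior knowledge |

The normal prior on $S$ is the informative ingredient: it encodes that
space ratios concentrate near 1.035 while leaving the other parameters to
the data. (The precision notation 1/sd² is used throughout; sd 0.01
corresponds to precision 10000.)

Sampling is component-wise random-walk Metropolis over
$(r_{CO_2}, S, R_W, F)$. Proposal scales adapt toward a 44% acceptance
rate in batches of 50 during burn-in only, so the post-burn-in kernel is a
fixed Metropolis kernel in detailed balance with the posterior. Defaults
follow the reference configuration: 50,000 iterations with 4,000 burn-in;
the package default is 2 chains (for split-$\hat R$ and ESS diagnostics,
reported on every run) with single-chain mode available. Chains are seeded
`seed + chain - 1`, making runs exactly reproducible. TEE is a derived
draw: the Weir factor times the $r_{CO_2}$ draw, draw by draw.

$F$ is sampled even though TEE does not depend on it — it is part of the
model and a useful by-product of the ²H data. Basal enrichments are fixed
at their measured values; a meteoric-water-line prior for basals is a
possible extension, not implemented as a default.

In the hierarchical model (`sample_hierarchical()`), individual parameters
are drawn from normal population distributions
$\theta_i \sim N(\mu_p, 1/\tau_p)$. Precisions have Gamma(0.01, 0.01)
hyperpriors except $\tau_S \sim$ Uniform(1, 10⁵), whose bounded support
again reflects the richer prior information about $S$. Hypermean priors are
not fully pinned down by the reference analysis; the package adopts the
per-subject vague priors for the hypermeans (including the informative
normal on the $S$ hypermean), and constrains individual parameters to the
same supports. Hypermeans and precisions have conjugate (truncated) normal
and Gamma full conditionals and are updated by exact Gibbs draws;
individual parameters keep the random-walk updates. Strata are analysed
per sex by default, since CO₂ production and body composition differ
between the sexes; a pooled mode exists.

Degenerate cohorts (n < 3) run with a warning: the population parameters
are then essentially prior-driven.

## The synthetic-cohort generator

The actual survey cohort behind the reference analysis (59 adults, 37
women and 22 men) is not publicly deposited, so `cohort_design()` /
`simulate_cohort()` emulate it with known ground truth:

* counts 37 + 22, 14 daily post-dose sampling days, noise sds 2 ‰ / 0.5 ‰;
* sex-specific truncated normals calibrated so that cohort medians land on
  the reported values — women: $r_{CO_2}$ 18.1 mol/day (sd 2.8), $F$ 0.376
  (sd 0.072), weight 69 kg; men: 25.9 mol/day (sd 3.3), 0.274 (sd 0.072),
  83 kg;
* space ratios $N(1.038, 0.008)$ truncated to (1.005, 1.075): the
  population mean matches the reported hyperparameter estimate (~1.038)
  and the between-subject sd of 0.008 is chosen so natural ratios span
  roughly 1.01–1.07, reconciling the narrow hyper-sd (0.0016, an sd of the
  mean) with the observed individual spread;
* water turnover has no published cohort summary; the defaults (women
  ~150, men ~210 mol/day, i.e. ~2.7–3.8 L/day) are chosen for consistency
  with published example kinetics ($k_H \approx 0.083$ day⁻¹ at pools of
  1900–2500 mol) and typical adult turnover;
* doses are back-computed so the t = 0 excess enrichments are ~300 ‰ (²H)
  and ~120 ‰ (¹⁸O), typical of adult DLW protocols; basal ¹⁸O is drawn
  near −7 ‰ with the ²H basal on the meteoric water line
  ($\delta^2H = 8\,\delta^{18}O + 10$).

What the generator does *not* emulate: analytical drift and non-linearity
of the mass spectrometers, within-subject variation of turnover over the
sampling fortnight, missing or irregular sampling schedules, and any
correlation between noise at adjacent timepoints. Recovery results on
synthetic cohorts therefore demonstrate correctness of the estimators
under the stated error model, not robustness to instrument pathology.

`make_prentice_like_fixtures()` provides three fixed synthetic subjects at
an assigned 70 kg with kinetics near published example values
($N_H \approx 2520$ mol, $k_H \approx 0.083$, $k_O \approx 0.109$), the
third carrying a single +11 ‰ outlier on day 11 for exercising outlier
behaviour. They are stand-ins constructed from published summary kinetics,
not measured data, and are seed-stable without disturbing the caller's RNG
stream.

## Numerical choices

* Exponential fits use Levenberg–Marquardt (`minpack.lm`) with the
  logarithmic fit as start; non-convergence raises a classed error
  carrying the initializer.
* Two-point curves are interpolated exactly; their standard errors are
  `NA` (no residual degrees of freedom) and error propagation then refuses
  rather than fabricating a CV.
* Proposals crossing the support or implying non-positive pools/fluxes are
  rejected via a −∞ log target, never raised as errors mid-chain.
* Truncated normal and Gamma full-conditional draws use inverse-CDF
  sampling with far-tail guards (pinning at the nearest bound when the
  truncation probability mass is below 10⁻¹²).
* Split-$\hat R$ halves each chain; ESS uses Geyer's initial monotone
  positive-pair sequence on chain-averaged autocorrelations. Both warn,
  never block. Acceptance rates outside [0.05, 0.95] after burn-in are
  warned about and recorded in the result.
* The closed-form normalization shift and its direct recomputation agree
  to machine precision *on the TEE scale*; comparing them relative to the
  (often near-zero) shift itself would amplify benign cancellation error.

## Validation problem sizes

The shipped tests validate: the exact algebraic identities (1,000-draw
round trips; 500 random kinetics for the normalization shift); a
restricted one-parameter sampler against a 4,001-point grid posterior
(total-variation distance < 0.05, 60,000 iterations); prior-only recovery
of the $S$ prior (40,000 iterations); and full parameter recovery on a
20-subject cohort at the stated noise with 10,000-iteration chains — a
size chosen to exercise the samplers thoroughly while keeping the default
check fast. With the 50,000-iteration default the same checks only
tighten.

## Known limitations

* Slope–intercept (multipoint) protocols only; no two-point plateau
  analysis.
* A fixed common RQ converts CO₂ production to energy; subjects with
  atypical macronutrient oxidation will be biased proportionally.
* The measurement-noise sds are fixed, not estimated; misstating them
  miscalibrates posterior widths (though not greatly the medians).
* No automatic outlier rejection: aberrant points stay in unless the
  caller removes them, matching the reference treatment of the day-11
  outlier.
* The Poisson-weighted fit is one reading of the intermediate error-model
  taxonomy (weights proportional to excess enrichment on the log scale);
  its estimates interpolate the other two flavours in most, not all,
  noisy replicates.
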