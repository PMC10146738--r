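---
title: "Methods: release-kinetics model fitting, mechanism classification, and solubility parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: release-kinetics model fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relkin)
```

## The model family and its assumptions

A release curve is an ordered series of (time in minutes, cumulative
release in percent of the loaded drug). Four parametric forms are fitted
to each curve:

* zero order, $Q_t = K_0 t + b_0$: constant release rate;
* first order, $Q_t = K_1 e^{a t} + b_1$: with $a < 0$ and $K_1 < 0$ a
  saturating rise toward the plateau $b_1$, typical of drug adsorbed in
  the interior of the substrate;
* Higuchi, $Q_t = K_H \sqrt{t} + b_H$: diffusion out of a matrix;
* Korsmeyer–Peppas, $Q_t = K t^n$: a semi-empirical power law through
  the origin, valid only for the first 60 % of fractional release.

The first-order form is kept exactly as written above rather than in a
rate-constant convention, so published fitted equations load directly as
parameter vectors (`fixture_params()`); a fitted plateau release then has
$K_1 < 0$. The power law defines $0^n = 0$ for $n > 0$, so the curve
passes through the origin; $t = 0$ with $n \le 0$ is rejected.

The key modelling assumptions are: cumulative release is measured on a
percent scale against a known loading; observation errors are additive
and homoscedastic on that scale; and the matrix geometry is a thin
cylinder (a fiber), which fixes the exponent thresholds used for
classification.

## Fitting

All fits minimize squared error on the *untransformed* percent scale.
The two linear forms (zero order, Higuchi) are solved in closed form by
ordinary least squares on $t$ and $\sqrt{t}$. The two nonlinear forms use
Levenberg–Marquardt (`minpack.lm::nlsLM`, `ftol = 1e-10`,
`ptol = 1e-12`, up to 1024 iterations) from deterministic starting
values:

* Korsmeyer–Peppas: ordinary least squares on $(\ln t, \ln Q_t)$ over
  positive pairs;
* first order: $b_1^{(0)} = 1.05 \max Q_t$, then least squares on
  $\ln(b_1^{(0)} - Q_t)$ against $t$ for $a$ and $K_1$.

If the optimizer fails, up to 3 restarts perturb the start
multiplicatively with seeded log-normal jitter (sd 0.2), so failures and
recoveries are reproducible. A fit that still fails is returned with
`converged = FALSE` and metrics computed at the best available point.
A log–log linearized mode for the power law
(`fit_scale = "linearized"`) is provided purely as a sensitivity check:
linearization reweights errors toward early times and is not the primary
estimator.

Fitting on the untransformed scale (rather than any log-linearization) is
a deliberate choice: the metric set used for comparison — adjusted
R², RSS, reduced $\chi^2 = RSS/(N-p)$ with unit weights, Pearson's r —
is only coherent if all models are scored against the same untransformed
observations. Pearson's r is defined as the correlation between observed
and predicted values for *every* model; for straight-line models this
coincides with the usual time–response correlation up to sign, and it is
the single definition that extends to the nonlinear forms.

The 60 % validity window of the power law is implemented as a prefix
rule (`restrict_kp_domain()`): points are retained strictly below the
cutoff up to the first crossing, and nothing after the crossing is
re-admitted even if the curve later dips below 60 %. The window is an
early-time validity statement, not a filter on values. The boundary
value 60.0 itself is excluded. At least 3 surviving points are required.

Degenerate inputs are handled explicitly: a constant curve fits the zero
order model with zero slope, but adjusted R² and Pearson's r are
undefined (zero total sum of squares) and returned as `NA`; curves with
non-increasing times, fewer points than parameters plus one, or release
above 110 % are rejected with typed conditions.

## Model selection

`rank_models()` formalizes the accepted two-step comparison: models whose
adjusted R² is within a *relative* tolerance of the best form a
shortlist, and the shortlist is resolved by smallest RSS, then smallest
reduced $\chi^2$, then fixed registry order (zero order, first order,
Higuchi, Korsmeyer–Peppas) with the tie recorded in the rationale.

Two defaults deserve justification:

* **Shortlist tolerance 0.05.** The shortlist exists because adjusted R²
  values computed on different point counts (the power-law window drops
  points) differ by a few percent even between equally adequate models.
  A tolerance much below 5 % would eject a power-law fit whose adjusted
  R² trails a first-order fit by 3–4 % while its RSS is several times
  smaller — precisely the situation in fast-release (burst) curves. The
  tolerance is configurable per call.
* **RSS before reduced χ².** The two disagree only when candidate fits
  use different `N - p`; preferring RSS means preferring the smaller
  absolute misfit, which matches how such tables are read in practice.

## Mechanism classification and burst flagging

For a cylinder, `classify_mechanism()` maps the fitted exponent to
`fickian` ($n < 0.45$), `non_fickian` ($0.45 \le n < 0.89$), `case_II`
($|n - 0.89| \le 10^{-6}$) and `super_case_II` ($n > 0.89$). The
literature states the inner boundaries with strict inequalities and
leaves $n = 0.45$ unassigned; the package closes the lower boundary into
the non-Fickian class so the partition is exhaustive, and records the
thresholds used in every `mechanism_call()` result. Only cylinder
thresholds ship; other geometries require user-supplied thresholds and
are rejected rather than guessed.

`flag_burst()` is an inclusive threshold on the power-law rate constant
$K$, default 6 (percent·min$^{-n}$). Reported release studies show a
bimodal gap — slow-release drugs clustering below $K \approx 0.9$ and
burst-release drugs above $K \approx 6.1$ — rather than a principled
cutoff; the default sits at the lower edge of the upper cluster and is
documented as a heuristic, configurable per call.

## Solubility parameters (Hoftyzer–Van Krevelen)

For a molecule described as a multiset of group fragments,

$$\delta_d = \frac{\sum F_{d,i}}{V},\qquad
  \delta_p = \frac{\sqrt{\sum F_{p,i}^2}}{V},\qquad
  \delta_h = \sqrt{\frac{\sum E_{h,i}}{V}},\qquad
  \delta_t = \sqrt{\delta_d^2+\delta_p^2+\delta_h^2},$$

with $V$ the molar volume from Fedors group increments (no measured
densities are needed). The embedded table (`hvk_group_table()`) carries
the canonical reference-book constants for the eight groups needed by
the nine shipped drugs; the fragmentation convention
(`hvk_drug_groups()`) encodes a disubstituted benzene ring as one
phenylene unit, methoxy as ether plus methyl, and esters as the
carboxylate unit plus the alkyl chain. Both tables are ordinary tibbles
and can be overridden by the user. No aromatic conjugation correction is
applied by default.

Known limitation: group-contribution solubility parameters are sensitive
to the table edition and the molar-volume source, and published values
computed with unstated table choices can deviate from values computed
with the canonical constants by more than the usual few percent — the
package's acceptance suite documents exactly this for two of the nine
reference drugs. Positional isomers are indistinguishable by
construction (one multiset), so the three methoxybenzoic acids share one
result bit-for-bit.

## The synthetic-data generator

`simulate_release()` draws
$Q_i = f(t_i;\theta) + \varepsilon_i,\ \varepsilon_i \sim N(0, \sigma^2)$
with independent additive Gaussian noise on the percent scale (a
multiplicative mode exists for sensitivity studies). A given seed gives
bit-identical curves. Values are not clipped by default; a noiseless
curve leaving $[0, 110]$ percent triggers a warning listing the
offending times.

Default grids (`release_time_grid()`) use 34 points — the count implied
by the degrees of freedom of the reference metric tables — starting at
5 min, log-spaced up to 5000 min to mimic the denser early sampling of
release assays. The upper end is capped where the model leaves its valid
range: at 95 % of the 60 %-crossing time for the power law and at the
100 % crossing for the unbounded linear forms; grids ending within
200 min (fast, burst-type release) are linearly spaced. Models with a
negative intercept start just above their zero crossing.

What the generator emulates: curve shapes of the four model families,
realistic point counts, monotone-tending trajectories inside the valid
release window, and homoscedastic observation noise. What it does not
emulate: replicate fabric swatches, heteroscedastic or autocorrelated
instrument error, calibration drift, aliquot-volume perturbations, or
any mechanistic transport physics (no Fickian series solutions are
solved — classification is entirely exponent-based). Passing round-trip
tests therefore demonstrates estimator correctness and calibration, not
that real fabrics obey these models.

## Problem sizes and test design

The test suite fits noiseless 18–34-point curves for all 36 reference
equations (each fit well under a second), checks degrees-of-freedom
consistency of every published RSS/reduced-χ² pair, replays model
selection from the published metric tables of all nine drugs, and runs a
200-seed calibration study (noise sd 1 %) verifying that the mean
power-law parameter estimates fall within three standard errors of the
generating values. These sizes were chosen as the smallest that exercise
every code path with comfortable statistical resolution.

`scripts/acceptance.R` recomputes the headline round-trip parameters
from scratch against the installed package and writes them as JSON; see
the README for invocation.
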