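---
title: "Methods: odor-value radar scoring and power-law release kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: odor-value radar scoring and power-law release kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoaroma)
```

This vignette explains the models implemented in nanoaroma, the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic-data generators do and do not emulate, and the numerical
choices made where the design was genuinely open.

## The problem

Essential oils are mixtures of volatile terpenes whose fragrance and
bioactivity degrade on exposure to air, light, and heat. Encapsulating
the oil in a biodegradable polymer shell (e.g. polycaprolactone
nanocapsules of ~180 nm) protects the volatiles and slows their release.
Evaluating such a formulation raises three computational questions this
package answers:

1. **What does the formulation smell like?** Quantified by odor-value
   scoring of the equilibrium headspace and an eight-family perfumery
   radar.
2. **How fast does it release?** Quantified by fitting the power-law
   release model to headspace time series and classifying the transport
   mechanism from the exponent.
3. **How good is the formulation?** Quantified by encapsulation
   efficiency, DPPH antioxidant scavenging, and replicate coefficients of
   variation.

## Headspace model

The gas phase in equilibrium with the liquid oil is approximated as an
ideal solution under an ideal gas:

$$p_i = \gamma_i x_i P_{vap,i}, \qquad
  c_i = \frac{p_i M_i}{R T} \quad (\gamma_i = 1 \text{ by default})$$

with mole fractions derived from GC area percentages treated as
mass-proportional, $x_i \propto \text{area}_i / M_i$. The canonical
concentration unit is mg/m³ because odor thresholds are tabulated in that
unit; measured series in µg/mL convert at the boundary (1 µg/mL =
1000 mg/m³). The default temperature is 298.15 K (the usual controlled
25 °C bench condition); it is an explicit argument everywhere.

Liquid-phase non-idealities of terpene mixtures are real but are not
modeled; an optional per-compound activity-coefficient map lets users
impose measured or estimated coefficients without changing the code
path. Both the predicted route (composition + vapor pressures) and the
measured route (headspace concentration CSVs) feed the same downstream
scoring, since published radars do not always state which was used.

## Odor values and the perfumery radar

For each compound with a tabulated odor threshold,

$$OV_i = \frac{c_i}{ODT_i}$$

a dimensionless intensity: how many times above its human detection
threshold the compound sits in the gas phase. Compounds *without* a
threshold cannot be scored; they are excluded with an explicit logged
signal, never treated as threshold zero (which would produce infinite
intensity).

Each compound carries 1–3 ranked olfactory families; its odor value is
distributed over them with rank weights

| families | primary | secondary | tertiary |
|---|---|---|---|
| 1 | 100% | — | — |
| 2 | 70% | 30% | — |
| 3 | 60% | 30% | 10% |

which sum to 1 per compound, so family aggregation conserves total odor
value — a property the test suite checks over random compound sets.
Family values are normalized to shares, $OV'_j = OV_j / \sum_j OV_j$,
making radars comparable across formulations of different overall
intensity; the all-zero case is returned as a flagged degenerate profile
rather than an error, because a blank headspace is a legitimate
measurement outcome. The polygon uses eight fixed axes (citrus, fruity,
floral, green, herbal, musk, oriental, woody), equally spaced clockwise
from the top.

**The "expressive compounds" filter.** Published radars are typically
built from the few compounds with significant headspace presence. This
is operationalized as a minimum share of the summed odor value
(`min_ov_share`, default 0.001 = 0.1%); compounds below it are dropped
and logged. The filter is data-driven but its interaction with the ideal
headspace model deserves honesty: under Raoult behavior a trace compound
with a tiny threshold (Z-β-ocimene, ODT 0.010 mg/m³) can carry a large
*predicted* odor value even though it may not be detected in a *measured*
headspace, while a heavy sesquiterpene with low vapor pressure
(β-caryophyllene, 4 Pa) can fall below the floor. Radar sets quoted in
the literature from measured chromatograms therefore need not coincide
with the ideal-model set; the dominant-family conclusion (woody, driven
by α-pinene's 39% liquid share and 513 Pa vapor pressure) is robust to
this choice, and the packaged-fixture tests assert exactly that
qualitative result, not a specific retained set.

## Release kinetics

Fractional release follows the semi-empirical power law

$$\frac{M_t}{M_\infty} = k\,t^{\,n}$$

where $k$ (min$^{-n}$) bundles structural and geometric effects and the
exponent $n$ diagnoses the transport mechanism. Fitting minimizes the
**linear-space** residual sum of squares with the Nelder–Mead simplex —
the estimator the release literature reports SSE/RMSE columns for — over
$(\ln k, \ln n)$ so both parameters stay positive without constraints.
The closed-form log–log OLS line provides the initial guess and, on
noiseless data, an independent oracle the optimizer must agree with to
1e-6 (tested). Defaults: 2000 iterations, SSE tolerance 1e-10; identical
input and options give bit-identical results.

Data hygiene: points with $t \le 0$ or fraction $\le 0$ cannot enter
(the log–log initializer is undefined there); fractions ≥ 1 are outside
the model's validity and are excluded by default; an optional
`fraction_cap = 0.6` restricts fitting to the classical power-law
validity window ($M_t/M_\infty \le 0.6$) — off by default since release
studies routinely fit the full curve. When the asymptote $M_\infty$ is
not supplied it is plateau-estimated as the mean of the longest trailing
window (≥ 3 points) whose relative spread stays below 2%, with the
provenance recorded; a monotone series with no plateau is a hard error,
not a guess.

Goodness of fit uses the standard definitions: $R^2 = 1 - SSE/SS_{tot}$,
$R^2_{adj} = 1-(1-R^2)(N-1)/(N-p-1)$, $RMSE = \sqrt{SSE/N}$ (divisor $N$
by default, $N-p$ selectable). Note that published tables in this
application area occasionally print $R^2_{adj} > R^2$, which the standard
formula cannot produce ($R^2_{adj} \le R^2$ always, a tested property);
this package implements the standard definition.

**Mechanism classification.** For spheres the Fickian-diffusion reference
exponent is 0.43 and the Case II (polymer-relaxation) bound 0.85; slab
(0.50/1.00) and cylinder (0.45/0.89) geometries use the corresponding
literature exponents. Exact equality of a fitted exponent with a
reference value is measure-zero, so a tolerance band is required. The
default half-width is **0.01**: exponents in this literature are reported
to two decimals, so the band accepts as "Fickian" precisely those values
that would print as 0.42–0.44. A wider band (e.g. 0.02) would swallow
exponents like 0.45 that practitioners interpret as anomalous transport;
the band is an explicit argument for users who prefer a different
convention. Between the bands: below Fickian − tol is
quasi-Fickian/combined, between the bands anomalous (non-Fickian), above
Case II + tol super Case II. Ties and boundary values land deterministically
by the closed Fickian/Case II bands.

## Assay formulas

- Encapsulation efficiency: $EE\% = 100\,(m_{if} - m_{uf})/m_{i0}$ —
  suspension mass minus filtrate (free, non-encapsulated) mass over the
  initially added mass. A filtrate below the detection limit is treated
  as zero and the result flagged as a **lower bound**, because undetected
  free compound can only raise, never lower, the true EE. Physically
  inconsistent balances ($m_{uf} > m_{if}$, or $m_{if} > m_{i0}$) warn
  rather than fail: they occur in real data through quantification error
  and should be visible, not silently clamped.
- DPPH scavenging: $\%SR = 100\,(ABS_{control} - ABS_{sample}) /
  ABS_{control}$ at 515 nm, control measured alongside each sample.
- Coefficient of variation: $CV\% = 100\,\sigma/\mu$; when a published
  mean ± sd is supplied directly, sd is used as given (sample convention
  applies only when computing from raw replicates).
- Calibration: OLS with intercept by default (`through_origin` is a
  flag), inversion $(area - b)/a$, extrapolation beyond the standard
  range allowed but flagged.

## Synthetic-data generators

The generators produce data with the statistical structure the analysis
assumes, so every stage is testable without instrument files:

- `simulate_release()`: $\min(1, k t^n (1+\varepsilon_t))$,
  $\varepsilon_t \sim N(0, \sigma^2)$ i.i.d. — multiplicative because GC
  quantification error is relative. Defaults are the fitted essential-oil
  kinetics ($k = 0.0234$ min$^{-n}$, $n = 0.45$), 20 log-spaced times in
  [1, 2000] min (log spacing matches how power-law curvature is
  resolved), $\sigma = 0.02$ (triplicate GC scatter).
- `simulate_composition()`: Dirichlet draw centered on a base
  composition (packaged oil table by default) rescaled to the base total,
  precision 5000 — chosen so component scatter matches the few-percent
  relative standard deviations of published triplicate area tables.
- `simulate_dpph_series()`: saturating first-order kinetics
  $SR(d) = SR_\infty - (SR_\infty - SR_0)e^{-rd}$ with additive noise
  (absorbance error is instrumental, not proportional), inverted to
  absorbance pairs with $ABS_{control} = 1$. Defaults ($SR_0 = 4.5$%,
  $SR_\infty = 80$%, $r = 0.25$/day, readings every 5 days for a month)
  emulate a free essential oil that saturates its scavenging capacity
  within about three weeks.

Each generator takes one integer seed, seeds its own RNG locally, and
restores the caller's RNG state, so outputs are independent of call
order. What the generators do **not** emulate: port-to-port diffusion
attenuation along a sampling tube, compound-specific detection limits,
drift or autocorrelated noise, and perceptual mixture interactions
(masking/synergy). Passing tests on synthetic data therefore demonstrate
correctness of the estimators under the stated noise model, not validity
of the physical approximations for any particular real oil.

## Problem sizes and determinism

The test suite runs generate-and-refit recovery at 20 points per curve
over 50 seeds (noise 0.02) plus smaller sweeps at 0 and 0.05 — enough to
estimate median relative error stably while keeping the whole suite in a
few seconds. All fits are deterministic; only the generators consume
randomness, always through an explicit seed.

## Known limitations

- Raoult-law headspace prediction ignores terpene-mixture non-idealities;
  activity coefficients are accepted but not estimated.
- Odor thresholds span orders of magnitude and dominate the radar's
  sensitivity; compounds with absent thresholds are invisible to the
  radar regardless of abundance.
- The power-law model is descriptive: the mechanism call inherits the
  geometric assumptions (sphere by default) and says nothing about which
  physical process produced the exponent.
- Plateau estimation of $M_\infty$ assumes the experiment actually
  reached stationarity; truncated experiments must supply $M_\infty$
  explicitly.
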