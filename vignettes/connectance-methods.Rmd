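---
title: "Methods: connectance analysis of photosynthetic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectance analysis of photosynthetic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photonet)
```

## The statistic

Plant ecophysiology usually compares treatment means variable by
variable. Connectance analysis asks a complementary, systemic question:
how *tightly coupled* are the physiological variables to one another
within a treatment, regardless of their mean levels? A network is
declared a priori as a set of variable pairs; for each pair the Pearson
correlation $r$ across the replicate plants of one treatment cell is
transformed to

$$z = \tfrac{1}{2}\,\ln\!\frac{1 + |r|}{1 - |r|} = \operatorname{atanh}(|r|),$$

and the *connectance* of a module is the unweighted mean of $z$ over its
pairs. Taking $|r|$ makes $z$ a pure strength: a tightly negatively
coupled pair contributes as much as a tightly positive one. The
variance-stabilising $\operatorname{atanh}$ stretches the scale near
$|r| = 1$, so connectance is dominated by near-deterministic
relationships rather than by many weak ones.

The default network ships as data (`default_network()`, editable as
YAML): a gas-exchange module of nine pairs among AmaxL (light-saturated
photosynthetic capacity), gs, E, Rd, Pr and Ci; a photochemical module of
six pairs among Fv/Fm, dF/Fm', NPQ and ETR; and a single linking pair,
ETR--AmaxL, that joins the two subsystems. The global connectance is

$$C_{g,\mathrm{total}} = \tfrac{1}{2}\,(C_{g,\mathrm{pho}} + C_{g,\mathrm{ge}}),$$

the mean of the two *module* connectances — not the pooled mean over all
15 module pairs, and without the linking pair, which is reported
separately. This aggregation rule is the one consistent with published
reference tables for a C3 soybean and a C4 palisade grass shipped in
`inst/extdata/reported_connectance.csv`: recomputing the global value
from the reference module values reproduces every printed total to
within ±0.01 at its printed precision, for nine of the ten cells. The
tenth (the C4 grass at 20 °C) differs in the last printed digit
(1.29 printed vs 1.28 recomputed) and is flagged `usable = FALSE` in the
shipped file.

Three reading choices deserve emphasis, because the literature leaves
them open:

* **Correlation type.** Pearson, following the connectance literature's
  original procedure. The correlation step is isolated in
  `pearson_r()`, so a rank-based variant is a one-line substitution.
* **Significance filtering.** All pairs enter the average, significant
  or not. Testing each pair (`correlation_pvalue()`, exact $t$ null on
  $n-2$ df) is reported per pair, but excluding or zeroing weak pairs is
  an explicit opt-in (`sig_filter = TRUE`), never the default: with
  $n = 7$ replicates the significance threshold at $\alpha = 0.05$ is
  $|r| \gtrsim 0.75$, and filtering would discard most of the network.
* **Replication unit.** Correlations are computed across replicate
  plants within one treatment cell, matching designs in which the plant
  is the replicate. Pooling across treatments would conflate
  treatment-mean differences with within-treatment coupling.

## Numerical choices

* $|r| \ge 1 - 10^{-12}$ (exact collinearity, common in degenerate
  small-$n$ resamples) is clamped to $1 - 10^{-12}$: $z \approx 14.2$
  rather than infinity. User-facing paths warn; resampling interiors
  clamp silently, since such draws are expected there.
* Missing cells use pairwise-complete deletion with the effective $n$
  reported per pair; fewer than 3 complete pairs, or a constant vector,
  is an error, never a silent `NA`.
* Report tables round half-up (`round_half_up()`, ties away from zero,
  with a $10^{-9}$ guard for binary representations of decimal
  midpoints); full precision is always retained in returned objects.
* Bootstrap intervals are percentile intervals over row resamples;
  resamples with a constant column are redrawn and counted. The
  permutation test reassigns plants to groups and uses the add-one
  p-value estimator $(1 + \#\{|\Delta|_{\mathrm{perm}} \ge
  |\Delta|_{\mathrm{obs}}\})/(1 + B)$, which is level-exact for
  exchangeable nulls. Both are pure functions of their seed: the global
  RNG state is saved and restored.

## Leaf physiology models

The simulator and the curve-level operations use the field's standard
models, written here from their defining equations:

* **C3**: FvCB with $A_c = V_{cmax}(C_i - \Gamma^*)/(C_i + K_c(1 +
  O/K_o))$, $A_j = J(C_i - \Gamma^*)/(4C_i + 8\Gamma^*)$, $A =
  \min(A_c, A_j) - R_d$, at fixed published 25 °C kinetic constants
  ($K_c = 404.9$, $K_o = 278.4$, $\Gamma^* = 42.75$, $O = 210$).
  Temperature scaling of the constants is deliberately absent: single
  cuvette-temperature data cannot identify it. The limb transition is a
  hard `min` by default; a hyperbolic smoothing is available behind a
  flag because it shifts fitted $V_{cmax}$ slightly.
* **C4**: the simplified enzyme-limited form $A = \min(V_{pmax} C_i /
  (C_i + K_p),\, V_{cmax}) - R_d$, which saturates an order of magnitude
  below the C3 form in $C_i$ and, with a bundle-sheath compensation
  point near zero, yields near-zero photorespiration — the two
  signatures separating the pathways in the simulated tables.
* **Light response**: the non-rectangular hyperbola, with
  $A(0) = -R_d$ exactly and the rectangular hyperbola recovered as the
  $\theta \to 0$ limit.
* **Fluorescence**: $F_v/F_m$, $\Delta F/F_m'$, $qP$, NPQ and
  $\mathrm{ETR} = \Delta F/F_m' \cdot \mathrm{PPFD} \cdot f_{PSII}
  \cdot \alpha$, with $f_{PSII} = 0.5$ and absorptance $\alpha = 0.84$
  as explicit arguments (they are species-dependent). All outputs are
  invariant to rescaling the raw signals.
* **Derived indices**: stomatal limitation $L_s = 100\,(A(C_a) -
  A_{op})/A(C_a)$; alternative electron sink as
  $(\mathrm{ETR}/4)/(A + R_d)$ — published variants of this index
  differ, and the denominator convention is documented at the function.
* `AmaxCO2`, the CO2-saturated potential, is operationalised as the
  fitted model's prediction at $C_i = 2000$ µmol mol$^{-1}$; "plateau"
  has no unique evaluation point otherwise.

Curve fitting uses Levenberg–Marquardt least squares with deterministic
initialisation ($\phi$ and $R_d$ from a line through the three
lowest-light points; $V_{cmax}$ from inverting the Rubisco limb on the
low-$C_i$ points). On noiseless model-generated curves both fitters are
identity maps on the parameters to well below 1%; under additive noise
of 0.5 µmol m$^{-2}$ s$^{-1}$ the median $V_{cmax}$ bias over 100
simulated curves stays below 5%.

## What the synthetic data emulate — and what they do not

Two tiers generate replicate tables:

1. **Direct tier** (`simulate_correlated()`): multivariate-normal draws
   with an exact target correlation matrix (Cholesky square root;
   slightly indefinite user matrices are eigenvalue-clipped to the
   nearest PSD correlation with a warning). This tier provides
   distributional ground truth: for an equicorrelated target $\rho$ the
   population connectance is exactly $\operatorname{atanh}(\rho)$, which
   the estimator recovers to < 0.02 at $n = 10{,}000$.
2. **Mechanistic tier** (`simulate_leaf_cell()`): each replicate plant
   draws its parameters ($V_{cmax}$, $g_s$, $R_d$, fluorescence
   efficiencies) around the scenario means with a shared latent "vigor"
   factor; the scenario's `coupling` in $[0,1]$ is the loading of every
   parameter on that factor, so any two coupled parameters correlate at
   about `coupling`². The plant's operational $C_i$ solves the
   supply–demand balance $A(C_i) = g_s(C_a - C_i)$; synthetic A/Ci and
   A/PPFD curves (with additive cuvette noise, and small actinic-light
   fluctuation so ETR is not an exact multiple of $\Delta F/F_m'$) are
   then refit to produce the measured capacities, exactly as an
   instrument session would. `fit_curves = FALSE` swaps the refit for
   the closed-form forward evaluation; large-$n$ distributional checks
   use it because ten thousand nonlinear fits would only test the
   optimiser again.

The presets encode the two study designs (2 species × 3 temperatures,
2 species × 2 water regimes, 7 plants per cell) with parameter means at
magnitudes typical of each functional type and couplings that rise with
stress, so the stressed cells have tighter networks. Inflating the
water presets to 200 plants per cell makes the direction
$C_{g,\mathrm{total}}(30\%) > C_{g,\mathrm{total}}(100\%)$ essentially
deterministic for both species.

What passing tests therefore show: the statistic, its aggregation rule,
its resampling inference and the curve-level operations are correct on
data whose ground truth is known, and the full pipeline reproduces the
qualitative stress-tightening pattern. What they cannot show: agreement
with any real study's connectance values — the raw plant data behind the
shipped reference tables were never deposited, so only the printed
module-to-total arithmetic and the percent-change claims are
recomputable, and the suite checks exactly those. The simulator's
single-factor Gaussian coupling is also a deliberate simplification: it
sets pairwise correlation levels but cannot produce, e.g., strongly
heterogeneous correlation signs within a module, which real stress
physiology can.

## Problem sizes used by the test suite

Distributional assertions use $n = 6{,}000$–$10{,}000$ replicates for
law-of-large-numbers checks, 100 seeded runs for coverage (bootstrap
95% intervals contain the population connectance in ≥ 90 of 100 runs at
$n = 500$), and 1000 simulated null pairs at $n = 20$ per group with 199
permutations each for the size of the permutation test (empirical
rejection within [0.03, 0.07] at $\alpha = 0.05$). The end-to-end
direction check runs the water presets at 200 plants per cell through
the full curve-fitting path. These sizes were chosen so that each
assertion's Monte-Carlo error is small against its tolerance.

## Known limitations

* With $n = 7$ the sampling noise of a single connectance value is of
  the same order as the treatment effects typically reported; the
  bootstrap rows in every report table exist to keep that visible.
  Single-cell connectance differences at $n = 7$ should be read through
  the permutation test, not at face value.
* No multiple-testing correction is applied across pairs — the
  statistic averages strengths; it does not select edges.
* No graph-theoretic machinery (degree distributions, driver-node
  controllability) and no two-way ANOVA with interactions: comparisons
  follow the one-way-within-species reporting unit.
* The AES/alternative-electron-sink index has no universally agreed
  formula; ours is one published convention and is labelled as such.
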