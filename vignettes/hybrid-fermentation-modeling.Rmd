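---
title: "Hybrid mechanistic-LSTM modeling of mixed-sugar yeast fermentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid mechanistic-LSTM modeling of mixed-sugar yeast fermentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridferm)
```

## The process and the model

`hybridferm` models aerated batch cultivation of *Saccharomyces
cerevisiae* on a sugarcane-like substrate mix — sucrose, glucose and
fructose — with urea as the nitrogen source. Such cultures show three
phenomena that a useful model must capture:

* **invertase-driven sucrose hydrolysis**: extracellular invertase splits
  sucrose into glucose and fructose faster than the cells take the
  monosaccharides up, so both transiently accumulate early on;
* **the Crabtree effect**: with abundant glucose, ethanol is produced
  even under fully aerobic conditions;
* **the diauxic shift**: once the fermentable sugars are gone the
  culture re-assimilates the accumulated ethanol at a much lower
  specific growth rate, giving a two-phase biomass profile.

The mechanistic core is a six-state mass-balance system for biomass
$X$, glucose $G$, fructose $R$, sucrose $S$, urea $U$ and ethanol $Et$
(all g/L), plus the culture volume $V$ (constant in batch; the feed and
dilution terms are kept in the balances so fed-batch extensions only
need a feed schedule). Growth is Monod-type on each monosaccharide with
non-competitive ethanol inhibition,

$$\mu_G = \mu_{max,G}\,\frac{G}{K_G+G}\,\frac{K_{i,Et}}{K_{i,Et}+Et},$$

respiratory growth on ethanol is Monod in $Et$ and repressed by the
fermentable monosaccharide pool $AF = G + R$,

$$\mu_{Et} = \mu_{max,Et}\,\frac{Et}{K_{Et}+Et}\,
  \frac{K_{inh,AF}}{K_{inh,AF}+AF},$$

and the total specific growth rate is $\mu_X = \mu_G + \mu_R + \mu_{Et}$
(the culture is isothermal at 30 °C, so no temperature factor enters).
Sucrose uptake is Monod with a hydrolysis yield $Y_{AF/S}$ feeding the
glucose and fructose pools equally ($\approx 0.526$ g monosaccharide per
g sucrose would be the stoichiometric value per pool). Sugar consumption
combines growth demand, maintenance and the ethanol-linked flux; urea
uptake is proportional to growth through $1/Y_{X/Ur}$.

### Smooth gating instead of hard switches

Every rate that must shut down when a pool empties is multiplied by a
leaky-ReLU-style gate normalized by its own argument,

$$g(z) = \frac{\max(\gamma z,\, z)}{\sqrt{z^2+\epsilon}},
  \qquad z = c - 0.001\ \mathrm{g/L},$$

which runs continuously from a tiny negative leak (magnitude at most
$\gamma\,0.001/\sqrt{\epsilon}$) up to 1. The same construction with the
mirrored argument $0.001 - G$ switches the fructose parameters to their
post-glucose values once glucose is depleted — glucose catabolite
repression as a pure function of the instantaneous state. The printed
form of that switching is a self-assignment, which is ill-defined inside
an ODE right-hand side; `effective_fructose_params()` implements it as a
blend $\mu_{max,R} + s\,(\mu_{max,postG} - \mu_{max,R})$, which
preserves both endpoints.

$\gamma$ and $\epsilon$ have no published values. The defaults are
$\gamma = 0.01$ (the conventional leaky slope) and
$\epsilon = 10^{-6}\,(\mathrm{g/L})^2$, which must be well below the
squared threshold so the gate is effectively 0/1 one threshold width
away from the switch point. Both are exposed in `gating_config()`.

### Choices where the source equations are ambiguous

* The ethanol-linked term of the fructose consumption rate divides by
  the *glucose* ethanol yield in the printed equations, which leaves
  $Y_{Et/R}$ absent from the model altogether even though it is
  reported as a significant, well-determined parameter. The package
  default follows the printed equations;
  `model_options(fructose_ethanol_yield_denominator = "R")` enables the
  plausible correction, and the identifiability and recovery analyses in
  the tests run under that option (otherwise $Y_{Et/R}$ is structurally
  unidentifiable — the objective is exactly flat in it).
* Ethanol production is gated on fructose only, as printed;
  `ethanol_production_gate = "G+R"` gates it on both monosaccharides.
* The urea balance as printed adds the dilution term all other balances
  subtract; the minus sign is used (moot in batch).
* The calibration objective divides residuals by the per-variable
  maximum of the experimental data. A pointwise-normalization mode
  exists behind a flag but is singular wherever a substrate is depleted,
  so it is not the default.

### Numerics

The ODE system is integrated with the explicit 8th-order Dormand–Prince
pair (`deSolve`, `rkMethod("rk78dp")`) at `atol = rtol = 1e-6`. The
rate laws live twice in the package: reference R functions
(`smooth_gate()`, `specific_rates()`, `reaction_rates()`,
`fermentation_rhs()`) that define the semantics and are unit-tested
against hand-evaluated values, and a compiled C mirror used by the
solver and the sensitivity system; a test asserts agreement to 1e-12 on
random states. Consumption rates are multiplied by $1\{c>0\}$ exactly
at $c \le 0$ so the gate leak can never drive a pool negative; solver
output in $(-10^{-3}, 0)$ (overshoot on the order of the tolerance near
depleted pools) is clamped to zero, larger negatives warn. Around gate
crossings the 1e-6-tolerance solution is accurate to roughly 1e-3 g/L
against a 1e-9 reference — adequate for data at measurement noise, and
tightened automatically wherever a test needs more.

## Synthetic experiments

No measurements are distributed with the package, so a generator
(`generate_experiment()`) emulates the study design the analysis
assumes: two train-like biological replicates with initial conditions
drawn from Normal distributions truncated at zero (sucrose
32.7 ± 3.9, glucose 27.3 ± 3.8, fructose 27.1 ± 4.1, biomass 0.5 ± 0.1,
urea 2.6 ± 0.7 g/L), one shifted test batch at fixed
39.6/27.5/25.8/1.2/2.3 g/L, ethanol 0 at inoculation, working volume
0.3–0.4 L. Sample times are drawn every 1.5–3 h up to 30 h and every
6 h afterwards out to 48 h. Measurement noise is Gaussian, truncated at
zero, with a 5% relative SD and a 0.02 g/L floor — the error model is
the package's own choice (the replicate SDs of the initial conditions
are the only published magnitude guidance).

What the generator does **not** emulate: dissolved-oxygen limitation
(the kinetic model carries no oxygen state, and the real cultures show
oxygen-linked variability between replicates), inter-replicate
invertase variability, assay-specific error structure (UHPLC vs
enzymatic urea kits), or autocorrelated sensor drift. Tests passing on
synthetic data therefore demonstrate correctness of the algorithms
under the model's own assumptions, not predictive validity on real
cultures.

`densify()` implements the preprocessing used before calibration and
identifiability analysis: per channel, polynomials of degree 2–6 in
standardized time are fit by least squares and the degree with the best
*adjusted* R² is kept; the fit is evaluated on an even grid of 10 points
per free parameter and clamped at zero. The adjustment and the clamp are
the package's guard against oscillatory overfit — the source only asks
that fits maximize R² while remaining consistent with process knowledge.
A constant channel gets a degree-0 fit with R² defined as 1. Train
replicates are densified separately and both enter the objective.

## Calibration

`calibrate()` minimizes the normalized sum of squared errors with a
grey wolf optimizer (`gwo_minimize()`): the pack moves toward the three
best wolves with the canonical coefficient vectors $A = 2a r_1 - a$,
$C = 2 r_2$, $a$ decaying linearly 2 → 0; solver failures score a 1e9
penalty so the search continues. Pack size defaults to 30 (a common
choice for a ~20-dimensional problem).

The search box starts at ±30% around the starting values and is
recalibrated after every round: a parameter found within relative 1e-6
of a bound gets a new box of ±10% around its current estimate,
intersected with an order-of-magnitude clamp around the literature
bounds. One pack persists across rounds and the coefficient decay spans
the whole run, so rounds are checkpoints rather than restarts; the run
stops early once a round brings neither an improvement nor a bound
move. With the default 20-epoch rounds a misplaced parameter can move
its box by at most ×1.1 (or ×0.9) eight times in a 160-epoch budget —
about a factor 2. Recovery experiments that must traverse the full
order-of-magnitude gap between the literature starting values and the
calibrated estimates therefore use 5-epoch rounds (32 recalibrations),
a choice documented with the experiment.

A known limitation, measured by the acceptance suite: with a 30-wolf
pack and 160 epochs the optimizer reliably fixes the strongly
determined parameters (growth rates, major yields) but cannot resolve
parameters whose objective contribution is three to four orders of
magnitude below the leading ones (the ethanol-uptake pair, $K_{inh,AF}$,
$K_G$). That matches the published uncertainty picture — several of
those parameters carry 1-σ confidence intervals of 20–88% — and is a
property of the experimental design and optimizer budget, not of the
implementation.

## Identifiability and uncertainty

`forward_sensitivities()` integrates the augmented system
$\dot S = (\partial f/\partial x)S + \partial f/\partial\theta$ with
$S(0)=0$; the Jacobians of the smooth gated right-hand side are central
finite differences evaluated in compiled code (step $\approx
6\times10^{-6}$ relative, the usual cube-root-of-eps choice). The
augmented system is non-stiff and integrates with an Adams
predictor-corrector, falling back to BDF at tightened tolerance. An
independent oracle — central differences of the *solution* — agrees to
better than 1e-3 relative error on every parameter.

`pra_metrics()` builds the scaled sensitivity matrix
$(\partial x_v/\partial\theta_j)\,\theta_j/N_v$ with $N_v$ the
per-channel maximum (the same normalization as the objective), forms
the covariance $s^2 (S^\top S)^{-1}$ with $s^2$ the max-normalized
residual mean square on $n_{obs} - n_{free}$ degrees of freedom, and
reports per parameter the relative SD, the t-value $1/\mathrm{relSD}$,
confidence bounds (± 1 σ — the convention that reproduces the published
interval for the sucrose half-saturation constant; ±1.96 σ is a flag
away), the correlation matrix and the per-channel mean absolute scaled
sensitivity $G^{prom}$. Parameters with numerically zero sensitivity
columns get infinite variance (t = 0) rather than the spurious
near-zero variance a pseudo-inverse would assign to a null-space
direction. `sequential_fixing()` then applies the screening criteria in
order — fix $t \le 2$, then break $|K| \ge 0.95$ pairs by fixing the
smaller-t member (ties by smaller mean $G^{prom}$), then *report*
parameters whose sensitivity is below 1e-3 of the global maximum
without fixing them, since such parameters can still be
phenomenologically necessary.

`monte_carlo_bands()` perturbs every parameter independently with a 5%
relative SD (Normal, truncated at an order of magnitude around the
nominal value), runs 100 simulations by default, and reports the
pointwise min/max envelope; at least 80% of draws must integrate.

## The residual LSTM and the hybrid blend

The data-driven stage never sees raw measurements: its only input is
the residual series $r(t_i) = y_{exp}(t_i) - y_{pheno}(t_i)$ over the
six channels, min-max scaled to the unit interval with bounds fitted on
training residuals only (test residuals may leave the unit interval; a
channel constant to within 1e-8 relative range is mapped to zeros).
Look-back windows of length $p = 5$ feed a two-layer LSTM — the
standard gate recurrence with sigmoid input/forget/output gates and a
configurable candidate/output activation, $h_0 = c_0 = 0$ — whose final
hidden state passes through a linear dense layer of width 6. The cell,
backpropagation through time and the Adam/RMSprop/Nadam updates are
implemented in the package and verified against numerical gradients and
an independently written scalar recurrence.

Training minimizes one-step MSE on a chronological 80/20 split (random
splitting would leak future information into fitting), stops early
after 15 non-improving validation epochs (500-epoch cap), and restores
the best-validation weights. Hyper-parameters are tuned by a
tree-structured Parzen estimator (`tpe_search()`): after a random
startup phase the trials are split at the 0.25 loss quantile,
per-dimension densities are estimated for the good and bad sets
(Gaussian kernels for numeric dimensions, smoothed counts for
categorical ones), and each step proposes the candidate maximizing the
good/bad density ratio among 24 samples from the good density.

`hybrid_predict()` blends the two predictions,
$y_{hybrid} = \lambda_{pheno}\, y_{pheno} + \lambda_{ml}\, y_{ml}$ with
defaults $\lambda = (0.3, 0.7)$, where $y_{ml}$ is defined as the
mechanistic prediction plus the inverse-scaled predicted residual —
this reading makes $\lambda = (1, 0)$ reduce exactly to the mechanistic
model. For the first $p$ points no window exists and the hybrid falls
back on the mechanistic trajectory, which produces the visible jump at
the window boundary; it is an artifact of the windowing mechanism and
is documented rather than smoothed. Two roll-out policies exist:
teacher forcing (windows from measured residuals, the default where
observations exist) and recursive roll-out (the model feeds on its own
predictions past the first window).

## Evaluation conventions

`rmse()` compares predictions and observations at matching times per
channel; the `Total` of an RMSE table is the arithmetic mean of the six
per-variable RMSEs — the convention under which the published
worked-example rows reproduce their printed totals (a pooled
quadratic-mean alternative sits behind a flag). Fold reductions are
mechanistic/hybrid total ratios reported to one decimal. RMSEs are
conventionally shown at two decimals.

## Problem sizes used by the shipped experiments

The test suite and the acceptance script run entirely on synthetic
data: two train replicates and one test batch per experiment, ~19–25
samples per run over 48 h, 100 Monte Carlo iterations, 10 TPE trials
over a reduced unit grid (16–64 units), and a 160-epoch, 30-wolf
calibration budget. These sizes keep a full run in minutes on one CPU
while exercising every stage at the fidelity the method analysis needs;
all of them are plain function arguments, so larger studies only change
a call.

## Known limitations

* No oxygen state: the model cannot express oxygen-limited variability
  between nominally identical runs.
* No cell-death term: late-phase biomass is overestimated whenever
  death becomes non-negligible.
* The ethanol-uptake parameters ($\mu_{max,Et}$, $Y_{cEt/X}$) are
  near-collinear by construction; expect wide intervals or a
  non-identifiability flag unless the data strongly excite the
  ethanol-consumption phase.
* Global calibration at the default budget resolves the dominant
  parameters only; see the calibration section.
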