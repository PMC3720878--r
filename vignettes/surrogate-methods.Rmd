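---
title: "Surrogate modeling of AMPA receptor activation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate modeling of AMPA receptor activation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synsurr)
```

## The problem

When a presynaptic vesicle fuses with the active zone, a few thousand
glutamate molecules are dumped into a cleft roughly 15–20 nm high. They
diffuse, bind AMPA receptors on the postsynaptic density, escape laterally
past the apposed membranes, and are cleared by glutamate transporters on the
surrounding neuronal and glial membranes. The observable this package works
with is the percentage of receptors in the conducting (open) state over the
10 ms following release, sampled every microsecond — a 10,001-point curve
with a fast rise to a single peak and a slow decay toward zero.

Particle-level Monte Carlo simulation of this process is accurate but far
too expensive to embed in network-scale models, where millions of synapses
would each need hundreds of repeated runs. `synsurr` implements a surrogate
strategy: simulate a *corpus* of synapses spanning the physiological
parameter ranges once, then learn the receptor activation function

$$\mathrm{AMPA_O} = F([\mathrm{AMPA}], [\mathrm{T}], L_s, H_c, E, t)$$

so that new synapses can be predicted without further simulation. The five
synapse parameters are the AMPA receptor density on the PSD
(1000–3000 µm⁻²), the transporter density on extrasynaptic membranes
(0–10000 µm⁻²), the synapse side length (150–750 nm), the cleft height
(15–20 nm) and the apposition factor $E \in [1, 2]$ (the apposed membranes
extend to a square of side $E \cdot L_s$). An extended scenario adds the
glutamate diffusion coefficient $D_g$ (0.25–0.75 µm²/ms) as a sixth
variable; otherwise $D_g = 0.4$ µm²/ms. Each vesicle carries 5000
glutamate molecules.

## The corpus simulator

The package generates its corpora with a reduced compartmental model rather
than a particle simulator, keeping every pipeline stage testable at desk
scale.

**Geometry.** Three well-mixed extracellular compartments in series with a
perfect sink: the cleft ($V = L_s^2 H_c$), the perisynaptic apposition
annulus (area $(E^2-1)L_s^2$, same height) and an outer extracellular
compartment. The enclosing tissue volume is taken as a cube of side
$2 E L_s$, and the outer compartment is sized so the total extracellular
space is exactly 20% of that volume, the canonical extracellular fraction
of neural tissue. The intercellular gap in the surround is interpolated
linearly from 38 nm to 65 nm as $L_s$ runs from 150 to 750 nm; how the gap
scales with synapse size in real tissue is not well constrained, and the
linear choice is a modeling convention.

**Transport.** Glutamate escapes cleft → peri → outer → sink with
first-order rates derived from the diffusion coefficient: $8 D_g / L_s^2$
out of the cleft (the characteristic radial escape time $r^2/4D$ with
$r = L_s/2$, times a fixed factor 2 for the two membrane exits), and
analogous rates with the annulus half-width and the outer half-size as
characteristic radii. With $E = 1$ the annulus vanishes and the cleft feeds
the outer compartment directly. These constants preserve the *sign and
ordering* of every parameter dependence; absolute peak amplitudes will
differ from particle simulations, which is why the package's acceptance
surfaces are accuracy metrics of the learning pipeline, not raw curve
amplitudes.

**Kinetics.** Receptor and transporter state dynamics are labelled Markov
models read from editable scheme files. The bundled receptor scheme is the
seven-state AMPA model of Jonas, Major & Sakmann (1993) — closed states
C0–C5 and one conducting state O, with two sequential glutamate-binding
steps; the bundled transporter scheme is a three-state cycle (free → bound
→ translocating → free) with rates in the range reported for glial
transporters, in which the translocation step removes glutamate from the
extracellular space. Because the literature sources report rate constants
rather than printing a canonical table, the schemes live in
`inst/extdata/*.scheme` and everything downstream is parameterized by the
scheme file, never hard-coded. Each state records its number of bound
glutamate molecules, so ligand bookkeeping (free + bound + absorbed) is
exact.

**Stochastic engine.** A binomial tau-leap with the fixed 1 µs step of the
reference simulations: for each state, the number of molecules taking each
outgoing transition in a step is drawn from conditional binomials
(equivalently, a multinomial over channels and "stay"), with
concentration-dependent rates converted through the compartment volume —
the cleft concentration term $N_{glu}/(L_s^2 H_c)$ is what carries the
cleft-height dependence. Per-channel probabilities are capped at 1; if
capped transitions ever exceed 10% of all transitions in a run the engine
raises an error instead of silently distorting the kinetics. Receptor
dynamics are aggregated multinomial counts rather than per-receptor chains
— the law is identical and the counts are much faster. The engine is
written in C++ (Rcpp) because 10,000-iteration stepping dominated runtime
in R by two orders of magnitude.

A deterministic mean-field integrator (`ode_reference()`, via `deSolve`)
solves the same reaction network with continuous counts. It exists as an
oracle: by the law of large numbers the stochastic mean must converge to it
as copy numbers grow, and the test suite asserts agreement within one
percentage point at 10× copy numbers. It is also the cleanest way to check
qualitative geometry effects (the peak amplitude decreases monotonically in
$L_s$) without Monte Carlo noise.

## The five-stage pipeline

**Stage 1 — sampling.** Each 10,001-point mean curve is reduced to 100
points. The *peak interval* runs from $t = 0$ through the (first) global
maximum until the curve first falls to 50% of the peak amplitude; 50 points
are the starts of 50 equal segments of that interval, and 50 more are the
starts of 50 equal segments of the remaining tail. This deliberate
oversampling of the short, high-variability segment preserves the peak
shape in the reduced sample. Segment starts snap *up* to the 1 µs grid
(whether the original study snapped or interpolated is unstated; snapping
keeps every sampled value an actual simulated value), and collisions —
possible when the peak interval is shorter than 50 grid steps — advance to
the next unused grid point so the sample always has 100 distinct on-grid
times. A curve that never decays to half its peak puts all 100 points on
the whole span, with a warning; simulated activation curves never hit this
fallback.

**Stage 2 — folds.** Ten-fold cross-validation partitioned at the
*configuration* level: all 100 points of a synapse stay in the same fold,
so no model is ever validated on a configuration it saw during training.
The partition is a seeded random split into folds whose sizes differ by at
most one; no target-value stratification is applied (the original
description splits configurations into equal groups, which is what is
implemented).

**Stage 3 — learning.** The regressor is an M5-style model tree: splits
chosen to maximize the standard deviation reduction
$\mathrm{SDR} = \mathrm{sd}(T) - \sum_i \frac{|T_i|}{|T|}\mathrm{sd}(T_i)$,
growth stopping when a node's target deviation falls below 5% of the root
deviation or fewer than `min_leaf = 4` cases remain; multivariate linear
models at the nodes (each node's model may use the attributes split on in
its subtree, simplified by greedy term elimination); bottom-up pruning
comparing each node model's adjusted error $\mathrm{MAE} \cdot (n+v)/(n-v)$
against its subtree; and prediction-time smoothing
$p' = (n\,p + k\,q)/(n + k)$ along the path to the root with $k = 15$.
These hyperparameters are the standard M5′ choices from the
Quinlan/Wang–Witten line of work and are all exposed in `m5_control()`.
One robustness refinement from the same lineage (it is how Cubist treats
its rule models) is adopted: every node model's prediction is capped at
the target range the model was fitted on. Without the cap, a held-out
synapse lying in a sparse corner of the parameter space can route to
linear models whose extrapolation leaves the physically meaningful range
entirely (negative percentages), and a single such configuration ruins
corpus-level metrics.
K-nearest-neighbors (z-scored inputs, distance ties to the lowest training
index) and ordinary linear regression are included as baselines; MLP, MARS
and PPR are not implemented natively — any function with the
`function(x, y, seed) -> model` contract can be plugged into
`cross_validate()` as an adapter.

**Stage 4 — validation.** RMSE $= \sqrt{SS_{res}/n}$ and
$R^2 = 1 - SS_{res}/SS_{tot}$ on the held-out points of each fold, on the
0–100 percent scale throughout. Metrics are reported per fold with their
mean and standard deviation; pooled metrics over all points are reported
alongside (whether the original tables pooled or averaged per fold is
ambiguous; both are computed). $R^2$ against a constant reference is
undefined and raises an error rather than returning a silent value.

**Stage 5 — curve fitting.** The cross-validated predicted points of each
configuration are condensed into a closed-form curve by nonlinear least
squares. The preliminary selection study enumerates 65 candidates —
polynomials of degree 1–9, Fourier series with 1–8 terms, Gaussian sums
with 1–8 terms, sine sums with 1–8 terms, 1–2-term exponentials, and the
full rational grid (numerator degree 0–5 × denominator degree 1–5) — and
ranks families by mean RMSE and mean $R^2$ across the corpus. The final
stage uses the two leaders of the original study: the 4/4 rational
(monic denominator, 9 coefficients) and the 8-term Fourier series
(constant, 8 cosine and 8 sine amplitudes and a shared fundamental
frequency: 18 coefficients). For Gaussian sums the package uses
$3k$ coefficients (24 for $k=8$, no constant offset); the published count
of 25 for that family does not match $3 \times 8$ and presumably includes
an offset term, but the difference is immaterial here since the Gaussian
family is not used in the final stage.

### Numerical choices in the fitting machinery

All families are evaluated in the normalized time $u = t/t_{scale}$ (with
$t_{scale}$ the curve span, recorded in every fit): ninth powers of raw
microsecond times would be hopelessly ill-conditioned. Fits are
Levenberg–Marquardt (`minpack.lm`) with analytic Jacobians and
family-specific initialization: polynomials are solved in closed form;
rationals are seeded by linearized least squares (multiplying through by
the denominator); Fourier series profile the fundamental frequency over a
grid, solving the then-linear problem at each candidate; Gaussian terms are
seeded at the largest observed values with width span/(4k); exponentials
take the slow term from a log-linear tail fit. Each fit runs 5 seeded
multi-starts (the deterministic initialization plus 4 perturbations) and
keeps the best residual, exiting early only when a start is already at the
numerical noise floor. Non-convergence sets a flag rather than failing
silently; rational evaluation errors on denominators below $10^{-12}$ in
magnitude. For rational fits the multi-start selection only admits
solutions whose denominator keeps its sign over the whole fitted span:
an activation curve is finite everywhere, so a solution with a pole
between sample points — which can easily arise when fitting 9
coefficients through 100 points — is spurious no matter how small its
residual at the points themselves; if no admissible solution is found the
best inadmissible one is returned flagged as non-converged. Fits with
fixed seeds are bit-reproducible.

The coefficient-estimation study (`fit_coefficient_linear_model()`)
regresses each fitted coefficient linearly on the five synapse parameters
(the V-matrix model) and reports Pearson correlations between coefficients
and parameters — the analysis whose failure motivates the machine-learning
pipeline: fitted-curve coefficients are *not* linear in the synapse
parameters.

### Predicting unseen synapses

A new configuration has no simulated curve to define its peak interval, and
the original description leaves the prediction-time sampling unspecified.
The package uses a two-pass scheme, documented as an interpretation: the
trained surrogate is evaluated on a uniform 1000-point grid, the Stage-1
peak-interval rule is applied to that *predicted* curve to choose 100
sampling times, the surrogate is evaluated there, and the final family is
fitted to those points, yielding the dense closed-form curve. Parameters
outside the training ranges warn and extrapolate rather than refuse.

## What the synthetic corpus does and does not show

The generator's defaults reproduce the reference study conditions: uniform
independent sampling over the ranges above, 10,000 steps of 1 µs, and
200-run averages per configuration (`mean_activation(n_runs = 200)`). The
bundled experiment scripts use a scaled-down corpus — 200 configurations ×
20 runs — so the whole study runs in minutes on one CPU; the vignette-scale
examples in the tests are smaller still (20 × 5). The compartmental mean
curves share the reference data's qualitative structure (single peak,
half-decay peak interval of a few hundred µs, monotone geometry effects,
side length as the dominant negative correlate of peak amplitude) and its
noise structure (binomial receptor-count fluctuations shrinking with
averaging).

They are, however, *smoother* and more symmetric than particle-simulation
averages: there is no diffusion-limited spatial heterogeneity, no receptor
mobility, and no release-site geometry. Two practical consequences show up
in the results. First, accuracy metrics of the learning pipeline on this
corpus act as optimistic analogs of the published ones — passing them
shows the pipeline machinery reproduces the published accuracy *on curves
of this class*, not that the compartmental model reproduces a particle
simulator. Second,
in the 65-candidate study the flexible high-order families (Gaussian sums,
higher-order rationals) can edge out the 4/4 rational that won on the
reference corpus, because smooth near-Gaussian peaks are exactly what they
excel at; the test suite therefore pins the stable qualitative facts (the
final-stage families sit near the top with $R^2 > 0.99$; compact low-order
families trail far behind) rather than exact ranks.

## Known limitations

- The compartmental reduction is calibrated for ordering, not amplitude;
  do not compare its absolute peak values against particle simulations.
- Vesicle release is deterministic (one full vesicle at $t = 0$); release
  stochasticity and multi-vesicular release are out of scope.
- Transporters are placed on perisynaptic and outer membranes only, with
  densities converted through idealized membrane areas.
- The M5 tree predicts a constant outside the convex hull of its training
  leaves' linear models; extrapolation far outside the parameter ranges is
  untrustworthy (and warned about).
- Model-tree training is deterministic given the data; the `seed` argument
  in the learner contract exists for learners that need it.
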