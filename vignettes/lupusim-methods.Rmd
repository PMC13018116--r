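---
title: "Modelling innate immune amplification in lupus nephritis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling innate immune amplification in lupus nephritis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lupusim)
```

## The modelling problem

Lupus nephritis in the NZB/W F1 mouse is driven by a self-amplifying circuit
of innate immune cells: type-I interferon (IFN-I) activates tissue-resident
helper ILC, which recruit monocyte-derived macrophages; monocytes and
vessel-associated NK cells accumulate in parallel; the resulting tissue
damage produces, in autoantibody-prone animals, immune-complex deposits that
feed back on infiltration and IFN-I release.  `lupusim` implements this
circuit twice: once as a generic, declarative framework for coupled
cell-cytokine networks (`network_spec()`, `assemble_rhs()`), and once as the
specific nine-state disease model (`lupus_rhs()`, `simulate_lupus()`), plus
a hybrid stochastic extension and the in-silico experiment suite built on
top of them.

## The generic framework

Cell states $x_i$ and cytokines $c_j$ evolve as

$$\frac{dx_i}{dt} = R[\beta_i(\cdot), n_i] +
  \sum_n \alpha_{in}(\cdot)\,(x_n - x_i) +
  \left[\gamma_i(\cdot)\left(1 - \frac{x_i}{\omega_i}\right) - \delta_i\right] x_i,$$

$$\frac{dc_j}{dt} = \sum_n q_{nj} x_n - \lambda_{nj}\, h[c_j, K_j]\, x_n - \eta_j c_j,$$

where $h[x, K] = x^3 / (K^3 + x^3)$ is a cubic Hill gate and every gated
rate uses the capped drive $\min\{\sum_k w_k h[\cdot], 1\}$, so a per-capita
rate can never exceed its maximal value.  All Hill exponents are fixed at 3.

Delayed processes are represented by the linear chain trick: $R[k, n]$ is a
cascade of $n$ first-order stages with common rate $k$,

$$\dot y_1 = k (u - y_1), \qquad \dot y_i = k (y_{i-1} - y_i),$$

whose output $y_n$ responds to the input $u$ with an Erlang-distributed
delay of mean $n/k$ and standard deviation $\sqrt{n}/k$.  Two details are
deliberate choices rather than transcription:

* the chain is written in its conservative, input-driven form, which is the
  form that actually produces the Erlang delay with mean $n/k$ (sign or
  boundary variants of the cascade do not);
* the delay standard deviation is $\sqrt{n}/k$, the Erlang moment
  (the coefficient of variation is $1/\sqrt{n}$, which is how the hybrid
  model's on-duration variability is parameterised).

Chain intermediates are appended after the named species in the state
vector, in declaration order; this layout is part of the public contract
(`network_state_names()`).

The generic activation term $\alpha_{in}(x_n - x_i)$ admits negative flux
when $x_n < x_i$; it is implemented as written.  The disease model below
uses only a one-directional activation drain, so the symmetric form is
exercised only through the generic interface.

## The disease model

`lupus_rhs()` implements the specific model: resting and activated tissue
ILC ($x_1$, $x_2$) sharing a logistic niche of capacity $\omega$; tissue
macrophages $x_3$ and monocytes $x_6$, whose proliferation is limited by
growth factors ($c_2$, $c_4$) secreted by epithelial populations ($x_4$
iPEC, $x_7$ cEC) and consumed by the growing cells; vessel NK cells $x_5$
recruited downstream of monocytes; tissue damage $x_8$ accumulating from
$x_3 + x_5 + x_6$; and immune complexes $x_9$ produced from damage through
an Erlang chain $R[\mu_2, n_{ic}]$ — only in the lupus-prone genotype
($\mu_2 = 0$ under WT).  IFN-I is algebraic (quasi-steady state),

$$c = \min\{q_0 + q_1 \mathbf{1}_{19 \le t \le 23} +
  q_2(\zeta_4 h[x_9, K_2] + \zeta_1 h[x_8, K_2]),\, 1\},$$

with the indicator controlled by the schedule's poly(I:C) window.

The five positive feedback loops map onto the weights $\zeta_1$–$\zeta_5$:
damage-induced IFN-I (F1, $\zeta_1$), damage-induced ILC activation (F2,
$\zeta_2$), immune-complex driven macrophage infiltration (F3, $\zeta_3$),
immune-complex induced IFN-I (F4, $\zeta_4$) and immune-complex driven
monocyte infiltration (F5, $\zeta_5$).  This mapping is an inference from
the loop descriptions; it is pinned by the structural identity that
eliminating F3+F4+F5 must reproduce the wild-type condition, which the test
suite asserts as trajectory equality.

Two parameter presets are first-class: the shipped default, in which the
immune-complex infiltration weights are down-scaled to
$\zeta_3 = \zeta_5 = 0.2$ (emphasising the ILC-mediated amplification route,
the configuration used for depletion and cohort analyses), and a
`"uniform"` preset with all five weights equal (used for the feedback-loop
elimination analysis on the unmodified topology).

### Units, time and initial conditions

All rates are per day; the kinetic constants are literature-anchored
($\gamma = 2.4$, $\delta = 0.24$, $\beta = 2.4$, $\alpha = 4.8$,
$\lambda = 14.4$, $q = 1.44$, $\eta = 0.24$ d$^{-1}$) and treated as fixed.
Abundances are dimensionless intrinsic units with $\omega = 1$.  The public
interface reports weeks of age with exactly 7 days per week.  Reported
simulations start at week 12 (the age of the young control animals);
effector populations, chain intermediates and cytokines start at zero and
the resting ILC pool starts from its pre-stimulus homeostatic value,
obtained by a burn-in of the pool's own logistic dynamics at baseline
IFN-I (`initial_state()`).  The burn-in result is independent of the seed
magnitude, which the test suite checks by comparing two seeds.

Because the model is started cold rather than at a full-system fixed point,
the first simulated weeks contain a genotype-shared ignition transient in
which the epithelial populations fill their niches and the
consumption-limited macrophage/monocyte populations settle at a low
homeostatic floor.  The NZB/W and WT trajectories separate slightly already
before stimulation, through the immune-complex terms.

### Depletion semantics

Antibody-mediated depletion is a windowed control: while active, the
targeted process is multiplied by $1 - \kappa$ — the tissue-ILC carrying
capacity for tILC depletion, the NK migration rate for vNK depletion.  At
the default strength $\kappa = 0.8$ the process runs at 20% of its normal
level, consistent with reports of more than 80% suppression of NK activity
under the corresponding treatment.  (Reading the strength as a multiplier
$\kappa$ itself would deplete by only 20% and contradict that anchor, so
the $1-\kappa$ reading is used.)  Because the capacity multiplier sits in a
denominator, full depletion ($\kappa = 1$) is approximated by a residual
capacity of 0.5%.

## Free parameters and calibration

The Hill constants, feedback weights, IFN-I levels and the damage and
immune-complex kinetics are not directly measured; they are fixed by an
ordered set of behavioural constraints (`calibration_constraints()`):

1. two-peak IFN-I response under NZB/W + poly(I:C): first peak inside the
   stimulation window (weeks 19–23), secondary maximum at weeks 25–27;
2. wild-type recovery: WT damage at week 35 below 10% of its peak;
3. a ~7.6-week interval between reaching the pre-ESRD and ESRD damage
   values in the untreated deterministic model;
4. virtual-cohort pre-ESRD fractions of ~92% (treated) and ~26% (tILC
   depletion) at week 25;
5. ~15% pre-ESRD for the hybrid model of untreated animals;
6. $\zeta_3 = \zeta_5 = 0.2$ held fixed.

The damage acquisition rate is anchored to the six-week timescale,
$\mu_1 = 1/42$ d$^{-1}$, and the damage decay rate $\nu_1$ is calibrated.
`calibrate_defaults()` implements the procedure as a seeded local search
(log-uniform perturbations, best violation score wins); the shipped preset
in `lupus_parameters()` is its output, and the package's acceptance tests
re-verify the constraints against that preset at run time.

The calibrated dynamics work as follows.  The homeostatic floor keeps all
damage gates cold.  Poly(I:C) saturates IFN-I for four weeks, activating
the ILC pool and driving the macrophage axis; damage rises to roughly 80%
of its eventual maximum and charges the immune-complex chain.  After the
stimulus is removed IFN-I collapses — the dip between the two peaks — and
damage sags until the delayed immune-complex output arrives, closes the
F3/F4/F5 loops and carries the system to its chronic state; the secondary
IFN-I maximum occurs as the immune-complex gate saturates.  The untreated
lupus-prone system follows the same route without the stimulus: the
immune-complex integrator climbs out of the floor on a timescale of months,
which produces late, slow disease onset, and the final approach through the
pre-ESRD/ESRD band reproduces the ~7.6-week interval.  Wild-type animals
lack the integrator entirely and simply relax back to the floor.

## Outcome definitions

ESRD is defined from a single reference run (default NZB/W + poly(I:C),
60-week horizon): the ESRD damage value is 95% of that run's maximal
damage, the reference time its first crossing; pre-ESRD is 70% of the ESRD
value (`esrd_reference()`).  Threshold crossings are interpolated linearly
on the output grid (0.1-week steps by default).  Pre-ESRD at week 25 — the
model's proteinuria proxy — is a *cumulative* event, like proteinuria
onset in the experiments it mirrors: a run counts as positive if it has
reached the threshold at any time up to the evaluation week
(`pre_esrd_at(..., cumulative = TRUE)`, the default; the instantaneous
reading is available).

## Stochastic components

*Virtual cohorts.*  Parameter uncertainty is modelled as multiplicative
log-normal noise: every positive rate, weight and level parameter (not the
integer chain shape) is multiplied by $e^{\varepsilon}$,
$\varepsilon \sim N(0, 0.1)$, giving ~10% coefficient of variation centred
on the defaults.  (A "log-normal with zero mean" is read as zero mean in
log space; a literal zero-mean log-normal does not exist.)  One flat seed
identifies a cohort; member $i$ draws from substream `seed + i`, so
enlarging a cohort never changes earlier members.

*Acute inflammatory events.*  The hybrid model adds a telegraph
(dichotomous) process: off-periods are exponential with mean
$\tau_{off}$ (the off→on rate is named `k_off`, the rate of *leaving* the
off-state — the naming is kept as is, with this warning); on-periods are
Erlang with mean $\tau_{on}$ and CV $1/\sqrt{n_{on}}$, simulated exactly by
the stochastic simulation algorithm.  While an event is on, immune-complex
production gains a term $\mu_2 \xi$, i.e.
$\dot x_9 = \mu_2(\xi X_{on} + y_n) - \nu_2 x_9$.  Between switches the
ODE system is integrated deterministically; the solver is restarted at
every switch so the discontinuous forcing is never smoothed across.  The
default event configuration (`telegraph_config()`) is a calibration
output, pinned by the ~15% pre-ESRD target for untreated animals together
with their reported 20–44 week onset window.

The event process and the cohort noise are the only stochastic elements;
cell populations themselves remain deterministic between switches.  What
the passing stochastic tests demonstrate is therefore reproduction of
onset *statistics* under these two noise models, not a claim that real
biological noise enters only through these channels.

## Numerical choices

* `lsoda` throughout (automatic non-stiff/stiff switching), relative
  tolerance $10^{-8}$, absolute $10^{-10}$; halving tolerances changes the
  default trajectory by less than $10^{-6}$ (asserted in the tests).
* The right-hand side is compiled C for speed; a pure-R reference
  implementation is kept and the two are asserted equal in the tests.  A
  further independent hand transcription of the model equations lives only
  in the test suite and pins both.
* Window edges (poly(I:C), depletion) and telegraph switches are solver
  restart points, never interior discontinuities.
* ESRD stopping uses root finding on the damage threshold, not grid
  scanning; scan outcomes interpolate crossings on a 0.1-week grid.
* Cohort classification simulates to week 26 only (one week past the
  evaluation time), which keeps a 1000-member cohort inside a minute of
  computation; scan and reference runs use 60–75-week horizons.

## Limitations

* The free parameters are pinned by behavioural constraints, not unique
  measurements; other parameter sets satisfying the same constraints would
  be equally admissible.  The calibration search documents the procedure
  but does not explore the full feasible set.
* Adaptive immunity appears only implicitly (the immune-complex chain);
  there is no spatial kidney structure, and no fitting to single-cell
  abundances or proteinuria survival curves beyond the stated constraints.
* The cohort noise model perturbs all rate-like parameters independently,
  including the IFN-I levels $q_0, q_1, q_2$; correlated variation between
  animals is not represented.
* Depletion is a clean multiplicative control with sharp window edges;
  antibody pharmacokinetics are not modelled.
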