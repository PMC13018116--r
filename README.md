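# lupusim

Simulation of innate immune-cell amplification at the onset of lupus
nephritis in NZB/W F1 mice, for systems immunologists studying how positive
feedback between type-I interferon (IFN-I), innate lymphoid cells and
myeloid cells turns a transient stimulus into chronic autoimmune disease —
and when depleting those cells can prevent it.

The package has two layers:

* a **generic response-time modelling framework** for coupled cell/cytokine
  networks: cubic Hill-gated couplings, capped drives, logistic niches,
  cytokine secretion/endocytosis balances, and Erlang-distributed delays via
  the linear chain trick (`network_spec()`, `assemble_rhs()`,
  `delay_chain()`);
* the **lupus-nephritis model** built in that framework: resting/activated
  tissue ILC, kidney macrophages and monocytes under cytokine-limited
  growth, vessel NK cells, epithelial niches, tissue damage, and — in the
  lupus-prone genotype only — delayed immune-complex deposition that closes
  the amplification loop
  (`lupus_parameters()`, `simulate_lupus()`).

Cell states $x_i$ and cytokines $c_j$ follow

$$\dot x_i = R[\beta_i(\cdot), n_i] + \sum_n \alpha_{in}(\cdot)(x_n - x_i) +
  [\gamma_i(\cdot)(1 - x_i/\omega_i) - \delta_i]\,x_i, \qquad
  \dot c_j = \sum_n q_{nj} x_n - \lambda_{nj} h[c_j, K_j] x_n - \eta_j c_j,$$

with $h[x, K] = x^3/(K^3 + x^3)$ and $R[k, n]$ an Erlang delay chain
(mean $n/k$, sd $\sqrt n / k$).  IFN-I is algebraic:
$c = \min\{q_0 + q_1\,\mathbf 1_{19 \le t \le 23} + q_2(\zeta_4 h[x_9, K_2] +
\zeta_1 h[x_8, K_2]), 1\}$.

On top of the deterministic model sit the study tools: a **hybrid
stochastic extension** where a telegraph process of acute inflammatory
events drives immune-complex production (`simulate_hybrid()`), **virtual
cohorts** with ~10% log-normal parameter variation
(`cohort_pre_esrd_fraction()`), feedback-loop knockouts, ±20% sensitivity
analysis and timed depletion-therapy scans (`depletion_scan()`), and the
calibration procedure that fixed the free parameters
(`calibrate_defaults()`).

## Worked example

```r
library(lupusim)

params <- lupus_parameters()          # calibrated NZB/W defaults
ref    <- esrd_reference(params)      # ESRD = 95% of max damage, treated run
ref
#> esrd_reference: ESRD damage 0.4011 (95% of max 0.4223), reached week 30.55; pre-ESRD 0.2808

# Treated lupus-prone animals: two IFN-I peaks, the second one driven by
# delayed immune-complex deposition after the stimulus is withdrawn
tr <- simulate_lupus(params, intervention_schedule(),
                     horizon = ref$horizon, stop_at_esrd = ref$esrd_value)
ifn_peaks(tr)
#>   week value
#> 1 22.1     1
#> 2 25.2     1

# Wild type: single transient, recovery to the homeostatic floor
wt <- simulate_lupus(params, intervention_schedule(genotype = "WT"), horizon = 40)
max(wt$x8)                                        # peak damage
#> [1] 0.3432183
wt$x8[wt$time_weeks == 35] / max(wt$x8)           # back near baseline
#> [1] 0.08086756

# Untreated lupus-prone animals: late, slow spontaneous onset
un <- simulate_lupus(params, intervention_schedule(polyic_window = NULL),
                     horizon = 70)
time_to_esrd(un, ref)$week
#> [1] 52.36539
```

The printed numbers mean: the treated reference run reaches end-stage renal
disease (95% of its damage maximum, 0.401 in intrinsic units) at week 30.6
of age, with IFN-I saturating during the stimulation window (first peak at
week 22.1) and again — now driven by delayed immune-complex deposition —
from week 25.2; the wild-type run peaks and decays back to ~8% of its peak
by week 35; the untreated lupus-prone run reaches ESRD spontaneously at
week 52.4, crossing its pre-ESRD level ~7.2 weeks earlier, which reproduces
the reported ~7.6-week interval between proteinuria onset and end-stage
disease.

A shell entry point wrapping the same functions is installed at
`inst/cli/lupusim` (subcommands `simulate`, `hybrid`, `knockout`, `deplete`,
`cohort`, `sensitivity`, `calibrate`; every run writes a JSON manifest
sufficient to reproduce it).

## Documentation

The methods vignette (`vignettes/lupusim-methods.Rmd`) describes the model
equations and their assumptions, the calibration of the free parameters,
the outcome definitions (ESRD reference, cumulative pre-ESRD
classification), the stochastic components and the numerical choices.
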