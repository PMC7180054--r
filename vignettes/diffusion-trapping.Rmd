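---
title: "Modeling AMPA-receptor diffusion trapping at synapses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling AMPA-receptor diffusion trapping at synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`ampartrap` simulates the lateral diffusion of AMPA-type glutamate receptors
(AMPARs) on a dendritic membrane segment and their reversible trapping by
immobile scaffold at postsynaptic densities (PSDs). The membrane is a closed
2D rectangle; synapses are axis-aligned squares; receptors are point
particles with two states, FREE and BOUND. The model deliberately contains
nothing else: no vesicular recycling or exo/endocytosis, no saturable
binding slots (scaffold is assumed in excess), no 3D spine geometry, no
fluorophore photophysics. Synaptic strength is read out as the number of
receptors inside each synapse square.

Each time step of length $\Delta t$ applies, in this order:

1. **Kinetics.** Using the position at the start of the step: a BOUND
   receptor unbinds with probability $\min(k_{off}\Delta t, 1)$; a FREE
   receptor inside a synapse binds (to that synapse's scaffold) with
   probability $\min(k_{on}\Delta t, 1)$; a FREE receptor outside any
   synapse stays FREE with certainty. Probabilities are the linear
   $k\,\Delta t$ rule, clamped at 1 — they are not exponentiated, so the
   per-step numbers match the rates only while $k\Delta t \ll 1$ (true for
   every default).
2. **Displacement.** Both coordinates are incremented by
   $\sqrt{2D\Delta t}\,n$ with $n$ standard normal and $D$ chosen by state:
   $D_{trap}$ if BOUND, else $D_{in}$ inside a synapse, else $D_{out}$.
3. **Region reflection.** Proposed positions beyond the rectangle are
   mirrored about the violated edge (repeatedly if necessary): the system is
   closed and the receptor count is conserved exactly.
4. **Border crossing (FREE receptors).** If the proposed move changes
   synapse membership, it is accepted with probability $P_{crossing}$ and
   otherwise rejected (the receptor keeps its previous position for this
   step). Which crossings are gated is configurable; see below.
5. **Confinement (BOUND receptors).** A bound receptor whose proposed move
   leaves its synapse square keeps its previous position (`bound_edge =
   "hold"`, the default) or is mirrored back into the square
   (`"reflect"`).

Within a step, receptors are updated independently in index order, and all
stochastic decisions draw from one seeded generator in a fixed documented
order (kinetics uniform, two displacement normals, crossing uniform), so a
`(config, schedule, seed)` triple fixes the trajectory bit for bit.
Replicate $r$ of a set uses seed $\texttt{base\_seed} + r - 1$.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `region_length` × `region_width` | 10 × 2 | µm | dendritic segment |
| synapses | 5 squares, side 0.3, centres x = 1, 3, 5, 7, 9, y = 1 | µm | 0.5 synapse/µm; positions are the package's choice (even spacing), only the density being constrained |
| `n_receptors` | 1000 | – | closed population; ceiling of 200/synapse |
| `dt` | 0.1 | s | integration step |
| `D_out`, `D_in`, `D_trap` | 0.1, 0.05, 0.006 | µm²/s | free outside, free inside (steric hindrance), scaffold-bound (PSD confinement); single-molecule-tracking scale values |
| `p_crossing` | 0.5 | – | synaptic border barrier |
| `k_on`, `k_off` | 1, 0.04 | s⁻¹ | scaffold binding/unbinding (SPT/FRAP-fitted scale) |
| `t_burn_in` | 300 | s | unrecorded equilibration |
| `t_baseline`, `t_post` | 300, 1800 | s | recorded 5 min baseline + 30 min post-induction (35 min total) |
| `sample_interval` | 10 | s | count sampling cadence, matching a 10-s acquisition cycle |

Receptors start FREE, uniform over the whole rectangle. Steady state of the
binding chain needs $t \gtrsim 1/k_{off} = 25$ s, but the global partition
of receptors between synaptic and extra-synaptic pools also requires
diffusion across the segment ($L^2/2D_{out} \approx 500$ s scale), so the
burn-in is set to 300 s; together with the recorded baseline the system has
had 600 s before any induction.

Protocols are piecewise-constant rate schedules. Induction happens at the
end of the recorded baseline. Defaults: `ltp` drops $k_{off}$ 0.04 → 0.004
s⁻¹; `ko_ltp` (knockout) drops it only to 0.008 s⁻¹; `phospho_basal` and
`phospho_ltp` run with $k_{on} = 3$ s⁻¹ throughout (the hypothesized kinetic
consequence of neuroligin-1 tyrosine phosphorylation: more trapping slots
behave like a higher apparent on-rate); `kon_step_ltp` is the rejected
alternative potentiation mechanism in which $k_{on}$ steps up at induction
with $k_{off}$ constant. Its default potentiated value, 10 s⁻¹, is chosen so
the post-induction ratio $k_{on}/k_{off} = 250$ matches the `ltp` protocol,
giving the two mechanisms the same plateau and isolating their kinetic
difference: the $k_{on}$ step reaches half-plateau in ~20 s versus ~50 s for
the $k_{off}$ drop at matched plateau (ranges quoted for the default seeds
in the test suite).

## The crossing barrier: which direction is gated?

The steady-state enrichment of synaptic over extra-synaptic receptor
density has the closed form

$$E = P_{crossing}\,\frac{D_{out}}{D_{in}}\left(1 + \frac{k_{on}}{k_{off}}\right),$$

in which $P_{crossing}$ multiplies the free-density ratio. A barrier applied
symmetrically to entries and exits cancels out of the stationary density
ratio (both fluxes are attenuated equally), so the formula is only
consistent with the barrier gating one direction. `ampartrap` therefore
gates **entry** by default: a membership-changing move into a synapse is
accepted with probability $P_{crossing}$, an exit is always accepted.
`crossing_mode` exposes `"exit"` and `"symmetric"` as alternatives, because
the choice measurably changes basal enrichment (symmetric roughly doubles
the basal count and halves the relative LTP plateau at these defaults).

## What the simulation yields, and the closed-form gap

Two analytic anchors bracket the simulated basal content:

* The printed closed form gives $E = 0.5 \times 2 \times 26 = 26$ at
  defaults; conservation
  ($N = \rho_{out}A_{out} + E\rho_{out}A_{syn}$) then implies **≈75
  receptors/synapse** (`predicted_basal_count()`).
* Comparable published simulations report **about 30** receptors/synapse.

The faithful discrete scheme lands between the two, at **≈59**. The reason
is quantifiable: for a sharp interface, per-step flux balance of the
discrete walk gives a free-density ratio
$\rho_{in}/\rho_{out} = P_{crossing}\sqrt{D_{out}/D_{in}} \approx 0.707$
(the square root, not the ratio, of the diffusivities — a well-known
property of naive position-jump schemes at diffusivity discontinuities),
and $59 \approx$ the conservation solution with that ratio. The package
reports the simulated value and the closed-form prediction side by side
(`reproduce-paper`, `sweep_kon()`'s `predicted_basal` column) rather than
tuning either. When the barrier and the diffusivity contrast are switched
off (`p_crossing = 1`, `D_in = D_out`) the scheme has no interface artifact
and the simulated basal count matches the closed form within Monte-Carlo
error — the test suite asserts this consistency.

The same algebra shows that the four published headline numbers (basal ≈30,
control LTP plateau ≈270% of baseline, ≈2-fold basal increase at
$k_{on} = 3$ s⁻¹, phosphorylated LTP plateau ≈190%) cannot all be produced
by one free-density ratio: the entry-gated scheme reproduces the 270%
plateau (simulated ≈268–272%) and the ≈2-fold basal increase (≈1.86), but
yields ≈167% rather than ≈190% for the phosphorylated LTP plateau and ≈59
rather than ≈30 at rest. These residual gaps are reported as measured.

## Analysis conventions

* **Per-synapse count** of a run is the mean over its five synapses;
  cross-replicate mean and SEM (denominator $n$ replicates) summarize a
  `replicate_set`. With 10 replicates the baseline SEM is well under 1% of
  the mean.
* **Normalization**: potentiation curves are the replicate-mean series
  divided by its baseline-window mean, ×100 (`percent_of_baseline()`, with a
  per-replicate option).
* **Plateau window**: final 5 min of the 30-min post-induction span, by
  which point the slowest relaxation ($1/k_{off} = 250$ s post-induction)
  has long equilibrated; `plateau_window = "experimental"` selects the
  6–10 min window used to quantify recorded traces.
* **Sweep**: 20 log-spaced $k_{on}$ values over 0.075–10 s⁻¹ by default;
  basal content is monotonically increasing and the relative plateau
  monotonically decreasing in $k_{on}$ — synapses already full of receptors
  have depleted the extra-synaptic reservoir LTP draws from.
* **EPSC mapping**: currents are taken proportional to receptor counts,
  anchored at 33 receptors/synapse for the 100% control level
  (`epsc_to_count()`); the anchor table carries no other invented numbers
  and is meant for plot overlays only.

## Numerical notes and degenerate inputs

Reflection uses the closed-form period-$2L$ triangle-wave fold, so even
pathological proposals cost O(1). Synapse squares are closed sets; a point
exactly on a border counts as inside (ties between two squares — a
zero-probability event — resolve to the lower id). $k\Delta t > 1$ clamps to
probability 1. `k_off = 0` with `k_on > 0` makes trapping irreversible:
`enrichment_ratio()` returns `Inf` with a warning and the conservation
accounting returns the 200-receptor ceiling. Zero diffusion coefficients,
`p_crossing` of 0 (absorbing compartments) or 1 (no barrier) are all valid
and covered by tests.

```{r}
library(ampartrap)
cfg <- sim_config()
ltp <- run_replicates(cfg, protocol("ltp"), n_replicates = 10, base_seed = 1)
plateau(ltp)
plot(ltp, normalized = TRUE)
```

## What passing tests do and do not show

The simulator is validated against independent oracles at reduced scale:
the two-state binding chain's stationary bound fraction
($k_{on}\Delta t/(k_{on}\Delta t + k_{off}\Delta t) \approx 0.9615$ at
defaults) and geometric dwell times; spatial uniformity under the null
dynamics (no binding, no barrier, uniform diffusivity); exact receptor
conservation and containment; seed determinism; agreement of the compiled
engine with the vectorized R reference stepper; and the closed-form
consistency check described above. Full-scale checks use the reference
configuration (1000 receptors, 24,000 steps per run, 10 replicates for the
headline conditions, a 6-value × 3-replicate sweep) — sizes chosen so the
whole suite runs in a few minutes while keeping replicate SEM under 1%.

Passing these tests shows the scheme implements its own stated dynamics and
reproduces the diffusion-trap steady-state theory; it does **not** show
that real synapses behave this way. In particular the model ignores
receptor turnover through recycling, scaffold saturation and remodeling,
spine geometry and neck diffusion barriers, interactions between receptors,
and heterogeneity between synapses — all of which shape real basal content
and potentiation amplitudes.
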