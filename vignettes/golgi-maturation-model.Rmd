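---
title: "A self-organizing model of vesicular transport in the maturing Golgi stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A self-organizing model of vesicular transport in the maturing Golgi stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(golgisim)
```

## The modelling problem

Golgi cisternae mature: a cisterna is born at the cis face from ER-derived
vesicles, advances one position per maturation period, and disintegrates at
the trans face. Resident glycosylation enzymes nevertheless maintain
position-specific steady distributions, and the two cognate Golgi SNARE
pairs maintain opposing gradients — the alpha pair (rBet1 with the
Membrin/ERS24/Syntaxin-5 complex) steeply decreasing cis→trans, the beta
t-complex (Gos28/Ykt6/Syntaxin-5) shallowly decreasing, and the beta
monomer GS15 *increasing* cis→trans. `golgisim` implements a kinetic model
in which these patterns self-organize from three ingredients, with no
built-in positional information:

1. **Cisternal maturation** as a conveyor: a discrete shift event once per
   period.
2. **SNARE-weighted vesicle fusion**: a single COPI-like vesicle class
   whose fusion probability with a target compartment is proportional to
   the product of its vesicular v-SNARE and the target's cisternal t-SNARE
   concentrations.
3. **Loss**: first-order decay of active SNAREs and escape of vesicles to
   the ER. Older cisternae have lost more, so vesicles preferentially fuse
   with younger cisternae; the resulting retrograde flux transports
   t-SNAREs cis-ward and deepens the very gradient that directs it.

Enzymes ride the same vesicles as passive cargo, competing for a fixed
pool of vesicular binding sites by mass action. Strong binders
(low dissociation constant `K`) monopolize vesicle space while they are
abundant; weak binders only load once the strong ones are depleted — which
happens in older cisternae. Combined with ER escape at the cis end this
reproduces ordered, overlapping cis/medial/trans enzyme peaks.

## State, units, and kinetic equations

The state is a species-by-cisterna concentration matrix `C` plus the phase
within the period. All concentrations are expressed in units of the
newborn-cisterna concentration (`C_init = 1` in every preset) and time in
units of the maturation period (`period = 1`); a loss rate `kappa = 0.2`
therefore means a ~18% loss per maturation step.

Between shifts, for species $x$ and cisterna $i$:

$$\frac{dC_x(i)}{dt} \;=\; -\kappa_x C_x(i)
  \;-\; \omega\, v_x(i) \sum_{j \ne i} w_i(j)
  \;+\; \omega \sum_{j \ne i} v_x(j)\, w_j(i),$$

with vesicular concentrations from the competitive mass-action equilibrium

$$v_x(i) = n \,\frac{C_x(i)/K_x}{1 + \sum_m C_m(i)/K_m},$$

and fusion weights $w_i(j)$ proportional to
$v_{t\alpha}(i) T_\alpha(j) + v_{t\beta}(i) T_\beta(j)$ over the
allowed-target set (the ER contributes $v_{er}(i)\,T_{ER}$), normalized to
sum to one per donor. Fusion with the donor itself is allowed and carries
zero net flux. At each shift, contents move one index trans-ward, the
trans-most contents are flushed, and a newborn cisterna is loaded.

Vesicle populations are not tracked explicitly: at the steady state of the
fast budding/fusion balance, the flux leaving a donor equals its budded
cargo distributed over targets in proportion to the normalized weights,
which is what the equations above implement directly. This removes a stiff
fast variable without changing the steady state.

### Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `n_cisternae` | stack size `N` | 8 | mammalian Golgi has 6–8 cisternae; 30 in `long_stack` |
| `omega` | lumped transport coefficient | preset-specific | absorbs budding rate, fusion constant, compartment area and the vesicle/cisterna dilution factor, which enter every flux only as a product and are not separately identifiable |
| `n_sites` | vesicular binding-site concentration | 1 | only the product `omega * n_sites` affects the dynamics (weights are normalized), so presets fix it at 1 |
| `K` | per-species dissociation constant | published table for the full model | lower `K` = stronger competitor |
| `kappa` | per-species loss rate | 0 except seed species | collects degradation, mis-targeting, inactivation; removed matter is not routed anywhere |
| `T_ER` | fixed ER t-SNARE | 0.7 | the ER is a boundary reservoir, never a donor |

### Boundary handling

Open boundaries treat the ER as a "zeroth cisterna" with fixed t-SNARE:
`er_access` selects whether only donor 1 reaches it (stacked enzyme
scenarios) or every donor does (the full model, where the expansive ER
neighbours the whole stack). A closed boundary confines vesicles to the
stack.

At the stack ends a local donor keeps its full three-slot normalization
(cis face / self / trans face): a face with no neighbouring cisterna falls
back to the donor itself, or to the ER at an open cis end. This choice
makes the flat profile an exact fixed point of the zero-loss dynamics — a
two-slot edge normalization provably drains cisterna 1 at first order in
`omega` and would manufacture an edge gradient without any loss mechanism,
contradicting the analytic result that loss is necessary for any gradient.
The trans-most cisterna receives no retrograde input in either convention.

### The `er_cargo_only` option

The enzyme-sorting analysis can also be run in a decoupled form in which
the SNARE subsystem evolves with stack-internal weights while only passive
cargo is delivered to the ER (`er_cargo_only = TRUE`) — the regime in which
the vesicle flux is prescribed by an autonomously evolving SNARE gradient.
The shipped presets use the fully coupled model; the option is provided for
studying the two formulations side by side.

## The analytic steady-state gradient

For a long stack in the linear loading regime (`C ≪ K`, so a vesicle loads
proportionally to the donor concentration), substituting the ansatz
$T_i(t) = a^i f(t)$ into the kinetic equation shows $f$ decays
exponentially between shifts, and periodicity (`cisterna i` pre-shift must
equal `cisterna i+1` post-shift) closes the relation

$$a \;=\; \exp\!\Big(-d \;-\; g\,\frac{(1-a)^2}{1+a+a^2}\Big),
  \qquad d = \kappa T,\; g = \omega n T / K.$$

`solve_exponent()` finds the root by bisection on $(10^{-12}, 1]$ with
tolerance $10^{-10}$; the bracket provably changes sign whenever $d > 0$,
and bisection was chosen over faster iterations for unconditional
robustness. Limits: $g = 0$ gives the pure conveyor decay $a = e^{-d}$;
$d = 0$ gives $a = 1$ for every $g$ (at first order
$a = 1 - d$, independent of $g$: `small_loss_expansion()`), so vesicular
transport *enhances* a loss-seeded gradient but cannot create one. The
`long_stack` preset (N = 30, `K = 20` so loading stays linear to within a
few percent) reproduces the analytic root to better than 0.1% when fitted
over interior cisternae 5–25; boundary layers at both ends are excluded
and are not treated analytically.

### Stability limits of the exponential state

The exponential steady state is dynamically stable only up to a finite
transport group. Empirically (N = 30, local topology), runs converge
cleanly for $g \lesssim 1.5$ at $d = 0.2$ and $g \lesssim 2$ at $d = 0.4$;
beyond that the profile breaks into slowly travelling concentration
islands — a cisterna that is locally SNARE-rich attracts still more
vesicles. The presets and the cross-validation settings live inside the
stable regime; the instability itself is physical (step-size refinement
does not remove it), and the same self-amplification appears in the
unrestricted topology (below).

## Scenario presets and their calibration

The published constants fix the dissociation constants of the full model
(ER v-SNARE 0.2; alpha t/v 0.4; beta t 1; beta v 5; enzymes 1.4, 2.5, 5),
the ER t-SNARE level 0.7, and the convention `C_init = 1`, `period = 1`.
The transport coefficient and the seed decay rates are not recoverable
from the source material; the preset values below were chosen once so that
each scenario expresses its documented qualitative behaviour, and are
reported as package defaults:

* `single_snare` (`omega = 2`, `kappa_t = 0.2`): both loss and transport
  act; the gradient is visibly steeper than the decay-only conveyor
  (`single_snare_loss_only`), while `single_snare_transport_only`
  (`kappa = 0`) stays exactly flat.
* `enzymes_open` / `enzymes_closed` (`kappa_t = 0.4`; `omega = 10` open,
  `omega = 4` closed): the open run needs a strong ER drain and a steep
  cis-end gradient for the strongest binder to peak in cisterna 1 and the
  weakest in the penultimate cisterna; the closed run is capped at the
  highest transport coefficient at which the closed SNARE subsystem is
  dynamically stable (the ER escape is itself stabilizing, so the open
  preset tolerates more flux). All species share one site pool, the
  published default assumption.
* `full_mammalian` (`omega = 10`, beta-t decay 0.1, ER access from all
  cisternae): reproduces the steep alpha and shallow beta t-SNARE
  gradients, the counter-current beta v-SNARE rise, and ER-recycled
  fractions ordered by vesicle affinity.
* `unrestricted_yeast`: the full configuration with fusion allowed to any
  cisterna.
* `long_stack` (`N = 30`, `K = 20`, `omega = 20`, `kappa = 0.2`): the
  asymptotic-regime probe, decay group 0.2 and transport group 1.

Two monotonicity conventions are worth stating. The trans-most cisterna is
the disintegrating face and receives no retrograde vesicular input, so its
pre-shift concentration dips below the interior trend; claims such as "the
beta v-SNARE increases cis→trans" are therefore evaluated over cisternae
`1 … N-1`. And because the newborn cisterna has aged one full period by the
pre-shift sampling instant, the decay-only profile is
`exp(-kappa * i)` — proportional to `exp(-kappa * (i-1))` with a one-period
offset.

## Numerical scheme

Explicit Euler with `dt = 1e-3` periods (the integrator refuses
`dt ≥ period/100`), steady state declared when consecutive pre-shift
snapshots differ by at most `tol = 1e-8` in sup norm, capped at
`max_periods`. Euler's first-order bias is about `kappa^2 * dt / 2` per
period (relative error ~2e-5 per period at `kappa = 0.2`), well inside
every tolerance used in the tests; step-halving (Richardson) checks are
part of the suite. Negative overshoot is clamped to zero and counted;
clamping during the final period voids the convergence flag, surfacing a
too-large step rather than silently biasing the state. The period
integrator is implemented in C++ for speed, with a line-for-line R
reference implementation (`engine = "r"`) against which it is tested to
machine precision. Everything is deterministic: there is no random number
generation anywhere in the model, and repeated runs are bit-identical.

### Oscillatory attractors

With unrestricted fusion at full-model flux the system does not settle
into a fixed periodic state: alpha/ER SNAREs are episodically drained to
the ER, the fusion bias collapses, newborn cisternae re-seed it, and the
cycle repeats. This is a genuine relaxation oscillation (its amplitude
survives step-size refinement). For such runs `run_to_steady_state()`
reports `converged = FALSE` and offers `average_periods`: the mean of the
last `k` pre-shift snapshots, which is stable across averaging windows and
is the observable used for the topology contrast — time-averaged enzyme
peaks under unrestricted fusion sit at cisternae 1–2 versus 2, 5 and 7
under local fusion, i.e. segregation is poor and every peak shifts towards
the young end.

## What the scenarios do and do not emulate

The presets are idealized study conditions, not fits to data: all newborn
concentrations equal, one vesicle class, fixed site pool, well-mixed
compartments with constant area and volume, and no anterograde secretory
cargo. Passing tests therefore demonstrate the internal consistency and
qualitative behaviour of the mechanism — gradient self-enhancement,
competition-based sorting, boundary-condition dependence — not quantitative
agreement with measured Golgi compositions. Known limitations: enzyme
segregation is sensitive to the transport coefficient and seed decay (a
property of the competition mechanism itself); the strongest binder's peak
position and the penultimate peak of the weakest binder coexist only in a
fairly narrow parameter band; and the unrestricted topology has no fixed
steady state at realistic flux, so only averaged observables are
meaningful there.
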