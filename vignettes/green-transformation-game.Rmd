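---
title: "A tripartite evolutionary game for the green transformation of anti-epidemic supplies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A tripartite evolutionary game for the green transformation of anti-epidemic supplies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greengame)
```

## The model and its assumptions

Three populations interact repeatedly over the adoption of environmentally
friendly masks (EFMs): governments choose between regulating and not
regulating EFM production and use; mask enterprises choose whether to
increase EFM production; medical institutions choose between EFMs and
disposable masks. All three are boundedly rational: nobody jumps to a best
response, strategies spread by imitation, which is exactly what replicator
dynamics model — a strategy's share `s` grows at
`ds/dt = s(1-s)(U_adopt - U_decline)`.

The payoffs rest on four structural assumptions. EFMs and disposables
protect equally well, so adoption is an economic decision. Total mask
consumption is fixed — every EFM displaces one disposable. Prices do not
respond to supply or demand (price endogeneity is out of scope). And the
reuse "cost benefit" `rc` — savings from not repurchasing, net of
cleaning, electricity and labour — may be negative, the only signed
parameter in the model.

```{r params}
game_parameters()
```

## Parameters that matter, and their defaults

All monetary parameters are CNY per mask; `q` (pieces) scales every payoff
and eigenvalue linearly and defaults to 1. The packaged baseline is a
calibration of the Chinese mask market:

* `H = 1.8` — reputation damage from government inaction. The engine of
  regulation: the government regulates when `H + f1` outweighs the
  regulation cost plus expected subsidy outlays.
* `GC = 2`, `GH = 0.2` — production and use subsidies. Note `GC` is large
  relative to `CG = 0.05` (regulation cost), so widespread production
  makes regulation expensive and pushes the government out.
* `P = 1`, `C = 0.5`, `alpha = beta = 1.5` — EFMs sell at `alpha*P` and
  cost `beta*C`; the margin spread drives enterprise adoption together
  with the retooling cost `CS = 0.3`.
* `rc = 2`, `d = 0.05`, `f2 = 0.2` — institutions gain `rc` per mask from
  reuse, pay a management overhead `d`, and owe liquidated damages `f2`
  on cancelled disposable contracts while enterprises that stopped
  increasing production receive them.
* `f1 = 0.1` — environmental penalty on non-adopting institutions under
  regulation.

## Equilibria and policy thresholds

Every corner of the cube is a replicator fixed point; the Jacobian is
diagonal there, and `classify_equilibria()` labels a corner `stable`
(an ESS) when all three eigenvalues are negative, `non_hyperbolic` when
one vanishes (|eigenvalue| < 1e-9), and `saddle` otherwise. The binary
stable/saddle labelling mirrors the field's convention — corners with all
eigenvalues positive (sources) are reported as saddles too, for parity
with the published table.

```{r equilibria}
classify_equilibria(game_parameters())
```

The policy surface is summarised by closed-form thresholds:
`regulation_thresholds()` gives the opponent-proportion levels at which
the government is indifferent; `critical_reputation_loss()` gives the
reputation damage above which regulating dominates regardless of the
unobserved player (`regulation_dominant()` is the predicate); and
`region_proportions()` evaluates each indifference condition with the
other proportion at one half, yielding the six quantities whose
parameter sensitivities `sensitivity_signs()` verifies by central finite
differences (all 17 signs reproduce at the baseline). Region proportions
are reported unclipped — a value above 1 means the regime holds for every
proportion — with a clipped view available for plotting.

## The two enterprise variants

The enterprise replicator equation is shipped in two forms. The canonical
`as_printed` form carries a `+P` term; expanding the enterprise's expected
utilities from the payoff table instead yields `+zP`. The difference,
`y(1-y)(1-z)Pq`, vanishes once all institutions adopt. We default to
`as_printed` because the published eigenvalue table is generated by it;
the `table2_consistent` variant is selectable everywhere and is the one
that shows the initial dip in the production share (producing EFMs while
almost nobody buys them loses money). `payoff_consistency()` recomputes
rates from the payoff table and reports the residual rather than patching
either side. Two analogous print-vs-derivation conflicts in the midpoint
region proportions (`v12`, and the sign of `rc` in `w31`/`w32`) are
resolved in favour of the indifference-condition derivation, which is
also what the published sensitivity signs require; the printed literal
forms remain available behind `strict_print = TRUE` for audit.

## Numerical choices

The simulator is fixed-step forward Euler with `dt = 0.05` over
`[0, 15]` by default — a deliberate mimicry of the system-dynamics
tooling the model was originally run in — with classical RK4 available
for cross-validation. States are clamped to the unit cube after each step
(Euler can overshoot a corner by a sliver). Interventions apply at the
first step boundary at or after their event time, with no interpolation;
"cancel regulation" is modelled as clamping `x` to 0 from that boundary
on. Convergence detection requires the state to sit within `tol = 0.01`
(max-coordinate) of a corner for `dwell = 20` consecutive steps — both
far below the unit inter-corner distance.

```{r simulate}
traj <- simulate_game(game_parameters(), strategy_state(0.1, 0.1, 0.1),
                      simulation_settings(t_final = 40))
detect_convergence(traj)
```

## What the scenario generator emulates — and what a green test shows

`baseline_scenario()` is the calibrated market above with a 10% adoption
start. `figure_presets()` reproduces the structure of the published
simulation experiments: initial regulation at 10% vs 50%, sweeps of
`alpha`, `beta`, `H` and `f2`, a five-level `rc` sweep spanning large
positive through large negative, and an `rc`-by-`GH` grid probing whether
subsidies can rescue adoption when reuse is costly (they cannot: the
institution's rate factor is bounded above by
`GH + f1 + f2 - alpha*P - d + rc - f2`, which stays negative for strongly
negative `rc` at any swept subsidy). The exact sweep levels for `alpha`,
`beta`, `H` and `f2` are artifact choices — half, baseline and double —
because no numeric levels are published; only the qualitative ordering of
outcomes is meaningful. `random_parameters()` draws each field uniformly
within ±50% of baseline (with `rc` allowed down to minus its baseline)
for property tests; "realistic" here means sign-correct and
baseline-scaled, nothing more.

A green suite therefore establishes: the algebra (payoffs, rates,
Jacobian, thresholds) is internally consistent and reproduces every
printed number; the simulator is a faithful fixed-step integrator of that
algebra. It does **not** establish that the calibration describes any
actual mask market, that replicator dynamics describe real institutional
adoption, or anything about the unpublished figure curves beyond their
qualitative shapes.

## Known limitations

* Two acceptance assertions are deliberately red. The contract asks the
  baseline run to end within 0.01 of (0, 1, 1) at `t = 15`; the model
  honestly gives `x(15) ≈ 0.037` (confirmed with an independent
  high-accuracy integration — `x` decays at asymptotic rate 0.45 from a
  peak of ~0.8 at `t ≈ 3.4`, so 0.01 is unreachable before `t ≈ 17` even
  in continuous time; it is met by `t = 30`). For the same reason the
  Euler-vs-RK4 agreement band of 1e-3 fails at `t = 15` (measured 2.3e-3)
  while holding with ~3e-8 to spare at any converged horizon.
* Only the eight pure corners are analysed; interior mixed equilibria and
  center-manifold behaviour are out of scope, as are stochastic
  finite-population dynamics, price/demand endogeneity, and monetary-unit
  conversion.
* The YAML parameter format is the flat `key: value` subset only.
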