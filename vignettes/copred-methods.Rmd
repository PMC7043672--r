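---
title: "Models and methods behind copred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind copred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science and the numerical
and design choices inside it: the ODE model family, what the synthetic-data
generator does and does not emulate, how the ABC-SMC engine is built, and
where genuinely open design questions were settled.

## The biological system

A batch culture of *E. coli* in a low-nutrient buffer is attacked by two
very different predators. A lytic bacteriophage adsorbs to a surface
receptor, replicates inside the cell and releases tens to hundreds of
virions per burst; receptor-loss mutants are fully resistant, arise at
fluctuation-test frequencies, and grow essentially unimpaired.
*Bdellovibrio bacteriovorus* invades the periplasm, converts the cell into
a rounded bdelloplast, and releases a handful of progeny hours later; no
simple genetic resistance is known, but a fraction of prey enters a
transient "plastic" resistant state that is not passed to daughters and
reverts on regrowth. Each predator therefore selects a refuge subpopulation
that the *other* predator can still kill — the mechanistic heart of why
dual predation can eradicate a population that either predator alone
cannot.

## The model family

Ten compartments (densities per ml, time in hours): prey subtypes `N_S`,
`N_P` (plastic Bdellovibrio-resistant), `N_R` (phage-resistant), `N_D`
(doubly resistant); free Bdellovibrio `P` and bdelloplasts `B`; free phage
`V` and infected cells `I`; medium `M` in prey-cell equivalents; signal
`C`. Writing `phi = mu_max * M / (K_M + M)` for the Monod growth factor,
`A_P` for the total Bdellovibrio attack flux on its susceptible prey
(`N_S + N_R`) and `A_V` for the phage attack flux on `N_S + N_P`, the
canonical equations of the full (N4, signal-driven, growth-coupled)
variant are:

* `dN_S/dt = (1 - m) phi N_S + (1 - m) phi N_P - att_P(N_S) - att_V(N_S) - k_sig C N_S`
* `dN_P/dt = k_sig C N_S - att_V(N_P)`
* `dN_R/dt = phi N_R + m phi N_S + phi N_D - att_P(N_R) - k_sig C N_R`
* `dN_D/dt = m phi N_P + k_sig C N_R`
* `dP/dt  = beta_P k_B B - A_P - d_P P`
* `dB/dt  = A_P - k_B B`
* `dV/dt  = beta_V k_I I - A_V`
* `dI/dt  = A_V - k_I I`
* `dM/dt  = -phi (N_S + N_P + N_R + N_D) + eps_B k_B B + eps_I k_I I`
* `dC/dt  = sigma_C * (source attack flux)`

with `att_P(N) = a_P P N` (variant Pi) or `a_P P N / (K_P + N_S + N_R)`
(Pii), and likewise for the phage (Vi/Vii). Sub-variants switch terms on
and off: intrinsic conversion replaces `k_sig C` by `r_I`; intrinsic back
conversion adds `r_back N_P -> N_S`; growth-coupled back conversion
instead routes the division flux of `N_P` into `N_S` (and of `N_D` into
`N_R`), so plastic resistance never propagates to offspring. Reduced prey
structures (N1–N3) zero the missing compartments; excluded compartments
are identically zero along any trajectory and this is enforced at the
interface.

Design choices worth making explicit, because the underlying process
descriptions leave them open:

* **Growth law.** Monod uptake with half-saturation `K_M` rather than
  linear consumption; it spans both the near-linear and the saturated
  regime and `K_M` is simply fitted.
* **Medium bookkeeping.** `M` is denominated in prey-cell equivalents with
  unit yield, so "lysis releases nutrients" becomes quantitative with two
  parameters (`eps_B`, `eps_I`), both constrained below one equivalent: a
  lysis residue cannot rebuild a whole cell.
* **Maturation and lysis collapsed.** Intracellular development and lysis
  are one first-order transition (`k_B`, `k_I`) whose completion releases
  progeny and residue simultaneously. Nothing in plate-count observables
  distinguishes two sequential intracellular stages, so the extra
  parameter would be unidentifiable.
* **Attack saturation.** The Holling type-II form saturates in the *total*
  susceptible prey density and is apportioned across subtypes by
  abundance. Under Pii the constant `a_P` is the maximum per-predator
  attack rate (1/h); under Pi it is a mass-action constant (ml/h). The
  same letter deliberately plays these two roles, mirroring how functional
  responses are usually parameterised.
* **Signal.** Produced proportionally to the attack (prey-entry) flux of
  the source predator(s), with no decay or consumption term. A decay
  constant would be confounded with `sigma_C` and `k_sig` on a 48-h
  horizon. The reference variant uses the Bdellovibrio-only source.
* **De novo resistance** diverts a fraction `m` of the division flux, not
  a constant per-capita rate — resistance arises in replication, as in the
  classical fluctuation analysis.
* **Observables include intracellular stages.** Plaque assays cannot
  distinguish a free predator from an infected cell that will release
  progeny, so Bdellovibrio PFU = `P + B` and phage PFU = `V + I`; prey CFU
  is the sum of all prey subtypes. `r_back` is active whenever back
  conversion is intrinsic (variants I and S).

## Numerical integration

The right-hand side is compiled C, integrated with `deSolve::lsoda`
(defaults `rtol = 1e-8`, `atol = 1e-8`; the ABC path relaxes to
`rtol = 1e-6`, `atol = 1e-4` for speed). Integration happens in linear
space; states are clamped non-negative inside the flux evaluation (so a
small negative excursion cannot feed back) and after integration, with
densities below `1e-12`/ml reported as exactly zero. Integrator failures
raise a classed error carrying the offending parameter set; the ABC
wrapper converts failures into an infinite distance so a pathological
proposal is simply never accepted. Correctness is pinned by an independent
flux-ledger implementation of the derivatives (agreement to `1e-12`
relative) and a fixed-step RK4 integrator at `h = 1e-3` h (agreement to
`1e-6` relative on all compartments above `1e-6`/ml), plus exact nesting
of N4 → N3 → N2 → N1 when the generating rates are zeroed and the
closed-form exponential in the predator-free limit.

## The synthetic-data generator

`generate_dataset()` emulates the experimental design the models target:
48 h, samples every 2 h, three replicates, four conditions (prey only,
each single predator, dual), initial densities 2.9e8 CFU/ml prey, 2.8e6
PFU/ml Bdellovibrio, 3.7e6 PFU/ml phage, and a plating detection limit of
10 CFU/ml. Replicate noise is multiplicative: each count is the true
observable times `10^e`, `e ~ Normal(0, log10_sd)` with `log10_sd = 0.15`
by default — plate counts at these densities are dominated by dilution and
pipetting error, which is multiplicative, not Poisson (a Poisson option
for counts below 100/ml exists but is off by default). The published
experiments report no numerical replicate scatter, so 0.15 is a package
default (about ±40% per replicate), not a claim about the data. Censored
values are stored as flags, never zeros, so the distance can floor them
explicitly.

What the generator does **not** emulate: optical density, the plating
dilution series itself, demographic stochasticity at low counts (the
trajectories are deterministic ODE solutions), day effects or shared
biological-repeat structure. Passing tests on synthetic data therefore
demonstrate that the inference machinery recovers known truth under the
stated noise model — not that the model family describes any particular
laboratory culture.

### The reference parameter set

`reference_parameters()` is a synthetic stand-in for a fitted "typical"
parameter set, calibrated once against the headline behaviours of the
48-h experiments: prey-only cultures remain viable on a limited medium
(`M0 = 2e8` equivalents/ml); phage-only predation crashes prey to about
2–4 × 10³ CFU/ml around 5–6 h, after which the phage-resistant fraction
(`f_R = 2.6e-6`, so ~754 cells/ml of the inoculum) regrows to roughly the
starting density; Bdellovibrio-only predation declines gradually to a
plastic-resistant plateau of ~2.3 × 10⁴ CFU/ml; and dual predation drives
total prey below 10 CFU/ml at ~14 h with no rebound. Individual rate
constants sit at textbook scales (phage burst 80, ~100 min latent cycle;
Bdellovibrio burst 3.5, ~4 h bdelloplast cycle, mortality 0.03/h). One
known limitation: under this parameterisation the dual-culture
initial-density sweep shows prey escape only for ten-fold *higher prey*
inocula; escape through ten-fold less Bdellovibrio or ten-fold more phage
would require weakening the Bdellovibrio attack enough to break the 14-h
eradication behaviour, so those regimes are not reproduced.

`reference_fit_parameters()` ships two frozen ABC-SMC fits (N3 and N4, 200
particles × 8 generations, fixed seeds) to the default synthetic dataset,
so that the doubly-resistant-prey predictions of the N4 equations are
reproducible without refitting. Both predict `N_D` far below the detection
limit at 48 h — double resistance occurs but is unobservable — with the
N4-own fit admitting more of it than the N3 fit.

## ABC-SMC

The engine is a standard sequential ABC with the model index inside the
particle:

* **Distance.** Observed replicates are averaged on the log10 scale with
  censored replicates entered at the detection limit; simulated
  observables are floored at the same limit; the distance is the sum of
  squared log10 differences over every condition × population × time
  point. Aggregating replicates first keeps the distance scale independent
  of the replicate count.
* **Priors.** Log-uniform for rate constants, fractions and scales
  (spanning at least four decades), uniform for the lysis-residue yields;
  recorded in `default_priors()` as the package's defaults. Measured
  initial densities are pinned; the unobserved initial medium `M0` is
  fitted.
* **Schedule.** Generation 1 accepts at the `alpha = 0.5` quantile of a
  pilot sample from the prior; each later generation accepts at the
  `alpha` quantile of the previous generation's accepted distances, capped
  to decrease strictly. A quantile schedule adapts to the attainable
  distance floor, which a fixed ladder cannot.
* **Proposal.** The model index is drawn uniformly from the models still
  alive (those with surviving particles); the parameter vector resamples a
  previous particle of that model by weight and perturbs it componentwise
  with a Gaussian kernel in the prior's transformed space (log10 for
  log-uniform parameters), scale 0.5 × the previous generation's
  per-parameter range. Out-of-support proposals are redrawn. Importance
  weights use the prior density over the within-model kernel mixture;
  kernel truncation at the prior box is ignored, the usual approximation
  with uniform priors. Weights are normalised across the whole
  generation, so model frequencies are read directly off particle counts.
* **Stopping.** A fixed number of generations, or an acceptance-rate
  floor; a generation that exhausts its proposal budget reports its
  tolerance in the error.

A competition "win" is a plurality of final-generation particles; the
hierarchical ladder (`default_stage_plan()`: prey phenotypes → conversion
mechanism → combined SG → signal source → resistance origin → saturation →
mortality) is configuration, not code, with each stage's non-competing
settings pinned to the reference ladder's winners. Because "how often does
a variant win" can mean one run's particle shares or many runs'
pluralities, `run_stage()` exposes the repeat count (`n_runs`) explicitly.

**Typical parameters.** From the final generation, particles are
transformed, weight-standardised and rotated by PCA; the returned set is
the accepted particle (a medoid, never a synthetic average — so it is
always simulable) closest to the weighted centroid, with per-component
distances weighted by each principal component's variance share so that
the dominant directions of posterior spread dominate the choice.

## Problem sizes

The shipped tests and the acceptance script run reduced but fixed
configurations chosen as this package's study sizes: 200 particles × 5
generations × 10 seeded runs for the prey-phenotype competition, 200
particles × 8 generations for parameter recovery (posterior medians of
`a_V`, `a_P`, `mu_max`, `f_R` land well within a factor of three of the
generating values), 100–400 particles for the engine sanity checks
(prior reproduction at infinite tolerance; a conjugate-Normal toy whose
posterior mean falls in the analytic 95% interval in ≥ 90/100 seeded
runs), and 50 prior draws for the non-negativity sweep. Oracle
integrations (RK4 at `h = 1e-3`) are compared on shortened horizons or
reduced initial densities where the full 48-h epidemic would make a
fixed small step needlessly expensive.

## Known limitations

Deterministic ODEs cannot represent extinction or jackpot fluctuations at
single-digit densities — "below the detection limit" is the honest readout,
and the clamp floor of `1e-12`/ml is bookkeeping, not biology. The signal
`C` is an effective variable: nothing identifies its units, so `sigma_C`
and `k_sig` are only jointly meaningful. The distance treats all
populations and times with equal weight on the log scale; series that are
entirely censored contribute zero and therefore no discrimination. Model
competitions between nested variants that fit equally well (N3 vs N4)
drift rather than decide — the package follows the minimal-adequate-model
convention in its reference ladder.
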