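---
title: "Modelling phage cocktail infection kinetics in a chemostat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling phage cocktail infection kinetics in a chemostat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagecocktail)
```

## The model

`phagecocktail` simulates a bacterial population growing in a chemostat —
a constant-volume vessel with nutrient inflow and culture outflow at a flow
rate $\omega$ (turnovers/h) — while it is attacked by one or two virulent
phages, A and B. Because resistance to one phage does not protect against
the other, and because two phages can infect the same cell, the bacterial
population splits into thirteen compartments:

* `S` — uninfected, susceptible cells;
* `I_A`, `I_B`, `I_AB` — cells infected by A, by B, or by both;
* `R_A`, `R_B`, `R_AB` — cells resistant to A, to B, or to both;
* `R_AIB`, `R_BIA` — resistant to one phage but infected by the other;
* `S_r`, `R_rA`, `R_rB`, `R_rAB` — refuge (dormant) counterparts of the
  four uninfected classes.

Alongside these, the state carries the two free-phage titres $A$, $B$
(PFU/mL) and the nutrient concentration $C$ (µg/mL).

**Growth.** Dividing classes (`S` and the three `R` classes only — infected
cells neither divide nor feed, refuge cells are dormant) grow at the Monod
rate $\psi\,C/(K+C)$, consuming $\varepsilon$ µg of nutrient per division.
The nutrient pool obeys

$$\frac{dC}{dt} = (C_{in} - C)\,\omega \;-\;
  \sum_i \varepsilon\, \psi_i \frac{C}{K+C} N_i ,$$

so in a closed vessel ($\omega = 0$, no phage, no decay) the quantity
$C + \varepsilon \sum_i N_i$ is conserved — one of the package's invariant
tests.

**Infection.** Adsorption can follow either of two primary models. Under
`"Standard"` (mass action) the per-step flux from a target compartment $N$
is $\delta P N\,\Delta t$ with $\delta$ in mL/min. Under `"Poisson"`
(multiple adsorption) the bound phage are
$P_b = (1 - e^{-\delta M \Delta t})P$ where $M$ sums every compartment the
phage can adsorb to, and the newly infected cells are the complement of the
Poisson zero class, $(1 - e^{-P_b/M})M$, apportioned over the target
compartments in proportion to their share of $M$. The two models agree to
first order at low multiplicity of infection (a property test holds them to
0.1% when $\delta M \Delta t < 10^{-3}$). The secondary-adsorption switch
decides whether phage also bind already-infected cells (`"Susceptible"`),
which drains free phage without further productive infection.

**Delayed lysis and superinfection.** An infection does not remove cells
instantly: a cohort infected at time $t$ lyses at $t + l$ (the latent
period), releasing $\beta$ phage per cell. The simulator keeps every
infected compartment as a ledger of cohorts indexed by their due step. When
a cell already infected by one phage is superinfected by the other, the two
lysis clocks compete: the cohort produces progeny of whichever phage's
clock expires first (strictly first — ties go to the resident phage), and
exactly one phage type is released per cohort. Pending cohorts shrink pro
rata under decay and washout, so no phage is ever released from cells that
have already died or washed out.

**Resistance.** Mutation to resistance happens only at cell division:
the mutant flux is $\mu \times (\text{births this step})$, never
$\mu \times N$. Double resistance arises at the product rate
$\mu_A \mu_B$ and is never set directly. Resistance is absolute — `R_AB`
adsorbs nothing under any mode. In `"Stochastic"` mode the mutant count is
drawn from Poisson($\lambda$) for $\lambda \le 10$ and from a
Normal($\lambda$, $\sqrt\lambda$) truncated at zero above that, using R's
Mersenne-Twister generator with Box–Muller normals, seeded from the run
configuration.

**Refuge.** A refuge models metabolically inactive cells
(`"Planktonic"`) or biofilm (`"LIFO"`). Cells enter at $\sigma$/min and
return at $\rho$/min; both rates must be positive to activate the mode.
Refuge cells never divide, mutate, or get infected. Planktonic refuge
cells still decay, wash out and (under Poisson, or Standard with
secondary adsorption) adsorb phage; LIFO cells are sessile and exempt from
all of these, and return newest-first through a per-compartment stack.
When a compartment has 10 or fewer cells outside the refuge, the influx is
a flat 0.1 cells/min rather than $\sigma N$; the rule is applied per
compartment (the convention could equally be read as applying to the
summed population — the source description does not say — and the
per-compartment reading is the plainer one).

## Numerical scheme

Integration is explicit Euler at a fixed step of 60, 30, 15 or 5 seconds.
All rates are normalised to the step before use: per-hour rates
($\psi, \gamma, \varphi, \omega$) by steps-per-hour, per-minute rates
($\delta, \sigma, \rho$) by steps-per-minute; latent periods are rounded
to the nearest whole step. One row per simulated minute is recorded
(minute boundaries coincide with step boundaries at all four step sizes),
and phage additions snap to the nearest step boundary.

Updates are *synchronous*: every flux is evaluated from the state at the
start of the step and applied together. This makes results independent of
equation ordering and automatically excludes newborn cells from the decay
term. Two capping rules guard against overshoot at coarse steps:

1. a phage's total adsorption demand plus its decay/washout is capped at
   the free pool (proportional scaling) before bacterial bookkeeping;
2. each bacterial compartment's total outflux is capped at its
   start-of-step content, scaling all of its outfluxes proportionally, so
   a compartment can empty exactly but never go negative. Influxes
   (births, refuge return) are added afterwards. Nutrient consumption is
   capped the same way, and births scale with it so conservation is never
   violated.

Cohorts due to lyse in the current step lyse in full and are excluded from
that step's pro-rata removals; this keeps the bookkeeping identity
$\Delta A = \beta_A(\text{lysed A-producers}) - P_A$ exact in a closed
vessel, which the test suite asserts at $10^{-9}$ relative. The ledgers are
authoritative for the delayed compartments — their titres *are* the pending
cohort sums — and `run_cocktail(check = TRUE)` re-derives each titre
independently from closed-form flux arithmetic every step and errors on
disagreement (double-entry audit).

There is no higher-order integrator by design: the method *is* fixed-step
Euler, and a 5-second run serves as the reference oracle
(`oracle_compare()`) against which coarser steps are checked for monotone
convergence.

Degenerate inputs are handled explicitly: `S0 = 0` disables bacteria
(useful for phage-only conservation checks), an empty additions table
disables a phage, `duration = 0` returns the initial state, and
`log10_titre(0)` is −16 by convention so extinct pools stay plottable.
With `round_below_one = TRUE`, any bacterial or phage pool strictly below
1 is zeroed after each full step (ledgers and stacks are cleared with it).

## Parameters

Defaults describe a fast-growing bacterium (think *E. coli* on glucose)
and two T-even-like phages; all values can be changed within the validated
ranges.

| symbol | meaning | default | range | unit |
|---|---|---|---|---|
| `S0` | starting bacteria | 1e5 | 0 or 0.1–1e12 | CFU/mL |
| `psi`, `psi_RA`, `psi_RB`, `psi_RAB` | max growth rates | 0.7 | 0–1.5 | /h |
| `K` | Monod constant | 5 | 0.01–100 | µg/mL |
| `epsilon` | nutrient per division | 2e-6 | 1e-8–1e-4 | µg/cell |
| `gamma` | bacterial decay | 0 | 0–1 | /h |
| `mu_A`, `mu_B` | mutation to resistance | 1e-7 | 0–1e-2 | /division |
| `sigma`, `rho` | refuge in/out | 0 | 0–0.01 | /min |
| `f_RA`, `f_RB` | initial resistant frequency | 1e-7 | 0–1e-2 | — |
| `f_RAB` | initial double-resistant frequency | 1e-14 | 0–1e-6 | — |
| `C0`, `C_in` | start/reservoir nutrient | 100 | 0–1000 | µg/mL |
| `omega` | flow rate | 0.2 | 0–100 | /h |
| `delta` | adsorption rate | 1e-10 | 1e-14–1e-7 | mL/min |
| `latent` | latent period (A/B) | 30 / 20 | 1–60 | min |
| `burst` | burst size | 100 | 0–1000 | PFU/cell |
| `phi` | phage decay | 0 | 0–1 | /h |

The only deliberate widening is `S0 = 0` (disable bacteria entirely),
which the interactive original had no reason to allow but a scriptable
simulator needs for phage-only runs. Out-of-range configuration values are
*errors* carrying the allowed range — no silent auto-correction, which
would hide mistakes in scripted use.

## The bundled scenarios and what they establish

```{r scenarios, eval = FALSE}
sim <- run_cocktail(builtin_scenario("fig2D"))
plot(sim, selection = c(1, 5, 6, 7, 14, 15))
```

* **fig2B** — one phage (burst 100, 1e8 PFU/mL) on 1e6 CFU/mL of bacteria
  at low nutrient (25 µg/mL), 200 h: damped predator–prey oscillations
  into coexistence with bacterial peaks near 1e7 CFU/mL and phage peaks
  near 1e9 PFU/mL.
* **fig2C** — the same with nutrient quadrupled to 100 µg/mL: the
  paradox of enrichment; strictly larger oscillations, yet the bacteria
  never reach zero.
* **fig2D** — both phages at 1e8 PFU/mL on 1e8 CFU/mL of susceptible
  cells, deterministic mutation, no initial resistance, 48 h at 5 s
  steps: each singly resistant class is eliminated by the other phage
  within the first hour, while doubly resistant mutants (seeded at
  $\mu_A\mu_B = 10^{-14}$ per division) grow to roughly 1e3 CFU/mL by
  48 h.

Two provenance decisions deserve a note. The single-phage scenarios fix
only the handful of parameters their figure captions state; everything
else comes from the package defaults, with one substantive choice: their
mutation rates and initial resistant frequencies are set to zero, because
the model they reproduce has no resistance compartments and a
deterministic resistant class at the default rate would sweep the culture
long before the 200 h horizon, making the documented coexistence
impossible. This was decided from the model structure, not tuned against
the test outcomes. Second, a fourth published comparison (a T4/*E. coli*
chemostat experiment) is *not* shipped: its full parameter set lives in a
data file that is not reproduced in print, so no faithful configuration
can be constructed from checkable sources.

These are synthetic scenarios: they exercise every kinetic term at
realistic magnitudes, but green checks establish internal consistency of
the model and agreement with the published simulated dynamics — not
agreement with any wet-lab experiment. Real cultures have distributed
latent periods and burst sizes (the model uses point averages), nutrient
release from lysed cells, debris that binds phage, and spatial structure,
none of which are modelled.

## Known limitations

* Explicit Euler: coarse steps overshoot; use 5 s steps (and
  `oracle_compare()`) when accuracy matters. The flux caps guarantee
  nonnegativity, not accuracy.
* The within-step flux-application order of the original interactive
  program is unknown; this package's synchronous update is its documented
  contract, so coarse-step trajectories may differ in micro-detail from
  other implementations while converging to the same dynamics as the step
  shrinks.
* Only mutation is stochastic; adsorption, lysis timing and refuge
  exchange are deterministic even in stochastic mode, and extinction
  therefore happens only through the optional round-below-one rule.
* Temperature, pH, immune effectors, pharmacokinetics and phage–phage
  interference other than lysis-time competition are out of scope.
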