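# phagecocktail

Forward simulation of bacteriophage infection kinetics in a chemostat:
one bacterial species, one or two interfering virulent phages, and the
nutrient that limits growth. The package is aimed at phage biologists and
phage-therapy researchers who want to explore infection dynamics — phage
dosing and timing, resistance emergence, refuge/biofilm protection,
nutrient enrichment — as scripted, reproducible runs rather than one-off
interactive sessions. It is a hypothesis-generation tool for in vitro
dynamics, not a pharmacokinetic model.

## The model

Thirteen bacterial compartments (susceptible `S`; infected `I_A`, `I_B`,
`I_AB`; resistant `R_A`, `R_B`, `R_AB`; resistant-but-infected `R_AIB`,
`R_BIA`; refuge `S_r`, `R_rA`, `R_rB`, `R_rAB`) are coupled to the
nutrient concentration *C* and two free-phage pools *A*, *B*. Dividing
classes grow at the Monod rate ψ·C/(K+C) and consume ε µg per division:

    dC/dt = (C_in − C)·ω − Σ_i ε·ψ_i·C/(K+C)·N_i

Phage adsorb either by mass action (flux δ·P·N per unit time, the
"Standard" model) or with Poisson-distributed multiplicity of infection
(bound phage P_b = (1 − e^(−δMΔt))·P, newly infected cells
(1 − e^(−P_b/M))·M, the "Poisson" model). Infected cells lyse after a
phage-specific latent period *l*, releasing β phage per cell; infection
cohorts are bookkept by due time so the delay terms I(t−l) are exact.
When both phages occupy one cell, the earlier lysis clock wins and only
that phage's progeny are released (superinfection interference).
Resistance arises only at cell division, at rate µ per division (doubly
resistant cells at µ_A·µ_B), deterministically or by Poisson/normal
sampling. Optional refuge compartments model dormant cells or biofilm
(last-in-first-out return). Everything planktonic washes out at the flow
rate ω; bacteria and phage can additionally decay (γ, φ).

Integration is fixed-step explicit Euler at 60, 30, 15 or 5 s, with
synchronous (start-of-step) flux evaluation and proportional flux capping
so that no pool ever goes negative. See the vignette
(`vignettes/phage-cocktail-kinetics.Rmd`) for the full scheme and the
design decisions.

## Worked example

The bundled `fig2D` scenario: 1e8 CFU/mL of susceptible bacteria hit at
t = 0 by two phages (1e8 PFU/mL each) that differ only in latent period
(A: 30 min, B: 20 min), deterministic mutation at 1e-7 per division, no
pre-existing resistance.

```r
library(phagecocktail)
cfg <- builtin_scenario("fig2D")
cfg$step_size <- 60     # coarse step for a quick look (scenario default: 5 s)
sim <- run_cocktail(cfg)
print(sim)
#> <cocktail_sim> 48 h simulated at 60 s steps (2881 records)
#> final titres:
#>          S        I_A        I_B       I_AB        R_A        R_B       R_AB
#> 2.529e-250 8.877e-254 3.539e-253 1.311e-256 1.088e-171  1.219e-13  1.711e+03
#>          A          B          C
#>  1.312e+05  7.550e+05  9.999e+01
```

Reading the numbers: the susceptible population is wiped out (`S` ~ 0),
and the faster phage B ends up far more abundant than A having claimed
most doubly infected cells. Cells resistant to only one phage never
establish — the other phage kills them; `R_A` peaks at ~2.2 cells/mL
around 25 min and collapses below 1 CFU/mL within the first hour:

```r
s <- as.data.frame(sim)
max(s$R_A)                         # 2.19 CFU/mL
all(s$R_A[s$time_h >= 1] < 1)      # TRUE
```

Only the doubly resistant class survives phage pressure, seeded at rate
µ_A·µ_B = 1e-14 per division and growing to `R_AB` ≈ 1.7e3 CFU/mL by
48 h. The free phage decline at the washout rate once hosts are gone, and
the nutrient relaxes back to the reservoir concentration (~100 µg/mL)
with no one left to consume it.

Charts and files:

```r
write_timeseries(sim, "fig2D.csv")                  # log10, titre 0 -> -16
render_chart(sim, "fig2D.svg", "svg", selection = c(1, 5, 6, 7, 14, 15))
```

The same run from a shell, via the thin CLI wrapper:

```sh
Rscript inst/cli/cocktail --scenario fig2D --step 60 --csv fig2D.csv
Rscript inst/cli/cocktail --config inst/extdata/fig2B.ctl --png fig2B.png
```

Run configurations live in a plain-text, strictly ordered, comma-delimited
`.ctl` format (`read_config()` / `write_config()`); canonical files for
all bundled scenarios are under `inst/extdata/`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation — the fig2D
two-phage scenario at its full 48 h / 5 s-step resolution — from the
installed package and writes the machine-readable report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The regression checks themselves (resistant-class collapse, the ~1e3
CFU/mL doubly resistant titre, coexistence and enrichment behaviour of the
single-phage scenarios, conservation and bookkeeping identities) run as
part of the test suite in `tests/testthat/test-acceptance.R`.
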