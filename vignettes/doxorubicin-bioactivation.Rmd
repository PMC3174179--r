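---
title: "Kinetic modelling of doxorubicin bioactivation: models, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of doxorubicin bioactivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doxcycle)
```

## The biochemical system

Doxorubicin carries a redox-active quinone moiety. Inside cells (and in
reconstituted reaction mixtures) the drug is *bioactivated* by two coupled
processes:

* **Reductive conversion** — cytochrome P450 reductase (CPR) transfers one
  electron to the quinone, producing a semiquinone radical; NADPH
  re-reduces the oxidized CPR. Net transformation of quinone into
  semiquinone is associated with drug toxicity.
* **Redox cycling** — molecular oxygen re-oxidizes the semiquinone back to
  the quinone, releasing superoxide. The loop is futile with respect to
  the drug (zero net transformation) but generates reactive oxygen
  species.

Which process dominates depends on the supply of NADPH and O2 and on the
activities of the surrounding enzymes (SOD, NADPH oxidase, G6PD). The
package implements two mass-action ODE models of this network:

* a **cell-free model** (9 species, reactions R1–R6): CPR_red/CPR_ox,
  quinone and semiquinone doxorubicin, NADPH/NADP, O2, superoxide, H2O2.
  R1: `k1 [CPR_red][Dox_q]`; R2: `k2 [CPR_ox][NADPH]` with `k2 = k1` by
  definition; R3: `k3 [O2][Dox_sq]`; R4: `k4 [NADPH][O2]` (non-enzymatic);
  R5: `k5 [O2-][Dox_q]`; R6: `k6 [O2-]^2`.
* a **cell model** (10 species, R1–R8) for two patient-derived acute
  lymphoblastic leukemia lines — EU1-Res (doxorubicin-resistant) and
  EU3-Sens (doxorubicin-sensitive). It splits the drug into
  extracellular/intracellular pools coupled by membrane permeation
  (R7: `k7 A [Ex_Dox_q]`, with `A` the aggregate cell surface per culture
  volume), makes R4 the NOX4-catalyzed reaction, and adds G6PD-driven
  NADPH regeneration (R8: `k8 [NADP]/(k9 + [NADP])`). The sensitive-line
  model is derived from the resistant-line model by measured fold changes
  (CPR, basal NADPH, `k4`, `k8`; no change in `k6`), never refitted.

All rate constants are per second and concentrations molar; time-course
input and output is in minutes. Published constants ship in the builders
(`build_invitro_model()`, `build_invivo_model()`); every scenario is a
declarative `dox_scenario()` that serializes to JSON/YAML and rebuilds the
identical model.

## Oxygen bookkeeping (a deliberate design choice)

The printed rate expression for dismutation, `k6 [O2-]^2`, does not state
what happens to the oxygen. We resolve it asymmetrically:

* spontaneous dismutation (cell-free R6) consumes two superoxide and
  yields H2O2 only — a terminal sink for oxygen;
* the SOD-catalyzed route (the optional cell-free SOD term, and the
  SOD1-linked R6 of the cell model) regenerates O2.

This is the only reading under which the cell-free model reproduces the
documented switching: at 100 µM NADPH the oxygen pool outlives NADPH and
the system redox-cycles; at 500 µM NADPH the NADPH/O2 reaction (R4)
exhausts oxygen, semiquinone re-oxidation stops, and reductive conversion
goes to completion; adding SOD restores cycling precisely because SOD
returns oxygen to the pool. With a symmetric "H2O2 + O2" stoichiometry on
the spontaneous route the oxygen pool never empties at 500 µM (we verified
this numerically) and no switch exists.

## Transport and compartment volumes

Permeation is written on the extracellular pool:
`d[Ex]/dt = -k7 A [Ex]`. The same molar flux concentrated into the much
smaller cytosolic volume raises the intracellular concentration by the
medium-to-cytosol volume ratio `vol_ratio`:
`d[In]/dt = +vol_ratio * k7 A [Ex]`. With the published cell density
(10^9 cells/L, part of `A`) and an accessible cytosolic volume of roughly
100 fL per lymphoblast, `vol_ratio = 1e4` (cytosolic volume fraction
1e-4). This coupling is essential, not cosmetic: the G6PD supply ceiling
is `k8 = 1.8e-6` M/s, and only a volume-concentrated drug influx produces
an NADPH demand of that order. Without it the cell models show no NADPH
depletion, no response to G6PD inhibition, and an inverted cell-line
ordering of quinone accumulation. Total drug
(`[Ex] + ([In_q] + [In_sq]) / vol_ratio`) is conserved exactly; the
package tests assert it along every trajectory.

## Intracellular oxygen

The cell model's initial O2 (1.5e-9 M) is a standing intracellular level,
not a closed reservoir: cells sit in oxygenated medium. By default the
model therefore *clamps* O2 at its initial value (`oxygen_clamp = TRUE`);
a fully dynamic pool is available as a flag. With a closed 1.5 nM pool
every oxygen-dependent flux collapses within seconds and the hour-long
readouts the model exists to describe (NADPH depletion, superoxide
generation, intervention responses) cannot occur.

## NOX4 drug dependence

The cellular R4 is modulated by intracellular quinone drug through a
dimensionless saturable factor `[In_q]/([In_q] + k_dox)` with
`k_dox = 1e-7` M (option `r4_mode = "table_literal"` removes it). The
modulation keeps the printed bimolecular form and units at saturation and
gives NOX activity the documented drug dependence: at the 10 µM dose the
factor is ~1 within minutes, at 100 nM it stays well below 1.

## Parameter fitting

The cost is the unweighted sum of squared residuals over observables and
grid points, with each series max-normalized when the stage demands it.
Every published fit is one-dimensional, so the optimizer is deterministic
bounded scalar minimization (Brent golden-section/parabolic via
`optimize()`), run on a log10 scale with bounds three decades either side
of the initial guess and a relative tolerance of about 1e-6. Recovery
tests start the search a factor of 10 from the generating value. Trial
values that make the system too stiff to integrate are penalized with a
large constant so the search retreats.

Stages (`run_fit_pipeline()`):

* cell-free, on max-normalized quinone + NADPH over 0–20 min (11 points):
  `k1` against the 100 µM NADPH redox-cycling condition, `k4` against the
  500 µM reductive-conversion condition, `k5` against the 500 µM + SOD
  condition, each carrying forward the previous estimates and `k2 = k1`
  throughout;
* cellular, resistant line at 10 µM over 0–60 min (7 points): `k7`
  against raw extracellular depletion first — that series is governed by
  transport alone, so ordering it first decouples the stages — then `k8`
  against max-normalized NADPH.

On noiseless self-generated data all five constants are recovered to
better than 1% (the identifiability check behind the acceptance suite).

## What the synthetic data emulate — and what they do not

`generate_invitro_dataset()` / `generate_invivo_dataset()` produce the
assay structure of the study: normalized quinone and NADPH series on the
11-point cell-free grid, and quinone accumulation, NADPH fraction,
cumulative superoxide signal and extracellular depletion on the 7-point
cellular grid. Noise is additive Gaussian with standard deviation a
fraction (default 0.02) of each series' maximum, independently for each
of 3 replicates, seeded and fully reproducible; normalized series are
clipped to [0, 1.05] and concentrations at zero. The superoxide readout
models an irreversibly oxidized probe, i.e. the running time-integral of
superoxide production (R3 + R4) normalized to its 60-minute value, not
the instantaneous superoxide concentration.

The generator does not emulate instrument drift, well effects,
proportional (signal-dependent) noise, or biological replicate-to-
replicate parameter variation. Passing recovery tests therefore show the
pipeline is self-consistent and numerically sound — not that the
published constants are uniquely determined by real assays.

Measured identifiability limits at the default 2% noise (20 seeds,
replicate-averaged fits): `k1`, `k4`, `k8` recover with median errors of
roughly 3%, 8% and 2%; `k7` does not (median ~25%), because the 10 µM
extracellular pool only falls by ~2.4% in an hour (`k7 A = 6.8e-6` per
second) — the signal sits at the noise floor; and `k5` is effectively
unidentified under the SOD condition, whose dismutation shunt makes the
cost nearly flat above the true value. The property tests assert the
identifiable set.

## Downstream analyses

* `classify_metabolic_mode()` labels a trajectory by the net fractional
  quinone transformation `1 - q(end)/max(q)`; the threshold 0.2 is a
  package convention (the published assignment is qualitative) and the
  statistic is unit-free.
* `integrated_flux()` is the trapezoidal time-integral of a reaction rate
  along a trajectory; the semiquinone-formation flux is R1's integral and
  the NADPH-dependent superoxide flux is R4's, over the 60-minute
  treatment window on a 0.1–0.25 min grid.
* `compare_intervention_fluxes()` runs the 2 cell lines x 2 doses grid
  with and without a 20% reduction of `k8` (the DHEA simulation) and
  reports intervention/control ratios.
* `sensitivity_scan()` perturbs one quantity at a time by ±10% and forms
  normalized central-difference coefficients
  `S = (O(+) - O(-)) / O(base) / (2 delta)` of three 60-minute readouts:
  quinone accumulation, depleted NADPH fraction, and cumulative
  superoxide production. Endpoint readouts (rather than time-integrated
  or pointwise ones) are the declared convention; coefficients at a zero
  baseline are flagged undefined rather than reported as zero.

## Numerical choices

Integration uses a stiff solver (`deSolve::lsoda`) at `rtol = 1e-8`,
`atol = 1e-14` M — species span roughly 1e-11 to 1e-3 M and the fastest
relaxation (semiquinone re-oxidation in the cell-free model) is ~8e4 per
second. Solutions are reported exactly on the requested minute grids.
Negative excursions from integrator overshoot are clamped to zero inside
rate evaluation only; the state is never modified. Halving the tolerances
moves reported observables by less than 0.1% (asserted in the tests). The
test suite cross-checks the solver against a fixed-step fourth-order
Runge–Kutta reference on a short window with a step inside the explicit
stability region, and the whole rate engine against an independently
hand-written transcription of the model equations at random states.

Problem sizes throughout the tests and the acceptance script are the
study's own: 11- and 7-point assay grids for fitting, 0.1–0.25 min grids
for flux integrals, 20-seed Monte Carlo for the noisy-recovery property.

## Known limitations

* The intervention analysis reproduces the documented directional
  pattern with one exception: with the printed bimolecular NOX rate
  (linear in NADPH), a 20% cut in NADPH supply lowers the integrated
  superoxide flux in *every* condition, including the sensitive line at
  10 µM, where the published simulations report no decrease. The
  mechanism claimed for that exception (an NADPH threshold below which
  NOX activity is unaffected) implies a saturable-NADPH rate law whose
  form is not published; we keep the printed linear form and report the
  discrepancy rather than invent the nonlinearity. The corresponding
  assertion in the acceptance suite is expected to fail and says so.
* Viability is outside the model: fluxes are linked to cytotoxicity only
  qualitatively.
* No mitochondrial/NADH pathway, nuclear compartment, glutathione
  detoxification, or efflux transport; no stochastic simulation.
* The El-Kareh-style saturable uptake component and the time-varying
  permeability mentioned for the high-dose condition are not published
  in closed form; transport is the linear permeation term with the
  dose-specific `k7` (the low-dose constant is 10x the high-dose one, as
  published).
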