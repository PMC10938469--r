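---
title: "An auxin transport model of shade-avoidance growth in the Arabidopsis hypocotyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An auxin transport model of shade-avoidance growth in the Arabidopsis hypocotyl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auxgrad)
```

## The modeled system

During the shade avoidance syndrome (SAS), a low red:far-red (R:FR) light
ratio — the optical signature of neighboring vegetation — triggers rapid
elongation of the *Arabidopsis thaliana* hypocotyl.  Growth is purely by
cell expansion, driven by auxin produced in the cotyledons and transported
down the hypocotyl.  Elongation is not uniform: epidermal cells in the
middle of the organ end up several-fold longer than cells at either end,
the characteristic *arch-shaped* cell-length profile.  `auxgrad` implements
a compartmental model in which this pattern emerges from a *shallow* auxin
gradient shaped by three processes — synthesis (input at the top),
polar/non-polar transport, and light-dependent degradation — with no
auxin-transport feedback of the kind that patterning models use to build
sharp auxin maxima.

## Model structure

The hypocotyl is a 2-D cellular grid: four concentric layers (epidermis,
outer cortex, inner cortex, endodermis) by 18 rows top to bottom, plus a
19th row representing the root, added to avoid boundary artefacts.  The
grid size follows measured epidermal cell counts (15–23 cells per file,
mode 18).  Each cell holds an auxin *quantity* `q`; its concentration is
`A = q / l`, where `l` is the row length (all layers of a row share the
epidermal length, because the thick-walled epidermis limits organ
elongation and inner tissues follow passively).

Two saturating response functions are used throughout, with translational
value `u`:

* sigmoid `S(x, u) = (x-u)^2 / (a + (x-u)^2)`,
* Monod `M(x, u) = (x-u) / (b + (x-u))`.

By default the package *clamps* `x - u` at zero inside these functions
(`clamp_regulatory = TRUE`).  The plain algebraic forms are symmetric about
`u` — they rise again for `x < u` — which contradicts the intended
monotone readings (more epidermal auxin means more growth; less light
means less degradation).  Clamping enforces those readings; the symmetric
literal behavior remains available via the flag.

The dynamics on the grid:

* **Input** (top endodermal cell only):
  `dq/dt = mu * alpha(t) * M1(I_c0 + \int_0^t I(s) ds, u_c)`.
  The Monod term tracks cumulative light as a proxy for cotyledon (source)
  size; `alpha(t) = 1 - S2(beta * I_fr(t), u_fr)` encodes R:FR control of
  auxin synthesis.
* **Transport**: every face carries the non-polar (ABCB-type) permeability
  `P_np`; the bottom face additionally carries the polar basipetal
  (PIN-type) component `P_polar_bottom`, and the outward face the polar
  centrifugal component `P_polar_out`.  The flux between neighbors is
  `P_ji q_j - P_ij q_i`, i.e. permeability times donor *quantity*, taken
  literally from the model's flux rule (a `transport_on_concentration`
  option divides by donor length for exploration; it is off by default
  because the literal rule is the documented one).  Boundaries are closed
  at the epidermis outer face, the endodermis inner face and the top of
  row 1; the root row absorbs the basipetal flux and returns nothing
  (pure sink — the root is read as importing whatever the hypocotyl
  exports).
* **Degradation**: `eta * (q_i / l_i) * S3(I(t), u_I)` per cell —
  proportional to concentration, activated by light (high white light
  promotes auxin inactivation; S3 is clamped to zero below `u_I`).
* **Growth**: `dl_k/dt = lambda * S1(A_k,ep, u_mu)` from the epidermal
  concentration only.  Growth is irreversible; lengths never decrease.

Genotypes enter as four multipliers in `[0, 1]`: synthesis (*sav3*),
non-polar permeability (*abcb1 abcb19*), polar permeability and input
(*pin3 pin4 pin7*, both fixed at 0.1 in the triple-mutant scenario).  The
*abcb* and *sav3* factors are free parameters estimated during
calibration, since the data constrain them only through the mutant
profiles.

## Light forcing

PAR is piecewise-constant: continuous (CL) regimes hold their fluence rate
(75 or 130 uE) at all times; long-day (LD) regimes give 16 h light / 8 h
dark per 24 h cycle, starting with light at t = 0.  The cumulative light
integral is evaluated in closed form, so no quadrature error enters the
input term.  Far red switches on at the start of day 4 (t = 96 h): the
relative phytochrome signal drops from 1 with first-order kinetics
(half-life 30 min, `I_fr,max * 2^(-2s)`) to a residual plateau
`epsilon = 0.3`, reflecting the ~30 % of phytochrome that stays active.
`I_fr,max` defaults to 1, which makes the signal continuous at onset.  The
signal depends only on FR onset, not on the LD dark phase, because the
source model's function has no photoperiod dependence; phytochrome
re-accumulation after FR removal is not modeled (the treatments never
switch FR off again).

## Numerical scheme

Integration is explicit Euler with a configurable step (`dt`, default
0.01 h), matching the discrete length-update rule the model is stated
with.  The scheme is guarded twice: a step-halving test requires final
lengths to move by less than 0.5 % when `dt` is halved, and any negative
quantity arising from too large a step is clipped at zero — clips beyond
1e-12 of cumulative input abort with advice to reduce `dt`.  During
calibration the package runs at `dt = 0.05` h (a 192 h trajectory per
condition costs ~4000 steps); reported simulations use `dt = 0.01` h.
The step-halving criterion holds across this range.  A mass ledger tracks
cumulative input, degradation and root export; the identity
`total q = input - degraded - exported` closes to 1e-8 relative at all
times and is tested.  Time is in hours throughout, so the phytochrome
decay exponent `2^(-2t)` gives the 30-minute half-life directly.

## Calibration

The objective compares measured and simulated 18-cell profiles.  The
printed score formula (`J = dt * sum_k |l_k - gamma_k l_k|`) is
dimensionally ambiguous — read literally, `gamma_k` multiplies the
measured length, and the `dt` prefactor ties the score to the integration
step.  The package's default objective is therefore the mean relative
absolute error `(1/18) sum |l_k - gamma_k| / l_k`, the only scale-free
reading, whose magnitude is also compatible with reported J values in the
0.13–0.22 range; the literal form is retained as `variant = "literal"`.
The global objective is the unweighted mean over all fit-split profiles
(day-4 white, day-6 white, day-6 FR for each genotype and condition in the
fit split: all wild type, plus the mutants at CL75 and LD130; mutants at
CL130 and LD75 are held out for validation).

Fitting is simulated annealing in three stages, mirroring an
approximation pass followed by two optimization rounds: a Latin-hypercube
screen (150 points) picks a starting point and narrows each bound to half
its width around it; then two annealing runs (geometric cooling 0.95, 200
iterations per temperature, Gaussian single-coordinate proposals with
standard deviation 5 % of each bound width; the second run restarts from
the first's optimum with the bounds re-narrowed around it and a tenth of
the initial temperature, so its proposals act as fine-tuning moves),
followed by a bounded Nelder-Mead polish — single-coordinate proposals
cannot descend correlated (diagonal) valleys of the objective, and a
local simplex from the annealing optimum resolves them.  Twenty-four
temperature levels per run keep a full calibration around ten minutes on
one core; the iteration and cooling settings are exposed through
`annealing_schedule()`.  The initial temperature is set from a pilot
sample of proposal deltas around the screening optimum (median worsening
divided by `ln 2`, i.e. a median-size uphill move starts ~50 % likely to
be accepted).  Proposals touch one
coordinate at a time because joint Gaussian moves in 17 dimensions are
almost never accepted at useful step sizes.  The initial temperature
defaults to the spread of the screening objective values.  Every
stochastic element is driven by one seed, so a fit is exactly
reproducible.

The constructor defaults of `model_parameters()` are the search's initial
values, and they encode one substantive prior: centrifugal (inward-to-
outward) auxin delivery is dominated by the non-polar ABCB component
(`P_polar_out` starts near zero, with moderate equal `P_np` and
`P_polar_bottom`).  The grid's geometry makes this choice consequential —
an epidermal cell has three non-polar exit faces and a single entry face,
so if outward delivery were mostly polar, *reducing* non-polar
permeability would *increase* epidermal auxin retention and growth, the
opposite of the severe *abcb1 abcb19* growth defect.  Starting the search
in the ABCB-delivery regime lets the calibration reproduce the mutant
ordering, and empirically it also reaches a lower objective than searches
started elsewhere, which tend to stall in the polar-delivery regime.

Fitted set: the three regulatory triples (`u_mu`/`a1`, `u_fr`/`a2`,
`u_I`/`a3`), `lambda_growth`, `mu_input`, `u_c`/`b1`, `beta`, `eta`, the
three permeability components, and the two free genotype factors.  Fixed:
`I_c0 = 25` uE (arbitrary origin of the light integral), `epsilon = 0.3`,
`I_fr_max = 1`, `l0 = 10` um, and `dt`.

`default_parameters()` ships the result of running exactly this procedure
against the packaged synthetic study (default specification, seed 1) —
the model's own working calibration, not measured constants.  The
upstream study's fitted table was never published, so these values stand
on the synthetic data alone.

## Sensitivity analysis

`sensitivity_scan()` perturbs each fitted parameter by +/-1 % of its
fitted value, recomputes the global J over the fit split, and reports
`delta_J = J_baseline - J_perturbed` (negative = the perturbation worsened
the fit), two signed entries per parameter, ranked most-negative first.
The scan is deterministic after fitting.  On the packaged synthetic
calibration the basipetal permeability group and the R:FR production
parameters rank among the most sensitive, consistent with polar transport
and FR-induced synthesis being the processes whose knockouts abolish the
growth response; the exact ranking depends on the synthetic effect sizes,
so the package treats it as a soft expectation (warning, not failure).

## The synthetic study

Real per-cell measurements behind the model were never deposited, so the
package generates a structurally faithful stand-in.  `arch_profile()` is a
Gaussian bump on a baseline — the simplest smooth interior-maximum family;
nothing in the source suggests a specific functional form.  Defaults, each
a one-time choice of plausible magnitude rather than a claim about the
real data:

* day-4 baseline: 20 um ends, shallow 60 um arch (cells roughly triple
  from the 10 um initial length in four days of white light);
* day-6 growth increment: up to 250 um at the arch center (cells of
  several hundred um mid-hypocotyl after shade treatment), centered at
  row 9.5 with width 5 rows;
* genotype multipliers 1.0 / 0.6 / 0.35 (wt / *abcb1 abcb19* / *sav3*) and
  condition multipliers 1.0 / 0.85 / 0.7 / 0.55 (CL75 / LD75 / CL130 /
  LD130), encoding the observed orderings: mutants grow less, low light
  and continuous light promote SAS;
* far-red boost 1.5 over white light at day 6;
* replicate noise sd 8 um, 8 replicates, 95 % CIs as `1.96 sd / sqrt(n)`.

What the generator does *not* emulate: measurement covariance along the
hypocotyl, non-Gaussian replicate scatter, day-4 genotype differences, and
any numerical agreement with the published figures.  Tests that pass on
this synthetic study therefore validate the machinery (simulation,
calibration, scoring, sensitivity) and the qualitative orderings — not the
published J-scores, which depend on unavailable data.

## Degenerate inputs and edge behavior

Grids of any size >= 1 x 1 are supported (the root row is always added);
a zero-duration simulation echoes the initial state; the unclamped Monod
function raises an explicit singularity error at `x - u = -b`; unknown
config keys are rejected by name; annealing proposals are clipped to their
bounds, so no fitted value can leave its box.

## Known limitations

* The calibration under-determines the growth threshold `u_mu` from
  wild-type-like data alone: profiles constrain the product of scale
  parameters more tightly than the threshold itself.  The triple-mutant
  no-growth scenario is the behavior that discriminates; it is checked,
  not enforced.  The calibrated optimum favors weak auxin degradation,
  under which even a 10 % input transiently clears the threshold during
  the white-light phase, so the simulated triple mutant shows some
  residual elongation instead of none — the corresponding check reports
  this rather than masking it.
* Explicit Euler limits admissible permeabilities to
  `dt * (sum of face permeabilities + degradation rate) < 1`; the fitting
  bounds respect this at `dt = 0.05` h except in extreme corners, which
  the objective rejects as unstable rather than silently accepting.
* No cell division, no stele/pericycle/phloem compartments, no radial
  asymmetry or tropic bending, and no subcellular transporter
  relocalization feedback — all deliberate scope boundaries of the model
  family this package implements.

## A short session

```{r, eval = FALSE}
study <- generate_study(synthetic_spec())
fit <- fit_parameters(study, init = model_parameters(dt = 0.05), seed = 1)
sim <- simulate_hypocotyl(fit$params, fit$geno_factors$wt,
                          light_regime("CL75"), duration_days = 6)
plot(sim$final_lengths, type = "b", xlab = "cell (top to bottom)",
     ylab = "length (um)")
conc <- epidermal_concentration(sim$final_state)
max(conc) / min(conc)        # shallow gradient: < 2.5-fold
sens <- sensitivity_scan(fit, study)
head(sens[order(sens$delta_J), ])
```
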