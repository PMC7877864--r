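---
title: "Methods: a QSP model of biomarker response in Crohn's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a QSP model of biomarker response in Crohn's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cdqsp` is a quantitative systems pharmacology (QSP) package for simulating
how biologic therapies move the clinical inflammation markers of Crohn's
disease — serum C-reactive protein (CRP, mg/L) and fecal calprotectin
(FCP, mg/kg) — in virtual patient populations. This vignette is the
package's own account of the model, its assumptions, and the design
decisions behind it.

## The immune-network model

The disease state is a single well-stirred serum/tissue compartment with 22
species: eleven cell populations (naive T cells Th0 and their Th1/Th17
progeny, regulatory T cells, NK1 cells, immature and effector dendritic
cells, resting and classically activated macrophages, resting and activated
neutrophils), nine cytokines (TNFa, IL-6, IL-8, IL-12, IL-17, IL-22, IL-23,
IFNg, GM-CSF), and the two clinical markers. Time is in days, cytokines in
pg/mL serum-equivalent.

Three rate-law families cover every reaction:

* first-order turnover for every species (boundedness),
* Michaelis–Menten (Hill, coefficient `n_hill`, default 1) activation for
  every modifier arrow,
* additive, cytokine-independent basal production floors.

The wiring follows the canonical Crohn's disease axes. IL-12 drives
Th0→Th1 differentiation and, with NK1 cells, IFNg production. IL-23 (with
an IL-6 co-drive) drives Th0→Th17, and Th17 cells produce IL-17 and IL-22;
IL-17 additionally carries a constant basal source, so IL-23 blockade can
never abolish it. TNFa activates dendritic cells, macrophages, and
neutrophils, with IL-6, IFNg, and IL-17 respectively as co-activators —
the co-activator arms are what give IL-12/23-directed therapy a route to
the innate compartment. The activated innate cells (eDC, M1, Neu_a) produce
TNFa, IL-6, IL-8, IL-12, IL-23, and GM-CSF; TNFa and IL-17 jointly amplify
IL-6 production through a saturating factor with its own half-maximum
constants (`Km_TNF_IL6`, `Km_IL17_IL6`). CRP production is a Hill function
of IL-6 (`Km_IL6_CRP`) over a small IL-6-independent floor; FCP production
is driven by activated neutrophils with an IL-8 co-drive. Homeostatic Treg
inhibits Th differentiation but receives no feedback, and the naive T-cell
pool is homeostatically maintained — differentiation drives Th1/Th17
production without depleting Th0, so blocking one axis cannot boost the
other through precursor competition. All loops in the network are positive
with saturating gains, so the system is monotone: the
test suite verifies that reducing any drug target's free fraction never
raises steady-state CRP.

`build_network()` returns the full reaction table (exportable to CSV with
`network_to_csv()`), and `cd_derivatives()` is the pure-R reference
implementation of the right-hand side. The solver uses an identical
compiled C implementation (`src/cd_rhs.c`) through `deSolve::lsoda` at
`rtol = 1e-8`, `atol = 1e-10`; the two paths are cross-checked against each
other and against an independently written rate-law evaluator in the tests.

### The baseline anchor

Rather than publishing a list of opaque rate constants, the nominal
parameterisation is *anchored*: structural constants (sources, turnover
rates, half-maximum constants, co-activation weights, floors) are stated
design values, and every production gain is solved in closed form so that a
stated moderate-to-severe disease baseline (TNFa 15, IL-6 10, IL-8 30,
IL-12 5, IL-17 8, IL-22 20, IL-23 5, IFNg 10, GM-CSF 5 pg/mL; CRP 10 mg/L;
FCP 600 mg/kg) is an exact fixed point:

```{r}
library(cdqsp)
p <- nominal_parameters()
max(abs(cd_derivatives(nominal_state(), p)))  # 0 to machine precision
```

`rederive_gains()` exposes the same operation for arbitrary structural
values. Calibration uses it after every parameter move, so fitting
dose-response *curvature* never un-anchors the disease baseline — the
analogue of training a disease model once on steady-state biomarker levels
and holding it fixed while drug layers are added.

## Drug layers: PK and target binding

Each antibody follows linear two-compartment kinetics in closed form
(biexponential after an IV bolus; first-order absorption for SC doses;
superposition over dose events), with mg/kg doses resolved at a 70 kg
standard weight. Published per-drug PK parameter values are not bundled here, so
the package ships literature-typical monoclonal-antibody defaults
(CL 0.2–0.3 L/day, V1 3–3.5 L, V2 2.5–3 L, Q 0.35–0.45 L/day, ka
0.22–0.26/day, F 0.65–0.75), marked as repo defaults and overridable per
drug via a YAML config. Every subject in an arm shares the arm's
concentration-time profile: between-patient variability is purely
mechanistic by construction.

Drug action enters through quasi-equilibrium binding. For a targeted
cytokine with total concentration T (nM), antibody binding sites
B = 2 x antibody (nM), and affinity Kd, the free fraction solves
L² + (Kd + B − T)L − KdT = 0, and wherever that cytokine acts as a
modifier its concentration is multiplied by the free fraction. Because
antibody concentrations (tens of nM) dwarf cytokine concentrations
(~10⁻³ nM), binding equilibrates far faster than weekly dosing, which is
why an algebraic treatment replaces on/off kinetics. Affinities are config
values: 0.1 nM for the IL-12p40, IL-23p19 and TNFa antibodies (typical
therapeutic affinity), and 2 nM for the anti-IL-6 antibody — the one
affinity the dose–response data actually constrain, since the graded
10/50/200 mg CRP response requires partial target coverage at trough in
the low-dose arm. The mechanism table maps ustekinumab to {IL-12, IL-23}
(shared p40 subunit), brazikumab/risankizumab to IL-23, infliximab to
TNFa, and PF-04236921 to IL-6; concurrent drugs on one target would
combine multiplicatively (none of the built-ins overlap).

## Virtual patients and trial matching

A plausible patient is a multiplier vector on the variability subset
applied to the nominal parameters, whose drug-free steady state converges
and lands inside the plausibility window (CRP 0.1–200 mg/L, FCP
10–5000 mg/kg, all cytokines < 10⁴ pg/mL). Multipliers are log-uniform
over ±10-fold. The variability subset is deliberately composed of
production gains, cell sources, and turnover rates — quantities that
genuinely differ between subjects — plus the TNFa-on-IL-6 half-maximum
constant, which the responder analysis examines. Half-maximum constants
and basal floors are otherwise held common: they are molecular properties
of receptors and enzymes, and letting them vary ten-fold creates a
saturation-driven non-responder class that is an artefact of the prior
rather than of the biology.

Trial matching (`select_trial_population()`) reproduces the reporting
heterogeneity of induction trials: a target can be stated as median+IQR,
mean+SD, or median+range, each approximated by a log-normal law for
importance weighting (weights are target density over kernel-smoothed
source density), followed by sampling without replacement, accept/reject
on the achieved joint statistic recomputed in the target's own kind, and a
greedy swap-refinement pass. Selection never fabricates patients — the
output is a subset of the input by id — and the CRP–FCP correlation is
whatever the mechanism induces.

## Trial simulation and responder rules

`simulate_arm()` integrates every patient from its own steady state under
the arm's binding-site forcing functions and summarises each marker as
median/IQR, mean/SD, and range, in absolute, change, and percent-change
form — matching however a given trial reports. Placebo arms are simulated
as no drug (the model carries no study-design/placebo component; placebo
correction is applied to reported rates only, by subtraction).

Responder rules: a percent-decrease criterion (`>= 60%` from baseline; the
comparison uses `>=`, one of the two readings the source material permits,
and the threshold is configurable) and absolute normalisation criteria
(CRP < 3 or < 5 mg/L, FCP < 250 mg/kg), all assessed at week 6 (day 42;
the output grid must contain the assessment day). Absolute criteria first
exclude patients already below the cutoff at baseline.
`classify_responders()` partitions a population into
both/only-A/only-B/neither for two treatments on identical patients, and
`compare_groups()` summarises baseline species and parameters per class.

## Calibration

`calibrate()` fits a chosen subset of structural parameters to printed
clinical outcomes. The default target set is the week-12 median percent
CRP change in the three anti-IL-6 arms (−65.6, −86.3, −95 %), the printed
dose-response readout this package treats as its training data; the
default fitted parameters are `Km_IL6_CRP` and `b_CRP`, which control the
curvature and floor of the IL-6→CRP transfer. The objective is a weighted
sum of squared relative residuals (log-scale for absolute concentrations,
linear for percent changes) over a frozen, seeded surrogate population of
100 patients, with integration failures penalised; the optimizer is a
Latin-hypercube multistart followed by Nelder-Mead on log-multipliers,
projected into ±100-fold bounds. The population-median objective is only
piecewise-smooth, which is why a derivative-free strategy is used. A
parameter-recovery experiment (tests) perturbs five production gains
three-fold, regenerates synthetic targets, and requires recovery within
25% across 20 seeded repeats.

Two deliberate scale choices: the calibration surrogate is unselected
(matching is applied once, after calibration, for reported simulations) —
re-matching inside every objective evaluation multiplies cost roughly
ten-fold without materially changing median-percent-change targets — and
reported analyses use 200-patient matched populations drawn from
desk-scale cohorts of 1,500–2,500 plausible patients (the full design
contemplates a 40,000-patient database; `generate_cohort()` defaults to
that size, and every result here is a function of the seed and sizes
recorded with it).

## Synthetic data, numerical choices, limitations

All inputs are synthetic and generated in code. `make_trial_fixture()`
draws log-normal baselines (CRP median 10 mg/L, FCP median 600 mg/kg,
geometric SD 2.5 — bracketing reported induction-trial baselines) and
longitudinal summaries as a true suppression curve plus seeded noise, in
any of the three reporting kinds; `make_study_defaults()` encodes the five
printed induction regimens and four response criteria. Fixtures carry a
provenance field marking them synthetic. What passing tests show is that
the *pipeline* — selection, simulation, classification, calibration —
behaves correctly on data with the assumed statistical structure; they
cannot show that the rate laws or priors are the true ones for any real
trial population.

Numerical choices: `lsoda` with `rtol 1e-8 / atol 1e-10` and a raised step
cap (extreme prior draws are stiff); steady states by windowed integration
(400-day windows, relative-rate criterion 10⁻⁷/day, 6,000-day cap, with
non-convergence treated as implausibility); tiny negative concentrations
from the integrator (< 10⁻⁶) are clamped to zero, larger ones are an
error; binding-site forcings are tabulated at 0.25-day resolution with
dose times inserted; assessment days use the nearest grid point within
half a day.

Known limitations, carried over deliberately: no epithelial barrier or
lumen transport (FCP is a serum-equivalent readout of neutrophil
activity), no membrane TNFa or receptor-level signalling, no
target-mediated drug disposition or immunogenicity, no placebo/response
study-design effects, no clinical-score (CDAI) linkage, and per-patient PK
variability is excluded by design. The alternative IL-17 source is a
constant basal term, the simplest mechanism consistent with an
IL-23-independent supply.
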