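# cdqsp — QSP simulation of biomarker response in Crohn's disease

`cdqsp` is a quantitative systems pharmacology (QSP) package for asking a
clinical-pharmacology question that induction trials in Crohn's disease
keep raising: given a therapy's mechanism — anti-TNFα (infliximab),
anti-IL-12p40 (ustekinumab), anti-IL-23p19 (brazikumab, risankizumab), or
anti-IL-6 (PF-04236921) — how should the workhorse inflammation markers,
serum C-reactive protein (CRP, mg/L) and fecal calprotectin (FCP, mg/kg),
move in a patient population, which patients respond under the biomarker
cutoffs trials actually use, and what would a combination of two
mechanisms buy?

It is aimed at pharmacometricians and systems pharmacologists who want a
tested, end-to-end reference implementation of the full workflow:
mechanistic ODE core → antibody PK → target binding → virtual populations
→ trial simulation → responder stratification → calibration.

## The model in brief

A single-compartment immune network of 22 species (11 cell populations,
9 cytokines, CRP, FCP) with three rate-law families: first-order turnover
for every species, Michaelis–Menten activation for every modifier arrow,
and additive basal floors. The canonical axes are wired feed-forward:

* IL-12 → Th1 → IFNγ;  IL-23 (+ IL-6) → Th17 → IL-17, IL-22
* TNFα activates dendritic cells, macrophages and neutrophils
  (co-activated by IL-6, IFNγ and IL-17 respectively)
* activated innate cells produce TNFα, IL-6, IL-8, IL-12, IL-23, GM-CSF;
  TNFα and IL-17 amplify IL-6 production
* CRP = Hill(IL-6); FCP = activated neutrophils × Hill(IL-8)

Production gains are derived in closed form so that a stated
moderate-to-severe disease baseline (CRP 10 mg/L, FCP 600 mg/kg, TNFα
15 pg/mL, …) is an *exact* fixed point of the network
(`nominal_parameters()`, `nominal_state()`, `rederive_gains()`).

Drugs enter as closed-form two-compartment PK (IV bolus / SC absorption,
dose superposition, mg/kg resolved at 70 kg) coupled through
quasi-equilibrium binding: the free fraction of a targeted cytokine solves
L² + (K_d + B − T)L − K_d·T = 0 with B the antibody binding-site
concentration, and every modifier arrow uses free, not total, cytokine.
Virtual patients are log-uniform (±10-fold) multipliers on a 15-parameter
variability subset, filtered to a plausibility window at steady state, and
matched to a trial's reported baseline statistics (median+IQR, mean+SD, or
median+range) by importance resampling.

## Worked example

Generate a 300-patient cohort, simulate the infliximab and ustekinumab
induction regimens, and stratify responders at the ≥ 60 % week-6 CRP
decrease cutoff:

```r
library(cdqsp)

co   <- generate_cohort(300, seed = 7)
defs <- make_study_defaults()          # printed regimens + criteria
spec <- trial_spec()                   # 84-day horizon, weekly grid

armI <- simulate_arm(co, list(defs$regimens$infliximab_5mgkg), spec)
armU <- simulate_arm(co, list(defs$regimens$ustekinumab_6mgkg), spec)

arm_summary(armI, "CRP", "percent_change")[c(1, 3, 7, 13), 1:4]
#>    time median    q1    q3
#> 1     0    0.0   0.0   0.0
#> 3    14  -48.6 -66.6 -19.5
#> 7    42  -51.8 -71.2 -21.7
#> 13   84  -51.7 -71.0 -21.2

classify_responders(armI, armU, defs$criteria$crp_pct60)
#> Responder partition (CRP percent_decrease 60 at day 42): both 0.3%,
#> only_A 41.0%, only_B 2.0%, neither 56.7%
#> (300 included, 0 excluded at baseline)
```

Reading this: infliximab cuts the median patient's CRP roughly in half
within two weeks and the effect plateaus under continued dosing, with a
wide interquartile spread that is purely mechanistic (every patient sees
the identical drug exposure). At the ≥ 60 % cutoff about 40 % of this
cohort responds to infliximab, almost none to ustekinumab alone — the
anti-TNFα axis reaches CRP directly through IL-6 production, while the
IL-12p40 axis must act through the IFNγ/IL-17 co-activation arms.

The `analysis/` directory holds the numbered drivers for the full study:
`01_build_population.R` (plausible cohort + trial matching),
`02_calibrate.R` (anti-IL-6 dose-response calibration),
`03_single_therapies.R`, `04_responders.R`, `05_combination.R`. Each
writes its tables under `results/`.

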