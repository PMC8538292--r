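---
title: "The ustekinumab QE-TMDD / calprotectin turnover model and its simulation engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ustekinumab QE-TMDD / calprotectin turnover model and its simulation engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ustekisim` simulates ustekinumab pharmacokinetics and fecal-calprotectin
(FC) dynamics in Crohn's disease under alternative dosing strategies. This
vignette is the package's account of the model, the assumptions behind the
virtual population, the numerical choices, and what the simulations can and
cannot say.

## The model

Ustekinumab binds the p40 subunit shared by IL-12 and IL-23. The p40 target
was never measured in the underlying cohort; it is a latent variable whose
disposition and binding parameters were estimated jointly with the drug PK.
The package implements the final estimated structure:

* **Drug disposition.** Two-compartment linear kinetics (central volume
  $V_c = 3.57$ L, peripheral $V_p = 3.30$ L, intercompartmental clearance
  $Q = 1.89$ L/day, linear clearance $CL = 0.277$ L/day) with first-order
  subcutaneous absorption ($k_a = 0.381$ day$^{-1}$) and an absorbed
  fraction $F$ of 88.8% in *FCGR3A* rs396991 V/V homozygotes and 71.0%
  otherwise. IV induction doses are infused over exactly one hour.
* **Target disposition.** Zero-order synthesis $K_{syn}$ and first-order
  degradation $K_{deg}$ in a central target compartment ($V_{c,t} = 2.44$ L)
  exchanging with a peripheral compartment ($V_{p,t} = 11.0$ L,
  $Q_t = 0.493$ L/day). The estimated $K_{deg} = 9.26\times10^{-10}$
  day$^{-1}$ and $K_{int} = 2.83\times10^{-6}$ day$^{-1}$ are so small that
  target turnover is negligible on the 32-week horizon; the operative
  quantity is the baseline concentration $R_0 = K_{syn}/K_{deg} \approx
  10.65$ nmol/L, and the apparent target-mediated elimination of drug is
  driven by redistribution of peripheral target into serum.
* **Binding.** Quasi-equilibrium (QE) in the central compartment with
  $K_d = 0.168$ nmol/L: the states carry the *total* central drug and target
  concentrations, and free concentrations are recovered at every solver step
  from the positive root of
  $C = \tfrac12[(C_{tot}-R_{tot}-K_d) + \sqrt{(C_{tot}-R_{tot}-K_d)^2 +
  4K_dC_{tot}}]$. The drug-target complex is internalized at $K_{int}$.
* **FC turnover.** An indirect-response model in which the *free target*
  stimulates FC production:
  $dFC/dt = K_{in}\,(1 + E_{max}R/(C_{50}+R)) - K_{out}FC$, with
  $K_{in} = FC_0 K_{out} / (1 + E_{max}R_0/(C_{50}+R_0))$ so the drug-free
  state is stationary. $K_{out} = 0.0581$ day$^{-1}$, $C_{50} = 2.46$
  nmol/L, and baseline FC is 213 mg/kg with endoscopic ulcers at baseline
  and 102 mg/kg without. The published $E_{max}$ of 219% is implemented as
  the dimensionless factor 2.19; that reading is what makes the baseline
  identity $dFC/dt = 0$ at $(R_0, FC_0)$ hold exactly.

Doses are converted to nanomoles at a molecular weight of 149 kDa, and
concentrations are reported both in nmol/L and µg/mL (1 nmol/L = 0.149
µg/mL).

### Bookkeeping with two central volumes

Drug and target have separately estimated central volumes (3.57 L vs
2.44 L). The model is therefore defined at the *concentration* level: the QE
quadratic and the $K_{int}$ terms act on central concentrations directly,
and volumes enter only in dose scaling and in the distribution fluxes. This
is the standard convention for TMDD models with a separately estimated
target volume; a strict cross-species molar mass balance between the two
compartments is not enforced, and the underlying report does not state how
this was reconciled in the original estimation software. The
concentration-level convention is one consistent reading, and all published
simulation results are reproduced under it.

## Covariate model and variability

Individual parameters come from the published covariate equations,

$$CL = 0.277\,(FFM/45)^{0.598}\,(1 - 0.0165(ALB - 43))\,(1 - 0.227\cdot
\text{bio-naive}),$$

$V_c = 3.57 (FFM/45)^{0.590}$, $V_p = 3.30 (FFM/45)^{0.586}$ and
$K_{syn} = 9.86\times10^{-9}(1 + 0.0846(CRP-3))$, with fat-free mass from
the Janmahasatian equations. Random effects are exponential on CL, $V_c$,
$V_p$, $K_{syn}$ and $FC_0$, and additive on the logit of $F$ (SD 0.173);
no covariances were reported, so effects are sampled independently.

The reported IIV magnitudes are CV percentages. Whether they were meant as
true CVs or as log-scale SDs is immaterial below ~30% but diverges at the
~99% magnitudes on $K_{syn}$ and $FC_0$. The default reading
(`scale = "cv-derived"`) uses $\omega = \sqrt{\ln(1+CV^2)}$ so the sampled
parameter's CV equals the published number; `"direct-sd"` uses the CV as the
log-scale SD. The switch is exposed on `sample_random_effects()` and
`run_config()`.

## The virtual population

`population_spec()` encodes a cohort emulating the study population's
baseline summaries: 56% women; weight log-normal with median 70 kg and IQR
59--84 kg (log-SD $\ln(84/59)/(2 \times 0.6745) \approx 0.262$ derived from
the IQR); height normal within sex (women 164 ± 6 cm, men 178 ± 7 cm,
chosen so the pooled median and IQR sit near 169 and 163--179 cm); albumin
normal 43 ± 2.2 g/L truncated to 30--55; 33.3% bio-naive; 8.8% rs396991
V/V; 77.2% with endoscopically active disease. Fat-free mass is always
derived from weight/height/sex, never sampled, so its median (~45 kg)
emerges from the anthropometric marginals.

Two published irregularities required decisions:

* The CRP summary (median 3, IQR 3--11 mg/L) has its lower quartile equal to
  the median, impossible for a continuous law. It is modeled as left
  censoring at the 3 mg/L assay floor: CRP is log-normal with median at 3
  and 75th percentile 11, reported as `max(3, value)` and capped at
  150 mg/L. Roughly half the virtual patients sit exactly at the floor.
* The study says the virtual population preserved the covariates'
  correlations but prints none. Continuous marginals are coupled through a
  Gaussian copula with assumed physiological defaults (weight--height 0.4,
  albumin--CRP $-0.3$, all others 0), fully configurable. The acceptance
  tolerances on cohort-level results reflect that these are assumptions.

The rs396991 allele mapping takes the C allele as V, pairing V/V with the
rarest printed genotype (8.8%).

What the generator does *not* emulate: joint tails beyond the Gaussian
copula, site-specific assay behaviour, longitudinal covariate change, and
any real-patient identifiability. Passing tests therefore demonstrate
fidelity to the published *marginal summaries*, not to the real cohort.

## Dosing scenarios and remission

Induction is weight-banded (260 mg at or below 55 kg, 390 mg above 55 up to
and including 85 kg -- the bands read as left-open/right-closed -- and
520 mg above). Six strategies are implemented (`build_schedule()`):
standard q8w maintenance (a); q4w maintenance from week 4 (b); repeated IV
induction q8w (c); and three week-16 response-adaptive rules (d--f) in
which non-remitters switch to q4w SC from week 20 (d), receive an IV
reinduction at week 16 and continue q8w (e), or both (f).

Biochemical remission is model-predicted FC strictly below 100 mg/kg at the
assessment day; remission proportions follow the study convention of being
computed on the endoscopically active subgroup. Classification uses the
individual prediction without residual error by default; the 57.3%
proportional FC error can be switched on (`remission_with_ruv`), and with it
the week-32 proportions move by only a few percentage points because the
error is symmetric around the prediction.

Conventions the source does not state, fixed here:

* Week-16 remission for the adaptive arms is read *pre-dose* at day 112
  from the standard-schedule simulation; a dose given at an assessment day
  is administered after the read-out (an SC dose only fills the depot and
  an IV infusion starts at that instant, so neither can affect it).
* The week-16 reinduction in (e)/(f) *replaces* the week-16 SC dose rather
  than adding to it.
* In (e), q8w maintenance resumes 8 weeks after the reinduction (weeks 24,
  32, ...), which coincides with the original calendar.
* Maintenance doses are placed at every interval multiple up to and
  including the horizon; trailing doses are inert for all reported
  outcomes.

The residual-error model (`add_residual_error()`) -- combined
additive/proportional for drug, proportional for FC -- exists to export
synthetic observation datasets and is never used in the scenario engine's
classification by default.

## Numerics

* **QE root.** The quadratic is evaluated in a cancellation-free form
  (conjugate expression when $R_{tot}+K_d \ge C_{tot}$, and the complex
  taken from the smaller total), keeping the identity
  $K_d \cdot \text{complex} = C \cdot R$ below $10^{-9}$ relative error over
  ten decades of concentration.
* **Integration.** `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`,
  restarted at every dose time and infusion boundary so events are exact in
  time; overlapping infusions sum their rates. The QE closure removes the
  fast binding timescale, so the system is non-stiff and lsoda stays in its
  Adams mode.
* **Cohort stacking.** `simulate_cohort()` integrates all subjects as one
  stacked system (6 states per subject). Protocolised dosing means all
  subjects share event times, so one solver pass serves the whole cohort;
  a property test pins the stacked path to per-subject integration. A
  2,000--3,000-subject scenario over 32--48 weeks runs in roughly ten
  seconds.
* **State guards.** The right-hand side aborts if any state falls below
  $-10^{-6}$; reported series clip the harmless sub-tolerance negatives at
  zero.
* **Verification oracles.** The test suite checks the integrator against a
  closed-form (eigenvalue) two-compartment solution in the linear limit
  ($K_{syn}=0$, no target) to 0.1%, and checks the QE approximation against
  a full kinetic-binding TMDD model ($k_{off} = 1000$ day$^{-1}$,
  $k_{on} = k_{off}/K_d$) to 1% beyond 0.1 day after each dose. Least-squares
  refitting of $(CL, V_c, Q, V_p)$ from a noiseless linear-limit profile
  recovers the generating values within 1%.

## Problem sizes and reproduction

The published study simulated 10,000 virtual patients. The package defaults
to that size, while the test suite and the reproduction script
(`scripts/acceptance.R`) use cohorts of 2,000--3,000, our chosen desk-scale
size: the binomial Monte-Carlo standard error of a remission proportion at
$n \approx 2{,}300$ evaluable subjects is about one percentage point, well
inside the differences of interest. The script regenerates the population,
runs scenarios (a)--(d) and (f), the typical-patient half-life (log-linear
slope over days 42--84 after a single 390 mg infusion), and the week-48
pre-dose trough medians under q8w and q4w maintenance -- the trough week is
our choice of "steady state", more than four terminal half-lives into
maintenance; troughs are PK-only summaries and are taken over the full
cohort.

## Limitations

No parameter estimation is performed: the population parameters are inputs,
and their uncertainty (bootstrap CIs) is not propagated, so simulation
spread reflects IIV only. The target is latent and its absolute scale is
model-defined. Remission proportions inherit every assumption above --
especially the unpublished covariate correlations and the FC threshold's
assay dependence -- and should be read as reproductions of a model-based
simulation, not as clinical effect estimates.
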