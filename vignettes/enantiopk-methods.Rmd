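---
title: "Methods: a two-enantiomer disposition model with systemic chiral inversion"
author: "enantiopk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-enantiomer disposition model with systemic chiral inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enantiopk)
```

## The model

Racemic ibuprofen is a 50/50 mixture of two enantiomers. Only S-ibuprofen
is pharmacologically active, but the body converts R-ibuprofen to
S-ibuprofen systemically and unidirectionally. `enantiopk` models each
enantiomer as its own one-compartment system, coupled by an inversion
clearance:

$$
\frac{dA_R}{dt} = -\frac{Cl_R}{V_R} A_R, \qquad
\frac{dA_S}{dt} = \frac{Cl_{R \to S}}{V_R} A_R - \frac{Cl_S}{V_S} A_S,
$$

with amounts per kg body weight, $C = A/V$, and an IV bolus starting both
amounts at half the racemic dose (each enantiomer receives $D/2$). The R
curve is mono-exponential; the S curve is bi-exponential, the second term
being the inversion input. Oral dosing adds a first-order depot per
enantiomer with rate $k_a$ and bioavailability $F$; the S solution is then
tri-exponential. The model is linear, so multiple-dose regimens are
superpositions of single-dose solutions.

Assumptions worth stating explicitly:

* inversion is strictly R-to-S (no back-conversion), with first-order
  (non-saturable) kinetics;
* $Cl_R$ is **total** R clearance, inversion included, so clearance to
  other routes is $Cl_R - Cl_{R \to S}$ and the structural constraint is
  $0 \le Cl_{R \to S} \le Cl_R$. This convention is the one consistent
  with the published group values: the reported inversion clearances are
  below the reported total R clearances in all four age groups, and
  $\ln 2 \cdot V_R / Cl_R$ reproduces the reported R half-lives (e.g.
  21.6 vs 22.6 min in one-week piglets), which the additive reading does
  not. A constructor switch (`convention = "additive"`) is provided for
  sensitivity analysis;
* no absorption lag time, and enantiomer-specific $k_a$ (separate R and S
  absorption rate constants are reported, so separate constants are
  estimated);
* protein binding and its maturation are not modelled explicitly; they
  are absorbed into the apparent volumes.

Units are fixed package-wide: minutes, mL/kg, mL/(min·kg), µg/mL; doses
are mg/kg of the racemate and converted internally to µg/kg. All
parameters are weight-normalised; whole-body values (mL/min, mL) are
formed only in the allometry/reporting layer via `whole_body()`.

## Numerical evaluation

Closed forms are built from two convolution kernels,
$\int_0^t e^{-\lambda u} e^{-k(t-u)} du$ and its second convolution with a
third exponential. Both are evaluated with `expm1`-based branches so that
nearly equal rate constants do not cancel catastrophically; below a rate
difference of $10^{-9}\,\text{min}^{-1}$ the code switches to the exact
$t e^{-kt}$ (and $\tfrac{1}{2} t^2 e^{-kt}$) limiting forms. An
independent numerical integrator (`simulate_ode()`, a stiff-capable
solver at tolerance $10^{-12}$) implements the same dosing semantics and
serves as the oracle: the test suite checks sup-norm relative agreement
of $10^{-8}$ or better across randomized parameter draws spanning the
published range.

## Estimation

Estimation is per subject ("two-stage": fit each pig, then summarise),
with bounded Levenberg–Marquardt least squares on log-transformed
positive parameters and proportional ($1/\hat{y}$) weighting, because
concentrations span orders of magnitude within a profile. Initial values
come from non-compartmental quantities ($V \approx D/C_\text{first}$,
$Cl \approx D/\text{AUC}_{0\to\infty}$), with three deterministic
jittered restarts on non-convergence. Observations below the limit of
quantification (0.25 µg/mL) are excluded before fitting; "below" is
strict, a value exactly at the LOQ is retained.

The scheme is sequential, mirroring the study design:

1. **IV stage** — `fit_iv_enantiomers()` jointly estimates $V_R$, $Cl_R$,
   $Cl_{R \to S}$, $V_S$, $Cl_S$ from both enantiomer curves. The
   inversion clearance is parameterised as a fraction of $Cl_R$, which
   enforces the structural constraint by construction.
2. **Oral stage** — `fit_oral_enantiomers()` freezes the IV-estimated
   inversion clearance (the value is carried into the result
   bit-identically) and estimates $k_{a,R}$, $k_{a,S}$, $F_R$, $F_S$.
   $F$ is deliberately not clipped at 1: per-subject estimates above
   100% occur and are reported as such.

By default the oral stage also freezes $V$ and $Cl$ at their IV
estimates. This was a genuinely open design choice, and the deciding
argument is identifiability: scaling $V$, $Cl$ and $F$ of an enantiomer
by a common factor leaves both predicted oral curves unchanged (the
elimination rate $Cl/V$ and the inversion input
$Cl_{R \to S} A_R / V_R$ are invariant), so re-estimating $V$/$Cl$
jointly with $F$ from oral data alone is structurally unidentifiable.
The `refit_vcl = TRUE` switch exists but is documented as
ill-conditioned.

Total-drug (R+S) profiles are fitted with a standard one-compartment
model (`fit_total_one_compartment()`), using the full racemic dose.

## Non-compartmental analysis

`auc_lin_up_log_down()` implements the linear-up/log-down trapezoid: a
segment uses the linear rule when concentration is non-decreasing or
either endpoint is zero, and the logarithmic rule
$(C_i - C_{i+1})\Delta t / \ln(C_i/C_{i+1})$ otherwise. Truncation times
inside a segment are interpolated with that segment's own rule; the
0–3 h AUC therefore lands on exactly 180 min whether or not a sample
falls there (on the study grids this is a no-op). No extrapolation
beyond the last sample is performed by the AUC itself;
`terminal_lambda_z()` adds $C_\text{last}/\lambda_z$ for
$\text{AUC}_{0\to\infty}$. The terminal slope window is chosen among the
last 3–6 strictly positive samples (never including $T_\text{max}$) by
best adjusted $R^2$ — an explicit convention where common NCA software
leaves the choice to defaults. Absolute bioavailability is the
per-subject dose-normalised ratio of 0–3 h AUCs (oral over IV), and the
accumulation ratio is $\text{AUC}_{0\to 6h}$ after dose 13 over that
after dose 1.

Two further conventions: for IV-bolus NCA the blank pre-dose sample is
replaced by a log-linearly back-extrapolated $C_0$ (otherwise the 0–5 min
area, the largest slice of a bolus profile, would be silently dropped
once the zero is excluded as BLQ); and the pre-dose concentration of the
dose-13 profile is retained as that profile's $t = 0$ value — the
superposed baseline is not subtracted.

## Renal markers and allometry

Glomerular filtration rate is the plasma clearance of iohexol
(64.7 mg/kg bolus) from a two-compartment fit
($Cl = D/(A/\alpha + B/\beta)$, with the rates parameterised as
$\beta$ and $\alpha - \beta > 0$ so the phases can never invert), and
estimated renal plasma flow is the clearance of p-aminohippuric acid
(10 mg/kg) from a one-compartment fit. The iohexol fit carries
physiologic bounds ($C_0 = A + B$ may not exceed the dose over a 20 mL/kg
minimal plasma volume): without them a noisy profile can absorb unbounded
area into an unobserved ultra-fast phase before the first 5-min sample
and drive the clearance estimate toward zero.

Allometric relationships are ordinary least squares of $\ln y$ on
$\ln x$; the slope is the allometric coefficient. Both an
individual-subject mode and a group-mean mode are supported. The
group-mean mode (`reference_allometry()`) regresses whole-body
total-drug clearance — per-kg group mean times mean body weight, using
138 kg for the 6–7-month group (midpoint of the 134 kg male and 142 kg
female sub-cohorts) — on body weight and reproduces the published
coefficient of 0.97. The distribution-volume and enantiomer-specific
coefficients were derived from individual animals, which are not
recoverable from group summaries, so the group-mean mode is not expected
to reproduce them exactly.

## The synthetic cohort

No individual animal data were deposited, so the package carries a
generator (`draw_subjects()`, `simulate_cohort()`) that emulates the
study design: four age groups (1, 4, 8 weeks, 6–7 months), 8 treated
pigs each (4 male/4 female), a single 5 mg/kg IV bolus, then 5 mg/kg
orally three times daily (0/360/720 min of a 1440-min day, a 12-h
overnight gap) for five days, rich sampling on the IV day and after oral
doses 1 and 13, marker profiles on two occasions, and LOQ censoring at
0.25 µg/mL.

Choices a reader should know about:

* **Between-subject variability** is log-normal per parameter, moment-
  matched to the published arithmetic mean (SD) summaries — the study
  reports arithmetic summaries only, so matching them is a documented
  choice, not the only possible one.
* $\log Cl_R$ and $\log Cl_{R \to S}$ are drawn with correlation 0.98
  (inversion is the dominant component of R clearance in piglets, so
  near-proportional variation is the physiologically coherent reading),
  and the rare draw violating $Cl_{R \to S} < Cl_R$ is rejected and
  redrawn. At this correlation rejections are about 1% and the marginal
  moments stay matched; at low correlations the rejection step would
  visibly bias the $Cl_R$ marginal.
* **Residual error** is $y = \hat{y}(1 + \varepsilon_p) + \varepsilon_a$
  with defaults 10% proportional and 0.05 µg/mL additive, floored at
  zero — assumed values; the study reports analytical precision, not
  residual PK error magnitude.
* **Renal marker generating values** (GFR 2.0/3.5/4.5/2.0 mL/(min·kg)
  across the age groups, eRPF about four times GFR, and the marker
  volumes) are synthetic defaults chosen to be physiologically plausible
  for growing pigs and to follow the reported qualitative pattern (both
  lower in the oldest animals); no marker parameter table was published.
* **Sex** is a label only; no sex effect is generated by default.

What the generator does *not* emulate: model misspecification (real pigs
are not a one-compartment system), absorption irregularities (gastric
emptying, fed-state effects beyond the flag), correlated residual
errors, drop-out, or saturable inversion. Passing recovery tests on this
cohort therefore demonstrates that the estimation machinery is correct
and well-conditioned at the study's design and noise level — not that
the model is an adequate description of any particular real dataset.

## What the recovery experiments show

With the defaults above, 20 replicate cohorts (problem size chosen to
keep the full experiment in the tens of seconds: 20 × 32 subjects, IV
occasion) recover every structural parameter's group mean with bias well
inside 15%. The *ranking* of the inversion clearance across age groups
is a harder target: the generating means of the 4- and 8-week groups
(4.6 vs 3.9 mL/(min·kg)) sit less than one between-subject SD apart, so
with n = 8 per group the sampling error of a group-mean difference
(about 0.6 mL/(min·kg)) flips that pair in a substantial minority of
replicates — the full strict ordering reproduces in roughly 75–80% of
replicates, not near-always. This is a property of the design (group
size and variability), not of the estimator; the package reports the
ordering fraction rather than pretending the ranking is deterministic.

## Degenerate inputs and edge behaviour

* Equal elimination rates, or $k_a$ equal to an elimination rate, use
  limiting forms — handled, never an error.
* Zero bioavailability gives identically zero curves; very fast
  absorption converges to the F-scaled bolus curve.
* Non-positive parameters, non-increasing dose times, mismatched curve
  grids, and totally zero profiles are rejected with named validation
  errors.
* Non-convergence of a fit is flagged in the result, not thrown;
  profiles with fewer usable observations than the fit's stated minimum
  (six per enantiomer for the IV fit) are rejected, which in a censored
  one-week cohort occasionally drops a fast-clearing subject.
* Fewer than three positive terminal points, or a non-negative terminal
  slope, flag the λ~z~-dependent NCA outputs as missing rather than
  erroring.

## A small worked run

```{r pipeline, eval = FALSE}
spec <- cohort_spec(n_per_group = 4)
res <- run_pipeline(seed = 1, spec = spec,
                    occasions = c("iv", "po_dose1"))
res$summaries$iv
res$allometry$cl_bw
```

The pipeline runs the stages in the study's order (IV fits, then oral
fits with frozen inversion, then NCA, markers, summaries, allometry) and
is bit-reproducible given the seed; all randomness flows from that one
integer.
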