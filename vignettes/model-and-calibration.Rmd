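---
title: "The ALK test-and-treat cost-effectiveness model and its calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ALK test-and-treat cost-effectiveness model and its calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alkcea)
```

## The decision problem

About 6.5% of advanced non-small-cell lung cancers (NSCLC) in China carry an
ALK rearrangement and respond dramatically to crizotinib, but crizotinib is
expensive and only helps that subgroup. The policy question this package
models: is it worth testing everyone (with an NGS panel at \$1,014.49 or a
multiplex PCR assay at \$660.75 per patient) and treating test-positives with
crizotinib, compared with giving everyone standard pemetrexed–cisplatin (PC)
chemotherapy? Costs are 2016 US dollars from the Chinese healthcare system
perspective, health is measured in quality-adjusted life-years (QALYs), and
the willingness-to-pay threshold is \$32,000/QALY. Because crizotinib's
affordability in China hinges on its patient assistance program (PAP), every
comparison is run with and without PAP.

## Model structure

Each strategy is expanded by a decision tree into test-outcome subcohorts:
with prevalence $\pi$, sensitivity $se$ and specificity $sp$, the weights
are $TP = \pi\,se$, $FN = \pi(1-se)$, $TN = (1-\pi)sp$,
$FP = (1-\pi)(1-sp)$. TP and FP patients receive crizotinib (and its
costs); FN, TN and untested control patients receive chemotherapy. FP
patients gain nothing clinically from crizotinib: they follow a
supportive-care progression curve obtained from the chemotherapy curve via
the proportional-hazards transform $S^{1/0.77}$ (0.77 being the published
chemotherapy-vs-supportive-care hazard ratio, repurposed here as the only
quantitative link the source provides — an assumption worth remembering
when interpreting specificity sensitivity analyses).

Each subcohort then runs through a three-state Markov cohort
(progression-free → progressed → dead):

* Progression follows a Weibull curve $S(t) = \exp(-\lambda t^{\gamma})$
  fitted to digitized trial PFS: crizotinib $(\lambda, \gamma) =
  (0.0211, 1.5326)$, PC $(0.0663, 0.8604)$. Per-cycle probabilities are
  time-dependent hazard increments, so the cohort's progression-free
  fraction reproduces the curve exactly (the telescoping identity is
  property-tested).
* Progressed patients die with a constant per-cycle probability of 0.086,
  the value implied by the published 5.4-month median post-progression
  survival under 21-day cycles and 30-day months
  (`cycle_prob_from_median(5.4, 21, 30)`). Patients who progress during a
  cycle spend on average half of it in the progressed state, so half of
  the same-cycle arrivals are exposed to that cycle's death hazard.
* Costs: chemotherapy patients pay pemetrexed (500 mg/m² at the 1.72 m²
  reference body surface area, billed per whole 500-mg vial — the Chinese
  hospital charging convention; proportional billing is a config switch),
  backbone chemotherapy and SAE management for at most four cycles, plus
  routine follow-up while progression-free. Crizotinib patients pay
  \$238.1/day while progression-free — all of it without PAP, only the
  first `paid_days` of it with PAP (see calibration). Progressed patients
  receive salvage chemotherapy at the published 56.6% uptake for a limited
  number of cycles and supportive care otherwise; the terminal palliative
  cost is attached to the death transition. Utilities are 0.804
  (progression-free) and 0.321 (progressed); SAE disutilities are shown
  only graphically in the source, so they ship as configurable decrements
  defaulting to zero. Everything is discounted at 5%/year over a 10-year
  horizon; a half-cycle correction flag exists but is off by default, as
  the source is silent on it.

## What the source leaves open, and how calibration resolves it

Four conventions are under-specified, and the printed base-case table is
not jointly reproducible from the printed inputs under any single guess:

* **Curve time units.** The printed Weibull pairs imply a *longer* median
  PFS for chemotherapy (15.3) than for crizotinib (9.8) in any shared
  unit, contradicting the trial result the source cites (10.9 vs 7.0
  months). The package therefore treats the unit of each curve as
  configurable and never silently "fixes" either printed number
  (`recalibrate_scale()` exists as an explicit escape hatch).
* **Cycle length.** Chemotherapy is administered in 21-day cycles, but the
  printed progressed-state life-years are more consistent with longer
  cycles under the printed 0.086 death probability.
* **Salvage duration** is unstated.
* **The PAP contract** is described only in a companion publication; it is
  modelled as "payer funds the first `paid_days` of crizotinib, free
  thereafter".

`calibrate_conventions()` grid-searches these (cycle length 21–33 days,
week/month units per curve, 4–20 salvage cycles, 0–126 PAP paid days)
against the seven published base-case quantities, scoring by the largest
absolute relative error (with the mean as tie-break) — the natural
objective when the reproduction gate is "within x% on each quantity".
The shipped defaults are the winner: **25-day cycles, chemotherapy curve
in weeks, crizotinib curve in months, 12 salvage cycles, 84 PAP-paid
days**; the ranked report is committed at
`inst/calibration/calibration_report.csv` and regenerated by
`scripts/calibrate.R`. At these settings every published base-case
quantity is matched within 14% (most much closer); the residual gap is
irreducible because the published incremental QALY gain (0.040 at 6.5%
prevalence, i.e. 0.615 QALYs per ALK-positive patient) would require a
crizotinib mean PFS of roughly 16 months, which no reading of the printed
crizotinib curve reaches.

One further convention was *derived* from the published table rather than
assumed: the NGS and PCR arm costs differ by only ~\$26 although the test
costs differ by \$353.74, and \$353.74 × 0.065 ≈ \$23 — the source
evidently accrued the test cost within the ALK-positive (treated)
subcohort. `test_cost_policy` makes this explicit: `"positives"` (the
shipped default, reproducing the published totals) or `"all"` (the
textbook convention of charging every tested patient). Decision-tree
identities such as "zero-prevalence strategy = control + test cost" hold
under `"all"` and are tested there.

```{r base-case}
run_cea(default_parameters(pap = TRUE))
run_cea(default_parameters(pap = FALSE))
```

## Sensitivity analysis machinery

One-way analysis (`one_way()`, `tornado()`) re-evaluates the ICER at each
parameter's published range bounds (crizotinib at half price per the
source's footnote; the discount rate over 0–8%, an assumed range since
none is printed), never mutating the input bundle. The probabilistic
analysis (`run_psa()`) draws every non-fixed parameter per draw:

* **Triangular** (mode = base, bounds = range) for ranged costs and body
  surface area. Note the published pemetrexed range (857.14–2126.51
  around 2083.97) is strongly left-skewed, so its triangular *mean* is
  well below the base case — visible as the dominant driver of PSA
  spread.
* **Beta** (method of moments, mean = base, sd = range/4) for
  probabilities, proportions and utilities. The progression-free utility's
  +25% bound is truncated at the ceiling of 1.
* **Boundary-mode beta** for test sensitivity/specificity, whose base of 1
  admits no mean-parameterized beta: the published 0.95–1 *confidence
  interval* is honoured by $\mathrm{Beta}(\alpha, 1)$ with
  $\alpha = \ln(0.025)/\ln(0.95) \approx 71.9$, i.e. mode 1 and 2.5% mass
  below 0.95. (A mean-at-boundary case that is not a stated interval
  falls back to uniform on the range, with a message;
  `sample_beta_from_range()` itself warns and falls back to uniform when
  the implied moments admit no beta.)
* **Fixed**: the crizotinib daily price (scenario-analysed via the PAP
  switch and the half-price one-way case), the Weibull parameters (no
  published ranges) and the discount rate.

All strategies are evaluated on the same draw (common random parameters);
output is reproducible from `(seed, n)`. `ceac()` computes acceptability
curves from net monetary benefit, and `psa_quadrants()` the incremental
scatter quadrants. A 1,000-draw run reports roughly 79–82% acceptability
for both test strategies at \$32,000/QALY with PAP (published: 82.3% and
82.9%) and exactly 0% without PAP.

## The synthetic-data generator

`generate_km_points()` emulates the digitization step that produced the
published Weibull fits: curve evaluation on a time grid with
multiplicative log-normal noise (digitization error scales with curve
height and keeps survival positive), clipped to (0,1) and forced
non-increasing. It generates what the tests need — no real digitized
coordinates ship with the package — so passing tests demonstrate
correctness of the fitting and modelling machinery, not agreement with
the PROFILE 1029 curves themselves. `generate_parameter_bundle()` draws
uniformly within all published ranges for property-style fuzzing of the
engine invariants (occupancy conservation, non-negative accruals).
`fit_weibull()` recovers noise-free input exactly; under noise it uses
weighted least squares in the log-log plane with delta-method weights
$(\ln S)^2$, because constant log-survival noise is amplified as
$1/\ln S$ near $t = 0$ and an unweighted fit lets the earliest,
least-informative points dominate the scale estimate (median scale error
6–18% unweighted vs 1–3% weighted at 2% noise).

## Numerical choices and degenerate inputs

Per-cycle probabilities use the cumulative-hazard increment
$1 - e^{-\lambda((t+\Delta)^\gamma - t^\gamma)}$, stable where $S$ itself
underflows. Trace length is $\lfloor \mathrm{years} \times 365.25 /
\mathrm{cycle\_days}\rfloor$ transition cycles; occupancy is conserved to
$10^{-9}$ and checked. Zero-weight subcohorts are skipped exactly. ICERs
are undefined at zero QALY difference (the cost difference alone is
reported) and dominance is flagged in the standard way. Fits require at
least three points with survival strictly inside (0,1); offending points
are named in the error.

## Problem sizes

The shipped analyses are small by construction: 146 cycles per trace,
up to three traces per strategy, 1,000 PSA draws (a few seconds to a
minute on one core). The test suite runs the full acceptance replication
including two 1,000-draw PSAs.

## Known limitations

* The source's internal inconsistencies mean the base case matches within
  ~14%, not exactly; the calibration report quantifies every residual.
* The HR-based supportive-care curve and the shared chemo curve for
  ALK-positive and ALK-negative patients are structural assumptions
  inherited from the source.
* No background all-cause mortality, no microsimulation, no correlated
  PSA sampling, no EVPI, no currency/inflation adjustment (the source's
  costs are deliberately uninflated).
* PAP is a deterministic pricing rule; its `paid_days` is a calibrated
  stand-in for a contract published elsewhere.
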