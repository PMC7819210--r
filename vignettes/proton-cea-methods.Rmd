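---
title: "Methods: individualized proton-vs-photon cost-effectiveness modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individualized proton-vs-photon cost-effectiveness modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonCEA)
```

## The decision problem

Intensity-modulated proton therapy (IMPT) reduces the dose to organs at
risk relative to photon IMRT in head-and-neck radiotherapy, and therefore
the probability of severe toxicity — but at a much higher upfront cost.
Because the dosimetric benefit varies strongly between patients, the
cost-effectiveness question is individual: for *this* patient, what does
each quality-adjusted life year (QALY) spared by protons cost?

`protonCEA` answers it with a per-patient Monte Carlo model. The inputs
are each patient's normal tissue complication probabilities (NTCP) under
both modalities for five toxicities: dysphagia grade ≥ 2, esophagitis
grade ≥ 3, xerostomia grade ≥ 2, hypothyroidism, and oral mucositis
grade ≥ 3. NTCP modelling itself is out of scope — probabilities arrive
as a cohort table (`read_cohort()`), typically from dose–volume-based
NTCP models evaluated on competing treatment plans.

## Model structure

Each replicate of each patient proceeds in four stages.

**1. Complication events.** Each complication occurs as a Bernoulli draw
at the modality's NTCP. By default one uniform per complication is shared
between modalities (*common random numbers*), so with proton NTCP ≤
photon NTCP the proton events are a subset of the photon events within a
replicate: the comparison is paired, the QALY difference is never
negative, and a replicate with identical events isolates the upfront cost
difference exactly. The paired design is a variance-reduction choice, not
a claim about nature; `event_coupling = "independent"` draws the two
modalities independently for comparison. Dysphagia carries an additional
chronicity flag, Bernoulli(0.5) in the base case (chronic for life vs
resolved within 5 years).

**2. Survival.** An annual discrete-time competing-survival model:
combined survival is background life-table survival times p16-stratified
cancer-specific survival, with the cancer-specific annual hazard
multiplied by a hazard ratio of 1.73 (95% CI 1.17–2.57) for patients
with a > 10 pack-year smoking history. The packaged life table is a
smooth synthetic Gompertz table and the packaged cancer curves are
emulation constants chosen so that p16-positive patients have markedly
longer life expectancy (5-year cancer-specific survival ≈ 0.86 vs ≈ 0.54,
both plateauing thereafter); both are configurable inputs
(`survival_model_spec()`), not estimates of any registry. Horizon: 40
years; ages beyond the life table reuse its last rate.

**3. QALYs.** Discounted life years are
$\sum_{t=1}^{H} S(t)\,(1+r)^{-(t-1)}$ — year 1 undiscounted, the same
convention used for cost annuities so both sides of the ICER are
commensurable. Each complication that occurred multiplies the utility of
the time spent in its health state:

| complication | utility (95% CI) | duration |
|---|---|---|
| dysphagia ≥ 2 | 0.83 (0.70–0.93) | chronic in 50% of cases, else 5 years |
| esophagitis ≥ 3 | 0.66 (0.35–0.90) | acute, 6 weeks in year 1 |
| xerostomia ≥ 2 | 0.82 (0.72–0.90) | chronic lifelong |
| hypothyroidism | 0.97 (0.94–0.98) | chronic lifelong |
| oral mucositis ≥ 3 | 0.06 (0.01–0.15) | acute, 6 weeks in year 1 |

Acute durations sit in year 1 (undiscounted); concurrent states combine
multiplicatively on the utility scale — the standard independence
assumption — with `utility_combination = "additive"` available since the
choice is genuinely open. The mucositis factor 0.06 is strikingly low
relative to the others; it is applied literally as a utility multiplier
over its 6-week window (a 0.94 × 6/52 ≈ 0.108 QALY loss), and because the
spec table is an ordinary input, users who read it as a disutility
decrement can simply supply an edited table.

**4. Costs.** Total cost = upfront radiotherapy cost + management costs
of the complications that occurred. Upfront costs for 33 fractions are
$20,257 (photon) and $36,659 (proton), extrapolated per fraction from
quoted Medicare reimbursements ($18,415/30 fx and $27,772/25 fx); the
extrapolation rounds halves up, since 18,415 × 33/30 = 20,256.5 exactly
and the quoted 33-fraction amount is 20,257. Management bundles (2018
USD) follow the standard of care: drug bundles, IV hydration, PEG tube
placement (30%), emergency-room visits (15% mucositis / 10%
esophagitis), hospitalization (10%), a month of lost work for grade ≥ 3
mucositis/esophagitis; stricture dilation ($1,700, 16%) and a chronic PEG
tube ($18,836/yr, 10%) for dysphagia; lifelong Levothyroxine ($174.2/yr)
for hypothyroidism; sialogogue courses for xerostomia. Lifelong items are
annuities over discounted remaining survival; the chronic-PEG annuity
mirrors the dysphagia duration rule (lifelong when the replicate's
dysphagia is chronic, otherwise capped at 5 years — the source is silent
here, so the cost rule deliberately tracks the QALY rule). Management
proportions enter as expected-cost weights within a replicate (the
literal reading of a "proportion of cases"); `management_mode =
"bernoulli"` instead realizes each management as a within-replicate coin
flip.

**Classification.** Δcost and ΔQALY (proton − photon) classify every
replicate: ΔQALY ≤ 0 → photon dominates (the zero case included, per the
convention that protons must *gain* quality-adjusted time to justify any
extra cost); ΔQALY > 0 with Δcost ≤ 0 → proton dominates; both positive →
trade-off with ICER = Δcost/ΔQALY. Cost-effectiveness at a
willingness-to-pay threshold is inclusive (ICER ≤ threshold). Replicates
with ΔQALY exactly 0 are additionally tallied as "no difference" — under
common random numbers these are exactly the replicates whose event sets
coincide.

## Uncertainty propagation

In `full_psa` mode every uncertain parameter is drawn per replicate:

* **Utilities** — beta distributions fitted so the 2.5th/97.5th
  percentiles match each utility's 95% CI. The fit is a damped Newton
  iteration on (log α, log β) with a finite-difference Jacobian,
  initialized from method-of-moments shapes; it converges to percentile
  residuals below 1e-9 for all packaged CIs, and errors (reporting the
  residuals) rather than returning a poor fit.
* **Management proportions** — normal distributions with mean the CI
  midpoint and sd (high − low)/3.92, truncated to [0, 1]. Truncation is
  by inverse CDF — the exact "resample" distribution obtained with a
  single uniform per draw, which keeps random-number streams aligned
  across scenarios (`truncnorm_mode = "clip"` gives the point-mass-at-
  bounds alternative). The hospitalization proportion is a single shared
  parameter for mucositis-or-esophagitis; the two emergency-room
  proportions are distinct. The stricture-dilation *amount* is likewise
  sampled from its $1,200–$2,200 range.
* **Smoking hazard ratio** — sampled on the log scale: the normal on
  log HR matched to the CI has median √(1.17 × 2.57) = 1.734, which
  reproduces the stated base case 1.73 to printed precision, whereas an
  arithmetic-scale normal would center at 1.87. That consistency is why
  log scale is the default; `hr_scale = "linear"` preserves the literal
  normal reading (truncated to positive values).

Degenerate inputs collapse cleanly: a CI of zero width yields a constant
equal to its base value, so `full_psa` with all CIs collapsed reproduces
`base_case` draws bit-for-bit (a tested invariant). Base-case mode fixes
parameters at their base values but keeps event sampling — the
complication lottery is the model, not a nuisance parameter.

## Random-number discipline

Every patient gets a dedicated substream seeded from the master seed and
a hash of the patient id, so cohort order cannot change results. Within a
substream the draw order is fixed (events → chronicity → optional
management coins → utilities → hazard ratio → proportions → amounts) and
all distribution draws are inverse-CDF transforms of those uniforms.
Consequences, all property-tested: a fixed seed reproduces the sample
table byte-identically through the file layer; one-way scenarios share
every draw with the base case, so varying the proton upfront cost or the
chronicity proportion perturbs only what depends on it (a patient with
zero dysphagia NTCP is bit-identical across chronicity scenarios).

## The synthetic cohort generator

No per-patient NTCP data are published for the kind of cohort this
analysis targets, so `generate_cohort()` emulates the assumed structure:
33 patients, 21 with bilateral comprehensive nodal irradiation and 12
unilateral; photon NTCP drawn uniformly from per-complication ranges that
are higher for the bilateral stratum (`default_ntcp_ranges()`); proton
NTCP = photon NTCP × a uniform relative risk on (0.2, 0.7), so the
generator contract `p_proton ≤ p_photon` holds by construction (the
*loader* does not enforce it — user cohorts where protons are worse for
some endpoint are accepted with a warning). Ages are uniform 45–75, 55%
p16-positive, 40% heavy smokers — arbitrary emulation constants that only
enter through the survival model.

The unilateral ranges are low enough that, under the default analysis,
roughly half of unilateral replicates show no complication difference and
hence zero QALY difference — qualitatively reproducing the reported
behaviour of unilateral patients in this literature (a substantial
no-benefit fraction), without being fitted to any published figure. What
the generator does *not* emulate: correlation of NTCPs across
complications within a patient (real dose distributions induce strong
positive correlation), per-patient dosimetric detail, and any calibration
of absolute NTCP levels to a real institution. Passing tests on synthetic
cohorts therefore validate the *engine* — classification logic,
discounting, distribution fits, determinism, monotonicities — not the
clinical magnitude of ICERs, which is entirely cohort-specific.

## Reporting conventions

The headline summary is the median (and IQR) of per-sample ICERs among
trade-off replicates, pooled over all patients × replicates. Because
several pooling conventions coexist, the summary also emits the
ratio-of-means ICER (mean Δcost / mean ΔQALY) and the median of
per-patient medians. Non-trade-off replicates are excluded from ICER
quantiles (not coded as infinities); they are reported through the
dominance fractions instead. The acceptability curve (`ceac()`) is
non-decreasing in the threshold and bounded between the proton-dominant
fraction and one minus the photon-dominant fraction — both tested
invariants. `report_threshold_grid()` arranges threshold × proton-cost
acceptability with per-patient minima and maxima alongside the pooled
value; `report_per_patient()` lists patients bilateral-first.

## Problem sizes and numerical tolerances

The full analysis — 33 patients × 10,000 replicates (330,000 samples) —
runs in a few seconds single-threaded; the test suite exercises the
engine at 100–500 replicates per patient and reserves one full-scale run
for the end-to-end check. Beta fits are accepted at percentile residuals
< 1e-6 (achieved < 1e-9); annuity computations agree with the
geometric-series closed form to 1e-9 relative error; Monte Carlo quantile
recoveries (hazard-ratio CI at 10⁶ draws) are checked within ~3 standard
errors. Discounting uses 3%/year throughout, year 1 undiscounted.

## Limitations

* Only five toxicities are modelled; unmodelled complications (and any
  proton benefit on them) are absent from both arms, which tends to
  understate the proton benefit.
* Equal tumour control between modalities is assumed; any loco-regional
  control difference would swamp the toxicity economics.
* The survival components shipped with the package are synthetic
  emulation constants; absolute life expectancies (and therefore
  chronic-state QALY losses and annuities) should be re-based on registry
  tables for any real application.
* Costs are 2018 US dollars from a single-payer-perspective bundle; no
  inflation adjustment or country-specific tariffs are applied.
* Complication onset timing is reduced to acute-in-year-1 versus chronic;
  no half-cycle correction is applied to the annual model.
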