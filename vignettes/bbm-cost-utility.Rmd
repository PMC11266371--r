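---
title: "A decision-tree + Markov cost-utility model of blood-biomarker triage in Alzheimer's diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-tree + Markov cost-utility model of blood-biomarker triage in Alzheimer's diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbmcea)
```

## What the model is

`bbmcea` evaluates where a plasma amyloid biomarker (BBM) is best placed in
the Alzheimer's disease diagnostic pathway when an anti-amyloid
disease-modifying treatment (DMT) is available. A unit cohort of
65-year-olds with subjective cognitive complaints enters one of three
strategies — standard-of-care referral (`SOC`), BBM gating referral from
primary care (`BBM_PHC`), or BBM gating CSF testing at the memory clinic
(`BBM_MC`) — and the model tracks one diagnostic year (decision tree)
followed by 30 annual cycles of disease progression (Markov cohort model),
accruing discounted costs and QALYs.

### Decision tree

The cohort is partitioned by true cognitive state (SCD 0.53, MCI 0.30, mild
dementia 0.17) and amyloid status (prevalence 0.31 / 0.548 / 0.841 by
state). Routing rules:

* SCD exits at primary care untested (no intervention exists at that stage),
  so amyloid-positive SCD is always a false negative.
* `SOC`: MCI/dementia referred with probability 0.52, independent of amyloid
  status; referred patients receive CSF, whose result (sens 0.91 / spec 0.89
  against true amyloid) sets the final label.
* `BBM_PHC`: MCI/dementia receive BBM (sens 0.89 / spec 0.69); BBM-positives
  are referred (rate 1.0) and receive CSF as above.
* `BBM_MC`: referral as `SOC`; referred patients receive BBM at the clinic
  and only BBM-positives continue to CSF.

CSF accuracy is conditioned on true amyloid status only, never on the BBM
result (test independence). The 3 × 2 × 2 cross-product collapses to ten
diagnostic groups because SCD can never be labelled AD. Diagnosis is a
one-time process: misdiagnosed individuals are not re-evaluated.

Two **parameter dialects** are exposed because two slightly different sets
of amyloid-prevalence figures circulate for the same inputs: `"text"`
(MCI 0.548, dementia 0.841 — the default) and `"table1"` (0.555, 0.84).
Most printed intermediate outcomes reproduce under the text dialect; the
memory-clinic CSF fraction of 16.90% requires the table1 dialect. No single
set reproduces every cell, which is why the switch exists. The SCD
prevalence is 0.31 in both dialects; with 0.314 the false-negative and
true-negative fractions stop matching their published one-decimal values.

### Markov model

Nine health states: SCD, MCI, mild/moderate/severe dementia in the
community, the three dementia stages institutionalised, and dead. Extended
with four tunnel states (`MCI_T1`, `MCI_T2`, `MILD_T1`, `MILD_T2`) that
index time on treatment, because "2 years or until progression to moderate
dementia" is not expressible in a memoryless 9-state chain.

* Pre-dementia progression is amyloid-specific: SCD→MCI 0.41 / 0.10,
  MCI→mild 0.22 / 0.05 (positive/negative). The amyloid-negative values are
  the stored published inputs; they derive from a progression odds ratio of
  5.89 via `OR = odds(p⁺)/odds(p⁻)`. The exact conversion yields 0.1055 and
  0.0457 — note that the SCD value rounds to 0.11, not the conventionally
  quoted 0.10; the model keeps the published 0.10 as its input and
  `odds_to_probability()` reports the exact value.
* No regression out of MCI or mild dementia; regression within the dementia
  block is allowed and comes from the fixture.
* Mortality: SCD/MCI use the raw life-table annual death probability q
  (hazard ratio 1); dementia states use `1 − exp(−q · HR)` with
  severity-monotone hazard ratios anchored at 1.82 for very mild dementia.
  The formula treats q as a rate, exactly as stated in its source; at q = 1
  it therefore does not reach certainty for dementia states — a documented
  property of the printed formula, not a bug.
* **Competing risks**: death is applied first each cycle and all non-death
  transition probabilities are scaled by (1 − p(death)). The source gives
  marginal progression and mortality without an ordering; this declared
  convention keeps rows stochastic. The alternative (progression first)
  would differ at the third decimal of occupancy.
* **Treatment**: diagnosed patients start in `MCI_T1`/`MILD_T1`. The effect
  (×(1 − 0.27) on MCI→mild and mild→moderate progression) applies only to
  amyloid-positive responders; false positives traverse the tunnels — and
  pay for the drug — without benefit. Progression from `MCI_T1` lands in
  `MILD_T2` (second treatment year); any exit from a `_T2` state, reaching
  moderate dementia, or institutionalisation ends treatment with no
  residual effect. Treating institutionalisation as a treatment stop is a
  package choice the source does not address.

### Economic valuation

Annual state costs (SCD costed as MCI at €9,180; community dementia €27,014
/ €30,824 / €35,471 by stage; institutionalised €81,383 / €66,849 / €66,977)
and utilities (pre-dementia split by amyloid status, dementia by stage;
institutionalised states reuse their stage's community utility; dead accrues
nothing). Costs and effects discount at 3%/yr; cycle 0 is undiscounted.

**Accrual convention**: membership at the start of a cycle earns that full
cycle's cost and utility (so immediate death still accrues one year). A
half-cycle (trapezoidal) correction is available via
`params$econ$half_cycle = TRUE`; the default is the plain start-of-cycle
rule because the original computation's behaviour is not verifiable. ICERs
are computed from unrounded increments.

**Quadrant convention**: in the southwest quadrant (cheaper, less
effective), an ICER at or above the willingness-to-pay threshold is read as
favouring the comparator. This follows the source analysis's stated
interpretation; note that net-monetary-benefit logic would read the same
point the opposite way, and the acceptability curve in the PSA uses NMB —
the two are intentionally not forced to agree.

### Sensitivity analyses

* **One-way (tornado)**: every parameter with published low/high bounds is
  set to each bound in turn, the full two-arm pipeline re-runs, and entries
  are sorted by ICER swing.
* **PSA**: beta distributions for probabilities/utilities and gamma for
  costs, fitted by moments with `sd = (high − low)/3.92`; `fixed` entries
  stay constant. Each parameter draws from its own counter-based stream
  derived from the master seed, so adding or removing a parameter does not
  perturb the others. No correlations are imposed (none are published).
  Varying the MCI cost also moves the SCD cost (the model defines SCD cost
  as the MCI cost), and varying a cohort share rebalances the SCD share so
  the shares keep summing to one.
* **Price threshold**: incremental QALYs are price-independent and
  incremental cost is linear in the annual DMT price, so the ICER is
  strictly monotone; the solver root-finds the price at which the ICER
  equals the threshold, and the test suite verifies the result against a
  €100 grid scan of the full pipeline.

## Synthetic fixtures: what they emulate and what they do not

Three inputs of this model class are registry-derived and not published as
reusable tables: the general-population life table, the dementia-stage
transition block, and stage-specific mortality hazard ratios. The
`bbm_fixtures` bundle "F0" provides deterministic synthetic stand-ins:

* **Life table**: Gompertz, `q(age) = 1 − exp(−a·e^{b·age})` with a = 2e-5,
  b = 0.11 (q(65) ≈ 0.025). These values make old-age mortality steeper
  than a contemporary Swedish cohort: remaining life expectancy at 65 is
  about 12.5 years rather than ~20, so lifetime costs, life years and QALYs
  computed on F0 sit well below published lifetime magnitudes.
* **Dementia block**: forward progression ~0.25/yr, institutionalisation
  ~0.06/yr, regression ~0.02/yr, seeded multiplicative jitter, no return
  from institutional care. On F0, median survival from mild dementia at 65
  falls in the 3–10-year envelope the test suite asserts.
* **Hazard ratios**: anchor 1.82 × 1.4 per stage, ×1.15 when
  institutionalised.

These are modelling conveniences, explicitly tagged `synthetic` in every
export. Consequently the tests pin only the decision-tree quantities (which
are fixture-free closed-form arithmetic) to published values; everything
downstream of the fixtures is validated by *properties* — oracle agreement,
conservation laws, monotonicities, reproducibility — not by published
lifetime totals. Passing tests therefore demonstrate correctness of the
machinery, not calibration to any real registry. Real supplementary tables
can be supplied via `read_fixture_bundle()` using the same CSV schema.

## Numerical conventions and degenerate inputs

* Probabilities validated to [0, 1] at load; cohort shares to sum 1 within
  1e-9; transition-matrix rows stochastic within 1e-9; dead is absorbing.
* Table outputs round percentages at one decimal half-away-from-zero;
  internal values keep full precision.
* Beta fitting fails loudly (classed `bbm_fit_error`) when the implied
  variance is infeasible for the mean, rather than clipping.
* Degenerate cases with defined behaviour (and tests): zero-width cohorts,
  zero costs, null treatment (`effect = 0` reproduces the untreated arm
  exactly), certain death (q = 1 empties pre-dementia states in one cycle),
  a price threshold of zero when the ICER already sits at the threshold,
  and a classed no-solution signal when the intervention gains no QALYs.

## Verification strategy and problem sizes

The package chooses deliberately modest default problem sizes so the whole
suite runs in well under a minute: the microsimulation cross-check uses
200,000 individuals (max absolute occupancy deviation < 0.005 against the
cohort matrices, with ≥99% of occupied cells within 3 Monte-Carlo standard
errors — with ~2,300 stochastic cells, a handful beyond 3 SE is the
expected nominal behaviour, so demanding literally every cell inside 3 SE
would reject a correct implementation); PSA determinism is checked at small
iteration counts and distribution calibration at 10,000 draws; the tornado
checks cover the parameters with a directional prediction (higher BBM
specificity lowers the ICER, sensitivity is near-null, drug price dominates
diagnosis-cost uncertainty).

## Known limitations

* Only AD-type dementia; no competing neurodegenerative diagnoses.
* No re-testing of misdiagnosed individuals; no test-sequence correlation
  (BBM and CSF errors independent given amyloid).
* Treatment modelled as a progression-rate multiplier; no direct effect on
  institutionalisation or mortality, no adverse events, no residual effect.
* The "very mild" dementia stage exists only as the mortality anchor; the
  eight MMSE-defined mortality states of the source registry analysis do
  not map one-to-one onto the six dementia Markov states, and the fixture
  collapses very mild into mild.
* F0 is synthetic: absolute lifetime results on it are illustrative, not
  estimates.
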