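---
title: "Measuring prescription patterns around clinical events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring prescription patterns around clinical events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pace)
```

## The problem

Whether prescribers react appropriately to a clinical event — stopping a
drug that aggravates hyperkalemia, starting one that treats it — is
usually audited with event-specific, hand-built quality indicators. This
package implements a generic, data-driven alternative: for any pair of a
monitored drug and a detectable clinical event, it classifies the
prescribing reaction into one of three discrete patterns (intervention,
maintenance, discontinuation) using nothing but day-level prescription
counts from inpatient EHR tables.

## The model

### Events and observation windows

An event is either a quantitative laboratory value strictly exceeding a
threshold (each qualifying measurement is an event of its own, anchored on
the day the result is known), or a nominal test milestone: the day a test
is ordered, the day a positive result returns, the day a negative result
returns, or a reference point a configurable number of days (default 5)
before the order.

Each event day D0 anchors a six-day observation window over offsets
D−4..D+1. Because the method reads prescribing behaviour during a
hospitalization, a window is *eligible* only when it lies entirely inside
one: the event must fall at least 4 days after admission and at least 1
day before discharge, both boundaries inclusive. Two further filters mark
windows ineligible:

* **Abnormal baseline.** If the first value of the event analyte observed
  in the admission *before the window opens* already exceeds the upper
  normal reference bound (configurable; default equal to the event
  threshold), the patient was abnormal at baseline and the window is
  excluded. A window with no measurement before D−4 is kept but flagged
  `no_baseline`: exclusion requires observed evidence of abnormality, and
  without the before-window restriction the event measurement itself could
  act as its own baseline and exclude every first-measurement event.
* **Excludable diagnoses.** Patients carrying any ICD-10 code matching a
  configured prefix list (default: the renal-failure codes I12.0, I13.0,
  I13.1, N17–N19, standing in for chronic renal failure on dialysis, which
  confounds potassium homeostasis) are excluded. How dialysis itself is
  recorded varies by hospital; prefix matching on diagnosis codes is the
  portable approximation, and the list is fully configurable.

The filters commute and only ever flip windows from eligible to
ineligible, so the eligible set is independent of filter order. Every
window carries its exclusion reasons; nothing is silently dropped.
Recurrent events in one admission are all counted separately by default;
`min_event_gap_days` optionally de-duplicates event clusters.

### The prescription change index

Prescription records of a drug are pooled per window-day offset over all
eligible windows and accumulated from D−4 to D+1 into a cumulative curve
C(k). The index is the ratio of the average slopes of that curve after and
before the event,

$$\mathrm{PCI} \;=\; \frac{(C(+1) - C(-1))/2}{(C(-2) - C(-4))/2}
\;=\; \frac{n_{D0} + n_{D+1}}{n_{D-3} + n_{D-2}},$$

the two-day prescription sum around the event against the two-day sum
before it. The anchor days D−4 and D−1 cancel and never affect the index —
a property the test suite asserts. Multiple records of a drug on one day
each count (the statistic counts prescriptions, not exposure days), and a
record falling inside two overlapping windows counts in each.

With the default cut-offs, PCI ≤ 0.667 (a 1.5-fold reduction) is a
discontinuation pattern, PCI > 1.500 an intervention pattern, and
everything between a maintenance pattern. Degenerate denominators are
tagged, not raised: a zero before-sum with a positive after-sum is
reported as `PCI = Inf` (the ratio's limit — a pure intervention), and
zero on both sides as an undefined PCI with an *indeterminate* pattern,
which is excluded from pattern summaries and from agreement calculations.
PCIs are computed in full precision and rounded to three decimals only in
written outputs.

### The binomial alternative

For comparison, `binomial_pattern()` applies an exact two-sided binomial
test (success probability 0.5, minimum-likelihood two-sided convention, as
computed by `stats::binom.test`) to the same two-day sums, calling a drug
an intervention/discontinuation only on a significant deviation (default
α = 0.05). The p-value gives a formal significance statement the slope
ratio lacks; the ratio in turn is semi-quantitative (a PCI of 5 is a
stronger intervention than 1.6) and needs no statistical machinery. On
simulated cohorts with strong effects (multiplier ≥ 3 or ≤ 1/3, ≥ 200
pooled windows) the two rules agree in ≥ 95% of replicates.

### Per-prescriber patterns and agreement

`pattern_by_prescriber()` recomputes patterns with the prescription table
restricted to one prescriber's orders within a lookback period (default
365 days, ending at the most recent prescription). Windows are cohort-wide;
windows without that prescriber's orders contribute zeros and so do not
move the pooled index. Pairs backed by fewer than 10 prescriptions of the
drug in the lookback are omitted as unreliable. The floor counts lookback
prescriptions rather than in-window prescriptions, so that it measures the
evidence behind the pattern rather than the prescriber's event exposure.

`cohens_kappa()` then measures chance-corrected agreement between
calculated patterns and externally supplied labels (e.g. questionnaire
answers) over shared (prescriber, drug) keys: κ = (pₒ − pₑ)/(1 − pₑ),
unweighted, over the three substantive categories. Indeterminate
calculated patterns are dropped (a questionnaire admits only three
answers), and κ is undefined when expected agreement is 1.

## Severity and condition profiles

`severity_sweep()` re-runs the entire pipeline at each point of an
increasing threshold grid (reference grid for potassium: 4.50–7.00 mmol/L
in 0.25 steps, 11 points) and `condition_profile()` across nominal
conditions (before-order, order, result-negative, result-positive). Each
point is an independent full run — no caching — so a sweep point is
identical to the single run at the same configuration, another asserted
invariant. The baseline bound tracks the swept threshold unless pinned
with `fixed_upper_ref`. Points backed by fewer than `min_windows` windows
(default 5; the floor is a reporting aid, not part of the method) are
flagged `low_n`, and undefined PCIs are exported as missing values.

## The synthetic cohort generator

`simulate_cohort()` draws the structure the method assumes: one admission
per patient with uniform stay length 8–20 days; one quantitative lab value
per day, normal around 4.2 ± 0.3 mmol/L (a normokalemic inpatient) with
independent per-day excursion probability 0.05 and excursion magnitudes
uniform on 5.6–7.0 mmol/L (or any supplied sampler); optionally one
nominal test per admission with an order day, a delayed result (default 3
days, the turnaround of a toxin assay), and a fixed positive probability.
Each drug follows an intent: independent daily prescription draws at a
baseline probability, multiplied by r from the drug's trigger (first
threshold crossing, test order, or positive result; onset offset
configurable) onward. Admissions are assigned uniformly to prescribers,
and per-prescriber intent overrides simulate prescribers with differing
knowledge. Randomness comes from per-patient substreams derived from the
seed, so identical seeds give identical cohorts and enlarging a cohort
preserves its existing patients.

`expected_pci()` gives the analytic pooled-PCI limit of an intent: r for
onset at D0, and the piecewise two-day expectation otherwise (e.g.
(1 + r)/2 for onset at D+1).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: correlated comorbidity and dosing structure,
dose adjustments without frequency change, calendar and weekday effects,
multi-admission patients, informative discharge (sicker patients staying
longer), and protopathic prescribing before the event is recorded. The
generator validates the estimator's statistical behaviour, not its
clinical calibration.

### Parameter recovery and the first-event restriction

Under the intent model the rate switch is permanent: after a patient's
first event, every later day runs at r·p. A window anchored on a *later*
event in the same admission therefore has its before-days (D−3, D−2)
already at the post-switch rate, and the pooled PCI over all windows
converges to a value diluted toward 1, not to r. The convergence statement
"pooled PCI → r" holds for windows whose before-days are pre-switch, i.e.
first-event windows. Parameter-recovery and concordance evaluations
consequently de-duplicate events to the first per admission (a large
`min_event_gap_days`); recovery is tested at two cohort sizes with
shrinking tolerance and at ~2 700 pooled windows recovers multipliers
0.25, 1, and 3 within ±10%. The step-intent sweep evaluation draws
excursion magnitudes from a bimodal mixture (85% uniform 5.6–6.0, 15%
uniform 6.0–7.0) so that sub-trigger grid points are dominated by
non-reactive events; with magnitudes uniform on 5.6–7.0 most events exceed
a 6.0 trigger and the sub-trigger grid points would correctly — but
uninformatively for the localisation check — sit below the cut-off.

## Numerical and interface choices

* Dates are handled at day resolution; administration times are truncated,
  because the statistic bins prescriptions per day.
* Input is UTF-8 delimited text with a header; delimiter and date format
  are configurable (ISO-8601 default). Write-then-read is the identity on
  records, and repeated writes are byte-identical. Every rejected input
  row is reported with its table, row, and reason.
* Nominal lab values are normalized to the closed vocabulary
  {positive, negative}; anything else is a row error.
* Baseline ties (two measurements on the earliest day) resolve to the
  higher value, the conservative choice for an exclusion rule.
* Cut-offs, thresholds, reference bounds, window de-duplication, the
  before-order offset, and the significance level all live in
  configuration with the reference analysis values as defaults; nothing
  event-specific is hard-coded.
* All simulation-backed tests fix their seeds; stochastic tolerances are
  set from the binomial sampling error of the pooled sums at the simulated
  sizes (e.g. ±10% at ≥ 2 000 windows is ≈ 2–4 standard errors depending
  on r).

## Known limitations

The six-day window reads only the immediate inpatient reaction; slow
tapers, outpatient follow-up, and dose changes at constant frequency are
invisible to it. The PCI carries no uncertainty statement — use the
binomial companion when significance matters. Pooled hospital-wide
patterns can mask heterogeneous prescriber behaviour; the per-prescriber
route exists for that, but needs enough prescriptions per prescriber to be
reliable.
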