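---
title: "Benchmarking HPB quality indicators: detectable differences, volume requirements and funnel plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking HPB quality indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpbbench)
```

## The problem

National clinical audits compare hospitals on quality indicators (QIs):
postoperative mortality, major morbidity (Clavien-Dindo grade >= 3a),
failure to rescue (FTR, death *after* a severe complication), and the
composite textbook outcome (TO, liver surgery) or ideal outcome (IO,
pancreatic surgery).  A hospital is called an outlier when its observed
rate falls outside 95% prediction limits around the national benchmark in
a funnel plot.  Whether an outlier *can* be seen at all, however, is a
sample-size question.  At an annual volume of 20 resections and a
mortality benchmark of 0.6%, the smallest detectable excess is an absurd
13.9 percentage points; a QI that never flags anyone is not an
instrument.  This package makes that arithmetic explicit, for the four
QIs and the four procedure groups of hepato-pancreato-biliary (HPB)
surgery: minor and major liver resection (fewer than three vs three or
more adjacent segments), pancreatoduodenectomy (PD) and distal
pancreatectomy (DP).

## Indicator definitions

Per patient record:

* **Mortality** — death during the initial admission or within 30 days of
  surgery.  The registry schema carries this as one boolean; the
  in-hospital/30-day distinction is collapsed at data-capture time and no
  date arithmetic is performed.
* **Major morbidity** — Clavien-Dindo >= 3a complication.  Death without a
  severe complication is mortality but not morbidity.
* **FTR** — death among patients with a severe complication.  Its
  denominator is the severely-complicated subgroup, so the FTR denominator
  always equals the major-morbidity numerator of the same stratum, and
  FTR deaths are a subset of all deaths.  With no severe complications the
  rate is undefined and flagged, never silently zero.
* **TO** (liver) — conjunction of: no severe complication, no death, no
  readmission, length of stay (LOS) at or below the 90th percentile, and
  an adequate resection margin.
* **IO** (pancreas) — conjunction of: no death, no severe complication, no
  POPF grade B/C, no reoperation, LOS at or below the 75th percentile, no
  readmission.

LOS thresholds are computed nationally per procedure group over the
benchmark window with the nearest-rank rule (the `ceiling(q*n)`-th order
statistic), so a threshold is always an observed integer day and a stay
exactly on it still achieves the composite ("<=" is inclusive).  The
stratification and percentile algorithm are choices of this package: the
TO/IO literature defines "prolonged stay" within a procedure group, and
nearest rank keeps at least the nominal mass at or below the threshold on
any sample.

The **benchmark** of a QI is the national mean event rate over the window,
interpreted here as the patient-weighted pooled rate (total events over
total eligible patients) rather than the unweighted mean of hospital
rates: the pooled rate is the quantity a funnel-plot centre line uses, and
it is reported alongside the across-hospital min-max exactly as audit
reports present it.  Records missing a component required by a composite
are excluded from that composite's denominator and itemised in an
exclusion report; direct indicators keep the full denominator.

## The power model

All sample-size statements derive from a two-sided one-sample proportion
test at significance level $\alpha = 0.05$ and power $1-\beta = 0.80$
(`power_spec()`), formulated on the variance-stabilised (arcsine) scale.
With Cohen's effect size

$$h = 2\arcsin\sqrt{p_1} - 2\arcsin\sqrt{p_0},$$

the required total caseload to distinguish a hospital running at $p_1$
from the benchmark $p_0$ is

$$n = \left(\frac{z_{1-\alpha/2} + z_{1-\beta}}{h}\right)^2 .$$

On the arcsine scale the variance of a transformed proportion is
approximately $1/(4n)$ independent of the rate, which keeps the formula a
clean closed form even at mortality-level event rates.  The
variance-stabilised formulation was adopted because it regenerates the
published national-audit threshold grid and volume statements from the
published benchmarks; Wald-variance alternatives do not.  Normal quantiles
are evaluated at double precision ($z_{0.975} = 1.959964$,
$z_{0.80} = 0.841621$), not the two-decimal textbook values; the
difference is below reporting precision but the choice is fixed for
reproducibility.

Inverting the relation at a given volume $n$ gives the smallest
detectable alternative in closed form,

$$p_1 = \sin^2\!\Big(\arcsin\sqrt{p_0} \pm
        \frac{z_{1-\alpha/2}+z_{1-\beta}}{2\sqrt{n}}\Big),$$

with "+" for adverse indicators (only increases signal worse care) and
"-" for composites (decreases are adverse).  When the arcsine argument
leaves $[0, \pi/2]$ the alternative saturates at 0 or 1 and the cell is
flagged, never silently truncated.  `required_n()` and
`detectable_difference()` are exact algebraic inverses; the test suite
checks the round trip to $10^{-6}$ relative error over a dense grid.

Reporting conventions, fixed once: detectable differences are printed in
percentage points rounded half-up to one decimal (internal values stay at
full precision); the minimum *annual* volume over $k$ pooled registration
years is $\lfloor n/k \rfloor$ — the rule uniquely consistent with the
published mortality quartet (totals of about 75.3/163.4/145.6/75.3 over
three years giving 25/54/48/25 per year).

```{r}
threshold_table(dutch_hpb_benchmarks(), volumes = c(20, 100))[1:8, ]
min_annual_volume(0.027, 0.05, years = 3)
```

### Known irreproducible cells

Feeding the published one-decimal benchmarks through the inversion
reproduces the published grid except for a handful of cells, which the
original analysis evidently computed from unrounded internal rates:

* the whole FTR column for minor and major liver resection (e.g. 19.8 and
  26.2 published at volume 20, vs 21.7 and 27.3 from the rounded
  benchmarks 5.4% and 14.2%);
* scattered one-tenth-point differences: PD mortality at 20/40/50/200
  (18.6/11.6/10.0/4.2 published vs 18.5/11.5/9.9/4.1), minor-LR major
  morbidity at 20 (25.0 vs 25.1), DP FTR at 20/40/200 (19.0/11.9/4.4 vs
  19.1/12.0/4.3), and a few cells of the composite block (major-LR
  30.0/21.8/19.5/13.9/9.9 vs published 29.9/21.6/19.4/13.8/9.7 pattern,
  DP at 20, PD at 100/200);
* the published major-LR TO minimum annual volume of 29 at a 15-point
  decrease over three years, where the floor rule gives 28
  (total $\approx 86.1$).

These cells are documented here and excluded from exact assertions; every
other published reference value is asserted at printed precision in the
test suite.

## Funnel limits and outlier calls

The funnel-plot construction is not standardised across audit software,
so both common variants are provided.  The default is the exact binomial
region, computed on the count scale: at volume $n$ the upper limit is the
smallest count $c$ with $P(X \ge c \mid n, p_0) \le \alpha/2$, the lower
limit the largest count with $P(X \le c) \le \alpha/2$, and a hospital is
an outlier only when its count is *strictly* outside the limits — a count
on the limit is still consistent with the benchmark ("fell outside" is
strict).  Discreteness therefore makes the exact region conservative:
across the acceptance grid the true per-side flagging probability is
below 1%.  The exact method is the default because at audit volumes
($n \approx 20$) and rare events ($p_0 \approx 0.6\%$) the normal
approximation $p_0 \pm z\sqrt{p_0(1-p_0)/n}$ is badly anticonservative;
the normal method is retained for comparability and agrees with the exact
limits to within 0.01 once $np_0(1-p_0) \ge 25$.  Degenerate benchmarks
($p_0$ of 0 or 1) put all null mass on one count and both limits collapse
onto it.  Better-than-benchmark deviations are classified `BETTER` and
reported separately: benchmarking in these audits deliberately acts on
the worse side only, but the two-sided geometry of the interval is kept.
Classification compares integer counts, so a rate can never drift across
a boundary through floating-point representation.

```{r}
funnel_limits(0.027, c(20, 50, 100, 200))
```

`detection_rate()` closes the loop: simulate a designated hospital at a
chosen deviation, classify each replicate (by the arcsine test or by
funnel limits), and report the empirical flagging probability.  At the
detectable $p_1$ for its volume, the arcsine-test classifier recovers the
80% design power; the acceptance suite verifies 0.74-0.86 over 2000
replicates for five (indicator, volume) scenarios chosen mid-grid
(mortality 2.7% at $n=100$; major morbidity 36% at $n=200$ and 28.1% at
$n=50$; TO 73.6% and IO 46.8% at $n=100$).  Small-$n$ rare-event cells
are deliberately not used for this check: the asymptotic test is
mis-sized there (e.g. at $p_0=0.6\%$, $n=200$ the exact two-sided size is
0.31, because the test already rejects at zero events), which is a known
property of arcsine tests at $np_0$ near 1, not a defect of the power
algebra.

## The synthetic registry generator

The real audit data are confidential, so the generator emulates their
structure and makes every downstream stage testable: 24 hospitals (21
performing liver surgery, 15 pancreatic, 12 both), fixed annual caseloads
matching the published 2021 per-hospital medians and ranges (minor LR
median 44, range 9-84; major LR 9, 1-54; PD 39, 22-144; DP 13, 5-30), and
eight registry years (2014-2021) at those volumes, giving about 9900
liver and 7700 pancreatic records — the scale of the audited cohorts.
Default generative probabilities are anchored to the published 2020-2021
benchmarks: `p_severe` and `p_death_given_severe` (the FTR probability)
take the published major-morbidity and FTR rates directly, and death is
drawn *conditionally* on severe complication, because FTR is defined
conditionally and must be a free parameter.

Two published triples are internally inconsistent: for major LR
(mortality 3.3% but $28.1\% \times 14.2\% = 3.99\%$) and DP (0.6% but
$22.3\% \times 3.1\% = 0.69\%$) the published mortality is *below* the
deaths already implied by deaths-after-complication, impossible if FTR
deaths are a subset of all deaths.  The generator resolves this by
setting `p_death_given_not_severe = 0` for those groups and letting the
marginal mortality be the implied product; for minor LR and PD the
conditional is solved so marginal mortality matches the published value
exactly.  Recovery tests therefore compare simulated rates against the
generator's *analytic implied rates* (`implied_rates()`), which are the
published values wherever the published values are attainable.

Length of stay is negative binomial — a right-skewed overdispersed count
model whose only role downstream is the percentile threshold —
parameterised by median and dispersion: NB(median 6, size 8) for minor
LR, NB(8, 8) major LR, NB(11, 4) PD, NB(7, 6) DP, i.e. realistic stays of
about a week for liver surgery and a week and a half after PD.  The
parameters were chosen once so that the population CDF is not knife-edge
at the 90th/75th nearest-rank percentile; otherwise the empirical
threshold would flip between adjacent days from sample to sample and the
composite rate would be bimodal across seeds.

Composite components (readmission, margin, POPF, reoperation) are drawn
independently — the audits publish no dependence structure, so any
correlation would be an invention.  This has a consequence worth stating
plainly: under independence the maximum attainable IO rate for PD is
$(1-0.36) \times 0.75 = 0.48$ even with perfect POPF, reoperation and
readmission performance, so the published IO benchmarks (46.8% PD, 63.3%
DP) are *not* reachable with realistic component rates.  Real audits
reach them because adverse components cluster in the same patients.  The
defaults therefore use realistic components (readmission 16%/14%, POPF
B/C 14%/21%, reoperation 9%/5% for PD/DP), and the implied IO comes out
near 32%/39%.  For liver surgery the published TO benchmarks *are*
attainable: margin adequacy is solved from the other components (giving
96.6%/91.7%), so the implied TO equals 73.6%/54.1% exactly.  Passing
recovery tests consequently show that the generator and the indicator
engine agree to binomial sampling error — they do not show that real
audit data are independent across components, and funnel or detection
results for composites should be read with that limitation in mind.

Determinism: one master seed; each hospital draws from a private
substream derived by stable hashing of its label, so adding, removing or
modifying one hospital never perturbs another's records — which also lets
`detection_rate()` simulate only the designated hospital and still obtain
exactly the records it would have inside the full registry.  Identical
configurations give byte-identical registry CSVs.

```{r}
cfg <- audit_sim_config(seed = 1, years = 2020:2021)
implied_rates(cfg)$pooled
```

## The fitted-benchmark object

`hpb_benchmark(records, window)` is the package's estimator: it returns
the benchmark table, per-hospital summaries, LOS thresholds, component
rates and annual volumes, with `coef()` (benchmark matrix), `predict()`
(detectable-difference grid), `plot()` (funnel plot), `residuals()`
(arcsine-scale standardised hospital deviations $z_h = (2\arcsin\sqrt{\hat
p_h} - 2\arcsin\sqrt{p_0})\sqrt{n_h}$) and `simulate()` (parametric
regeneration of registries at the fitted rates — the funnel-plot null).
`run_pipeline()` drives registry, validation, fit, grids, adequacy and
funnel outputs into one result directory with a manifest; rates are
serialised with six significant digits next to raw numerator/denominator
columns, so published-table rounding stays a formatting layer.

## Problem sizes and numerical tolerances

The test suite runs everything at the scale the analysis itself uses:
full eight-year registries (~17 600 records) for distributional recovery
at a $4\sqrt{p(1-p)/n}$ tolerance; 2000 replicates per design-power
scenario; 5000 null hospitals per funnel-coverage cell; 200 seeds for
generator recovery at reduced $n$; and a 1000-point grid for the
algebraic round trip at $10^{-6}$ relative tolerance.  All stochastic
checks run under fixed seeds chosen up front; the margins above (true
per-side funnel mass below 1%, exact design powers 0.79-0.83 inside the
0.74-0.86 band) make the outcomes insensitive to the particular seed.

## Limitations

No case-mix or risk adjustment (by design: without adequate sample size
even impeccable adjustment is inconclusive), no tumour-type-stratified
benchmarks, no volume-outcome modelling, no overdispersion inflation of
funnel limits, no multiplicity correction across the threshold grid, and
no exact-binomial (small-sample) power variant — the published analysis
is asymptotic and the package reproduces it.  The generator does not
model temporal trends, minimally-invasive-technique shifts, or
component correlations; see above for what that implies about composite
indicators.
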