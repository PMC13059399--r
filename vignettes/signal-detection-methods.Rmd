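---
title: "Disproportionality methods in pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality methods in pvsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous-reporting systems such as FAERS collect post-marketing safety
reports: each report names one or more drugs (with role codes — primary
suspect, secondary suspect, concomitant, interacting), one or more reaction
terms coded as MedDRA preferred terms (PTs), and sparse demographics.
Because there is no denominator of exposed patients, safety screening relies
on *disproportionality*: is an event reported with this drug more often than
the background reporting of that event across all other drugs would predict?

For a target drug and an event label the deduplicated report collection is
cross-classified into a 2×2 table,

|            | event      | no event |
|------------|------------|----------|
| drug (PS)  | a          | b        |
| other      | c          | d        |

with `N = a+b+c+d`. "Drug" here means the report lists the target as its
primary suspect; reports where it appears with any other role count as
background, which mirrors the usual primary-suspect inclusion rule. Each
report contributes to exactly one cell per label, and at most once per label
even when several of its PTs map to that label (the once-per-report-per-label
convention; an event-occurrence counting mode is available through
`count_unit = "event"` because published tabulations are ambiguous at the
system-organ-class level, but report counting is the default and the
convention all tests use).

## The four statistics

`pvsignal` scores each table with the four estimators in routine
pharmacovigilance use, and flags a label as a potential signal only when
**all four** pass their thresholds:

* **ROR**, the reporting odds ratio `ad/bc`, with the Wald 95% CI
  `exp(log ROR ± 1.96·sqrt(1/a + 1/b + 1/c + 1/d))`. A zero cell makes the
  odds ratio undefined; the Haldane–Anscombe correction (+0.5 on all four
  cells) is applied *only* to the ROR and only when a zero occurs, and is
  logged. The other three statistics handle zeros natively.
* **PRR**, the proportional reporting ratio `[a/(a+b)]/[c/(c+d)]`, paired
  with the Pearson chi-square of independence. The chi-square is uncorrected
  by default — the magnitudes conventionally quoted alongside PRR are the
  uncorrected ones — with Yates' continuity correction available as an
  option.
* **IC**, the Bayesian information component of the BCPNN family, in bits:
  with `E = (a+b)(a+c)/N`, the default closed form is
  `IC = log2((a+0.5)/(E+0.5))` with lower credibility bound
  `IC025 = IC − 3.3(a+0.5)^{−1/2} − 2(a+0.5)^{−3/2}`. This form is
  deterministic, defined for `a = 0`, and converges to `log2(a/E)` as counts
  grow. The original posterior-moment formulation (Dirichlet/Beta
  hyperpriors, delta-method variance, 1.96σ bound) is available via
  `ic_method = "bate"`; the two agree asymptotically and differ mainly for
  very small `a`, where both are dominated by the credibility penalty.
* **EBGM**, the empirical Bayes geometric mean of the multi-item
  gamma-Poisson shrinker (MGPS). The relative reporting ratio λ of every
  (drug, label) cell gets a two-component gamma mixture prior; with
  `a | λ ~ Poisson(λE)` the marginal count is a mixture of negative
  binomials whose likelihood is maximized over the five prior parameters
  (α₁, β₁, α₂, β₂, w). The posterior is again a gamma mixture;
  `EBGM = exp(E[ln λ | a])` (computed with the digamma function) and
  `EBGM05` is the posterior 5th percentile, found by root-finding the
  mixture CDF to high precision. EBGM is the *geometric-mean* posterior
  summary — that is what the name means — not the posterior mean.

Default gate (all overridable through `da_thresholds()`): `a ≥ 3`,
ROR lower 95% bound `> 1`, `PRR ≥ 2` with `χ² ≥ 4`, `IC025 > 0`,
`EBGM05 > 2`. These are the standard published criteria for the respective
methods; requiring all four at once is deliberately conservative, which the
null-calibration test quantifies (mean flagged fraction well under 5% on
signal-free simulations).

## Fitting the MGPS prior

The prior is fitted once per aggregation level on the cells of **all**
primary-suspect drugs in the store (full drug × label cross product with
positive margins, zero-count cells included), not only the target drug's
cells — the shrinker's job is to adjust for the overall reporting rate
across drugs. Numerical choices:

* L-BFGS-B on log-transformed gamma parameters and a logit-transformed
  weight, from a fixed list of four asymmetric starting points, so the fit
  is deterministic; no RNG is consumed.
* A single-component fit is always computed as well. The mixture is kept
  only when it improves the log marginal likelihood by more than 2 units and
  its two components are not nearly identical; otherwise the single gamma is
  returned with `w = 1`. A two-component likelihood fitted to one-component
  truth is flat in the weight (any split of identical components fits
  equally well), so without this collapse rule the reported `w` would be an
  arbitrary label-switching artifact.
* Components are reported with the higher-mean (`α/β`) component first, so
  `w` always refers to the elevated-risk component.

Parameter-recovery tests simulate 50,000 cells from a known prior
(including the classic (0.2, 0.1, 2, 4, w = 1/3) configuration) and require
every parameter back within 20% relative error; at desk scale the realized
errors are a few percent.

## Ingestion rules

* **Deduplication**: one row per case, keeping the highest version, with
  ties broken by later receipt quarter and then input order. FAERS-derived
  extracts differ in how they were cleaned upstream; this keep-latest rule
  is this package's explicit convention, applied identically to real and
  simulated input.
* **Drug names** are case-folded, whitespace-collapsed and mapped through a
  user-supplied synonym table (trade name → substance), so `"CRYSVITA "`
  and `"burosumab"` meet the primary-suspect filter identically.
* **Quarters** derive from the `fda_dt` date by calendar quarter; the
  analysis window is inclusive on both ends. Window and primary-suspect
  filters commute, which is tested.
* Reports with no reaction rows are dropped with a warning rather than
  erroring; unknown role codes downgrade to concomitant with a warning;
  more than 10% malformed demography rows is an error.
* At SMQ level a report whose PTs hit no SMQ is pooled under a reserved
  `"NA"` row (reported in provenance, excluded from signal tables);
  unmapped PTs at SOC level go to `"unmapped"`, likewise excluded.

## What the simulator emulates — and what it does not

`generate_reports()` draws, per report: a primary-suspect drug from a
popularity vector (Zipf by default — spontaneous-report databases are
heavily dominated by a few drugs); an event count `k ~ 1 + Geometric`
(mean 1.8 by default); `k` i.i.d. PTs from the event distribution
conditional on the PS drug, deduplicated into the reaction set. An injected
signal multiplies one PT's conditional probability by `rr` before
renormalization. This scheme was chosen because it admits a closed-form
oracle: `P(PT in report | drug)` and the expected 2×2 cells
(`expected_counts()`) are exact expressions, so convergence of empirical
tables is testable at 3 Monte-Carlo standard errors rather than by eye.

Demographics mirror the profile typical of a rare-disease biologic in
FAERS: sex and age unknown for ~99.5% and ~99.7% of reports, one dominant
reporting country, a dominant indication, and serious outcomes absent
(hence "unknown") for roughly 80% of reports, drawn as independent
per-outcome Bernoullis. A configurable fraction of cases (5% by default)
is emitted twice with an incremented version and resampled demographics to
exercise deduplication. The default window is 2018Q1–2024Q3. The remaining
scale choices — 50,000 reports, 25 drugs, 100 PTs — are a desk-scale
stand-in for a multi-million-report background: large enough that
shrinkage, gating and ranking behave qualitatively as at full scale, small
enough that the whole suite runs in minutes. Tests use smaller instances
(typically 2,000–8,000 reports, 6–8 drugs, 20–40 PTs) chosen so each check
is comfortably powered at its stated tolerance.

The simulator does **not** model drug-name typos, time-varying reporting
rates, stimulated reporting after publicity, correlated event clusters
beyond the hierarchy, or informative missingness. Passing tests on
synthetic data therefore demonstrate correctness of the statistical
machinery under a known sampling scheme — not that any particular
real-world extract is clean, nor that published signal values for a
specific drug can be reproduced without the same multi-million-report
background those values were computed against.

## Degenerate inputs and tie-breaks

Empty stores flow through every filter and summary without error (the
percentage operation refuses a zero denominator; callers guard). Ranked
outputs sort by the chosen statistic with ties broken by case count
descending, then label lexicographically, so output files are byte-stable
across runs — the pipeline writes its configuration hash and report funnel
to `provenance.yaml` to make that auditable. Frequency tables always
tabulate the `"unknown"` sentinel explicitly: in spontaneous-report data
missingness is a finding, not an absence.

## Known limitations

Crude (unstratified) disproportionality only; no age/sex/year
stratification. The MedDRA-style hierarchy is synthetic or user-supplied —
the licensed MedDRA distribution is not shipped, and SMQ narrow/broad
scopes are not distinguished. LLT→PT coding is out of scope. Statistics are
association measures on reporting behavior, not causal or incidence
estimates.
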