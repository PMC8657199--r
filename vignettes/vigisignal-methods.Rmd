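---
title: "Case/non-case disproportionality screening with vigisignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case/non-case disproportionality screening with vigisignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigisignal)
```

## The problem

Spontaneous-reporting pharmacovigilance databases collect individual case
safety reports (ICSRs): one report describes one patient, the drugs they
took (each with a reporter-assigned causal role — suspected, interacting
or concomitant), and the adverse reactions observed, coded as preferred
terms (PTs) from a five-level regulatory terminology
(SOC > HLGT > HLT > PT > LLT). Because there is no denominator of exposed
patients, risk cannot be estimated; what can be estimated is
*disproportionality* — whether an event is reported more often with a
drug of interest than with everything else in the database. vigisignal
implements the case/non-case version of this design end to end: event-set
definition through the term hierarchy, eligibility filtering, 2×2
screening with the reporting odds ratio (ROR), time-to-onset (TTO)
summaries, and descriptive cohort tables, together with a synthetic ICSR
generator that makes the whole pipeline testable against known truths.

## The model

For one (drug, event-PT) pair over a set of eligible in-window reports,
each report is classified once into the 2×2 table

|                        | event PT | any other PT |
|------------------------|----------|--------------|
| drug of interest       | a        | b            |
| all other drugs        | c        | d            |

where "drug of interest" means the drug appears with a suspected or
interacting role (concomitant mentions never count as exposure). The
reporting odds ratio and its Woolf (log-normal) 95% confidence interval
are

$$\mathrm{ROR} = \frac{a/b}{c/d} = \frac{ad}{bc}, \qquad
\mathrm{CI}_{95} = \exp\!\Big(\ln \mathrm{ROR} \pm 1.96
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\Big).$$

A pair is *screened* only when it has at least `min_cases = 5` cases
(the usual EMA signal-detection threshold; the comparison is `a >= 5`,
configurable). A **signal of disproportionate reporting (SDR)** is a
screened pair whose CI lower bound exceeds 1. When any cell is zero the
estimate is reported as undefined rather than continuity-corrected: a
silently corrected value would not be the plain cross-product ratio the
screen documents, and at the five-case threshold zero cells in `a` never
arise for screened pairs.

Counting is per report, not per mention: a report listing the event PT
twice contributes once to `a`; a report carrying two drugs of interest is
exposed in each drug's own table and unexposed (c/d side) in the others.

## Eligibility and duplicates

The default criteria exclude reports (i) not notified by a health
professional, (ii) with unknown age, (iii) with unknown sex, and
(iv) rule-based duplicates — applied in that fixed order, with each
excluded report attributed the *first* reason that caught it. Only the
attribution depends on the order; the final eligible set does not. The
same eligibility is applied to the whole database before any 2×2 is
built, so cases and non-cases are filtered identically; per-flag switches
allow the alternative (filtering cases only) for sensitivity analyses.

Duplicate detection in large databases is proprietary and probabilistic;
vigisignal substitutes a documented deterministic rule: two reports are
duplicates when they agree exactly on sex, age, country, the sorted
suspected/interacting drug-name set and the sorted reaction-PT set, and
their report dates lie within 30 days (both the key and the tolerance are
configurable). The earliest report of a duplicate group is kept, ties
broken by smallest report id; the operation is idempotent.

### Partial dates

Report, treatment-start and onset dates are kept as `"YYYY"`,
`"YYYY-MM"` or `"YYYY-MM-DD"` strings at their stated precision.
Interval tests (analysis windows) coerce a partial date to the *earliest*
consistent day — inclusive and deterministic — while day-level arithmetic
(TTO) is computed only from day-complete dates and is otherwise missing,
never imputed. Analysis windows run per drug from its
marketing-authorisation date to the common window end, anchored on the
report date (onset dates are too often missing to anchor on).

## Time to onset

TTO is onset date minus treatment start date in whole days. The start
date is the earliest day-complete start among the drug's
suspected/interacting entries (a re-challenge therefore anchors on the
first course); the onset is the earliest day-complete onset among the
event PT's entries. Negative differences are implausible, logged, and
returned missing. Summaries report the available-n explicitly — a median
of n cases "with available data" is the honest denominator when dates are
incomplete. The median of an even-sized sample is the mean of the two
central order statistics; Q1/Q3 use linear interpolation of order
statistics (`stats::quantile` type 7). Published tables rarely state
their quartile convention, so the type is configurable and printed
quartiles from other software should not be expected to match to the
digit. The empirical CDF export steps at each distinct day value with
fraction `count(<= v)/n` and always ends at 1.

## Descriptive tables

Three denominators coexist in a cohort description and are kept explicit
in every output block: number of cases (reports), number of study-drug
mentions across cases, and number of qualifying event-PT mentions across
cases — one case can mention two study drugs and several renal PTs, so
these differ. Percentages are rounded half-up to one decimal (the
convention of typeset tables; base R's round-half-to-even disagrees on
exact halves), ties in top-k blocks break alphabetically, and
"before `era_cut`" pools early reporting years.

## The synthetic generator

`synth_config()` / `generate_database()` emulate the *structure* of a
large pharmacovigilance database: multi-drug, multi-reaction reports, a
reporter-type mix, missing demographics, partial dates, and exact-clone
duplicates with shifted dates. Events follow a multiplicative-odds
model: for PT with baseline reporting probability $p_0$,

$$\mathrm{odds}(p) = \mathrm{odds}(p_0) \cdot \prod_{\text{drug } j}
\theta_{j,\mathrm{pt}}$$

over the drugs the report carries with a suspected/interacting role and
a planted $\theta$. This is the simplest composable choice and makes the
planted $\theta$ exactly the odds ratio the pipeline should recover.
Exposures are independent across drugs by default (no co-prescription
correlation), clones are exact copies, and country/indication joint
structure is not modelled — so passing tests demonstrate estimator
correctness and pipeline integrity, not robustness to masking,
notoriety bias or fuzzy duplicates, which real data exhibit.

Defaults describe a six-drug anti-EGFR oncology slice: the real
marketing-authorisation dates, renal event PTs at low baseline rates
with relative frequencies shaped like a renal-safety case series, ~28
background oncology PTs (~80% of reports draw at least one; the rest
receive one sampled background PT so every report has a reaction),
85% health-professional reporters, 5–8% missing demographics, 15%
partial start/onset dates, 2% duplicates, and ages ~N(66, 12²) truncated
to [18, 100]. Time to onset is planted per (drug, PT) as a log-normal
with stated median (days) and log-scale sigma.

## Validation by parameter recovery

The exact comparator counts behind published RORs from access-restricted
databases are unpublished, so correctness is validated by parameter
recovery: `simulate_ror_recovery()` plants a known odds ratio via the
exposed/unexposed event probabilities, runs the *full* pipeline
(generate → eligibility → window → screen) per replicate, and averages
the ROR point estimates. The package's own validation uses:

* **Headline recovery** — six planted odds ratios (2.70, 1.73, 2.41,
  1.42, 4.01, 4.94) against an unexposed event probability of 0.02;
  25 replicates each. The reproduction script uses 50,000 expected
  exposed and 500,000 unexposed reports per replicate; the test suite
  runs the same design at half scale (25,000 / 250,000), where the
  Monte-Carlo standard error of the replicate mean is still several
  times smaller than the 2% agreement band.
* **General recovery** — $\theta \in \{0.5, 1, 2, 5\}$ sized for ~500
  expected cases per replicate, 25 replicates, 2% band.
* **Null calibration** — $\theta = 1$ at a small expected case count
  (~10), 500 replicates: the SDR rate must stay within the one-sided
  2.5% implied by the 95% CI construction plus three Monte-Carlo
  standard errors.
* **Formula oracle** — on 200 random tables the estimates must equal an
  independently coded `ad/bc` and Woolf interval to floating tolerance,
  and satisfy inversion (`ROR(c,d,a,b) = 1/ROR(a,b,c,d)`) and transpose
  invariance.

The recovery simulations draw fully observed reports (all
health-professional, complete demographics, no planted duplicates); the
eligibility stage still runs, but duplicate removal is disabled there
since nothing is planted and the rule is exercised by its own dedicated
fixtures.

## Design decisions that were genuinely open

* **Threshold reading** — "minimum of five cases" is implemented as
  `a >= 5`; the alternative strict reading is available via
  `min_cases`.
* **Comparator filtering** — eligibility is applied to the whole
  database, not only to cases, for internal consistency of the 2×2;
  flags allow the other behaviour.
* **Window anchoring** — the report date, not the onset date, places a
  report inside a drug's analysis window.
* **Dedup key** — an artifact-defined stand-in for proprietary record
  linkage; both key fields and the 30-day tolerance are configurable.
* **Quartile convention** — type 7, configurable, documented as a
  source of digit-level disagreement with other software.
* **Multiple drug courses** — the earliest start date anchors TTO; the
  earliest qualifying onset is used when a case reports the event PT
  more than once.

## Limitations

Disproportionality emits signals, not risk estimates; nothing here
quantifies incidence. The generator does not model under-reporting
heterogeneity, stimulated reporting, co-prescription correlation (a
masking knob is a natural extension), or realistic country/indication
joint distributions. No multiplicity adjustment is applied across the
screened pairs, matching standard practice for this design. PRR,
Bayesian shrinkage estimators (IC/EBGM) and censoring-aware TTO models
are out of scope.
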