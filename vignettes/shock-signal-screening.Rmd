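---
title: "Screening spontaneous reports for drug-associated shock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening spontaneous reports for drug-associated shock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shockscreen)
```

## The problem

Spontaneous-report databases such as the FDA Adverse Event Reporting
System (FAERS) collect voluntary reports of suspected adverse drug
reactions. They have no denominator of exposed patients, so drug safety
signals are screened by *disproportionality*: for each drug--event pair,
the observed co-reporting frequency is compared with the frequency
expected if drug and event were reported independently within the same
database. shockscreen implements this screening workflow for
shock-related adverse events — an acute, frequently fatal class of
reactions spanning cardiogenic, septic, anaphylactic, hypovolemic and
related presentations — together with the ingestion, deduplication and
descriptive machinery around it, and a spontaneous-report simulator with
planted ground truth so that every stage can be validated end to end.

All statistics operate on the report-level 2x2 table

| | target event | other events |
|---|---|---|
| target drug | a | b |
| other drugs | c | d |

with margins $N_{drug} = a+b$, $N_{effect} = a+c$, $N_{total}=a+b+c+d$,
$N_{observed} = a$ and $N_{expected} = N_{drug}N_{effect}/N_{total}$.

## From raw quarterly files to an analysis cohort

FAERS ships as "$"-delimited quarterly ASCII tables (DEMO, DRUG, REAC,
OUTC, DELE, and THER/INDI/RPSR, which are accepted and ignored here). A
case (CASEID) may have several submitted versions (PRIMARYIDs);
`deduplicate_cases()` keeps, per CASEID, the version with the most
recent FDA_DT, breaking date ties by the highest PRIMARYID (numeric
comparison when the identifiers parse as numbers, lexicographic
otherwise; unparseable dates sort lowest and are never preferred).
Deletion lists are applied after deduplication at CASEID granularity.
Reports are then restricted to healthcare professionals
(OCCP_COD in MD, PH, OT), ages are converted to years from their unit
codes with values above 120 years set to missing (real shock cohorts
carry artifacts such as a recorded age of 5200), drug names are trimmed,
case-folded and passed through an exact-match synonym map standing in
for a licensed drug dictionary, and shock events are flagged by
case-insensitive match against a preferred-term set.

The bundled term set (Shock, Cardiogenic shock, Septic shock,
Anaphylactic shock, Hypovolemic shock, Distributive shock, Circulatory
collapse, Neurogenic shock, Obstructive shock, Toxic shock syndrome) is
a surrogate for the licensed standardised MedDRA query covering shock;
it is a plain-text, one-term-per-line resource so a licensed query can
be dropped in via `read_term_set()`.

Two conventions are deliberate design choices rather than published
rules:

* **Seriousness** — a report is serious when it carries at least one
  outcome row, since every FAERS outcome code (DE, LT, HO, DS, CA, RI,
  OT) denotes a serious outcome.
* **Exposure roles** — primary suspect, secondary suspect and
  concomitant drugs all count as exposure by default (`roles` argument
  of `build_cohort()`); restricting to suspects is a one-argument
  change.

The counting unit everywhere is the deduplicated report: a report
contributes once to one cell of each drug's table, multiple mentions of
a drug collapse, and multiple shock terms in one report count once for
the `any_shock` scope. This avoids the double counting that
event-row-level tables would introduce (a shock cohort can easily carry
~14% more event rows than reports).

## The four disproportionality methods

For each drug with at least `min_a = 3` shock co-reports:

* **ROR** (reporting odds ratio): $ROR = ad/bc$,
  $SE(\ln ROR) = \sqrt{1/a+1/b+1/c+1/d}$, 95% Wald interval on the log
  scale. Signal: $ROR > 1$ and lower bound $> 1$.
* **PRR** (proportional reporting ratio):
  $PRR = \frac{a/(a+b)}{c/(c+d)}$,
  $SE(\ln PRR) = \sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}$, with the
  uncorrected chi-squared
  $\chi^2 = \frac{(ad-bc)^2\,N_{total}}{(a+b)(a+c)(c+d)(b+d)}$ (no
  Yates continuity correction). Signal: $PRR > 2$ and $\chi^2 \ge 4$.
* **BCPNN information component**: the closed-form credibility-interval
  variant
  $IC = \log_2\frac{N_{observed}+0.5}{N_{expected}+0.5}$ with
  $IC_{025} = IC - 3.3(N_{observed}+0.5)^{-1/2} -
  2(N_{observed}+0.5)^{-3/2}$ and
  $IC_{975} = IC + 2.4(N_{observed}+0.5)^{-1/2} -
  0.5(N_{observed}+0.5)^{-3/2}$. Signal: $IC_{025} > 0$. The
  expectation/variance variant ($E(IC)$, $V(IC)$, $IC - 2SD$) under the
  standard priors $\alpha_1=\beta_1=1$, $\alpha=\beta=2$,
  $\gamma_{11}=1$ is computed and reported alongside for comparison,
  but the credibility bound drives the flag: the two lower bounds agree
  closely except in very sparse tables, and the closed form is the one
  commonly used for the $IC_{025}>0$ criterion.
* **EBGM**: the closed relative-reporting-ratio form
  $EBGM = aN_{total}/((a+c)(a+b)) = N_{observed}/N_{expected}$ with
  $SE(\ln EBGM) = \sqrt{1/a+1/b+1/c+1/d}$ and the 90% lower bound
  $EBGM_{05} = \exp(\ln EBGM - 1.645\,SE)$ driving the signal rule
  $EBGM_{05} > 2$ (the symmetric 95% interval is also emitted). This is
  *not* a fitted multi-item gamma Poisson shrinker: no gamma-mixture
  prior is estimated, so for very sparse tables the closed form
  shrinks less than a full empirical-Bayes fit would. The gamma-mixture
  fit is deliberately out of scope.

Zero cells make ROR, PRR and EBGM undefined; such results carry an
explicit `NA` with the cause in a note column and can never flag. The
IC and omega forms are smoothed and always defined.

Combined tiers count the positive methods: `none` (0), `weak` (1--2),
`three_method` (3), `four_method` (4). No multiplicity correction is
applied — the screen is hypothesis-generating by design — but the
number of tests performed is recorded on the result
(`attr(signals, "n_tests")`).

A caveat documented here because it is easy to trip over: the shrunk
statistics (IC, EBGM) are *not* monotone in `a` for arbitrary tables —
when the target drug or event dominates the database, $N_{expected}$
grows faster than $N_{observed}$ and both can decrease as `a` rises. In
the sparse regime that disproportionality assumes
($d \gg a+b+c$, $a \le \min(b, c)$) all four statistics are
nondecreasing in `a`, and the property tests assert exactly that
regime.

## Omega screening of drug pairs

Pairs of co-administered drugs are screened with the smoothed,
shrinkage-adjusted odds ratio

$$\Omega = \frac{(a+0.5)(d+0.5)}{(b+0.5)(c+0.5)} \times
\text{shrinkage factor},$$

where exposure is the co-occurrence of *both* drugs in a report and the
interval is Wald on the log scale with
$SE = \sqrt{\sum_{cell}1/(cell+0.5)}$. Values above 1 suggest a safety
signal; a pair is flagged when its lower bound exceeds 1 and it has at
least `min_a` shock co-reports. Two design decisions are worth
flagging:

* The +0.5 smoothing is treated as the operative shrinkage and the
  multiplicative `shrinkage_factor` defaults to 1; it is kept as a
  configuration hook for prior-based calibrations.
* The pair table is an ordinary 2x2 with "both drugs present" as
  exposure. The three-way interaction contrast of the omega literature
  (observed pair count against an additive expectation built from the
  single-drug effects) is *not* implemented; the 2x2 form means a pair
  of drugs that are each individually associated with shock will show
  an elevated omega even without a genuine interaction. The simulator's
  `interaction_only` plantings are the tool for checking that truly
  interaction-driven pairs surface.

Pair enumeration is capped before any statistic is computed: only pairs
co-occurring in at least `min_a` target-event reports are evaluated,
which bounds the combinatorics at roughly the square of the number of
drugs appearing in shock reports. Ranking is by shock co-report count,
then omega, then the lexicographic pair name, making the top-30 list a
pure function of cohort and configuration. Smoothing contracts toward
the null in the limit (as $s \to \infty$, $\Omega \to 1$) and provably
on symmetric-margin tables, but *not* uniformly: for extremely
unbalanced tables with the odds ratio near 1, adding 0.5 to every cell
can move the estimate away from the null. The property suite asserts
the provable contractions only.

## The simulator and what passing tests mean

`simulate_faers()` generates the five table kinds the pipeline consumes,
with the structural features the pipeline must survive: duplicate case
versions (later versions get a strictly larger FDA_DT with probability
0.8, an equal date with a larger PRIMARYID otherwise, so both
deduplication tie rules occur), quarterly deletion lists, occupation
codes, missingness in sex/age/country, age unit codes (YR, MON, DY) with
occasional implausible 5200-year entries, Zipf-distributed drug
exposure sampled without replacement within a report, independent
background event terms, and planted signals.

A planted signal multiplies one event term's baseline probability among
exposed reports (capped at 1); `event_term = "any_shock"` applies the
multiplier to every shock term, which is what a drug-level shock signal
means. For pair exposures, `interaction_only = TRUE` boosts only
reports carrying both drugs. Co-exposure beyond the planted pairs
arises only by chance, keeping interaction truth identifiable.

Default study conditions: 50,000 cases, 100 drugs, Zipf exponent 1,
~2% shock prevalence dominated by the generic "Shock" term, 5%
duplicated cases (up to 3 versions), 0.5% deletions, 90% healthcare
professional reporters, sex/age/country missingness of 10.5%/19%/30%,
99.26% serious, four quarters. The signal scenario plants ten
single-drug signals at relative rate 5 and two interaction-only pairs
at relative rate 6. Planted single-drug exposures sit at popularity
ranks 51--96: with only 100 drugs, planting strong signals on the most
popular drugs would put a large share of all reports under a boosted
shock rate and contaminate the comparator cells — an artifact of the
small universe, not of spontaneous reporting, where any single drug
holds a tiny share of the database. At these ranks each planted drug
still accrues an expected 20--45 shock co-reports, comfortably above
the `min_a = 3` inclusion rule. The two planted pairs sit on popular
drugs (ranks 2+5 and 4+6) because chance co-exposure, which scales with
the product of the two popularities, is what gives an
interaction-only signal enough co-reports to be detectable at all.

What the simulator does *not* emulate — and therefore what passing
tests cannot show about real FAERS data: correlated reporting
(stimulated reporting waves, duplicates with altered content),
drug-name misspellings beyond exact synonyms, indication confounding
(drugs prescribed *for* conditions that themselves cause shock, e.g.
vasopressors in septic patients), event-term migration across MedDRA
versions, and reporting-rate drift over calendar time. Recovery of
planted signals demonstrates that the statistical machinery is
implemented correctly, not that the criteria have any particular
sensitivity or specificity in the real database, where no reference
standard exists.

## Descriptive summaries and evaluation

`summarize_cohort()` emits the characteristics table (gender, age
group at the conventional boundaries 18/45/65, reporting year,
reporter occupation, region, country, seriousness) with percentages
rounded half-away-from-zero — base R's round-half-to-even would differ
on exact halves, and a fixed convention keeps the tables reproducible.
Continuous age uses quantile type 7 (inclusive linear interpolation)
for the quartiles; the convention is stated because published tables
rarely say which one they used.

`evaluate_methods()` scores each method and the combined rules against
the planted truth: a drug is condition-positive when it carries a
planted single-drug signal with relative rate above 1. Confusion
counts conserve the number of screened drugs by construction, and the
all-four conjunction can only lose positives, so its specificity
dominates every single method's — a structural fact the tests assert
as a sanity check, not a finding. `aggregate_by_atc()` distributes
signal drugs (three or more positive methods by default) over ATC
level-1 classes via a user-supplied map, with a bundled demonstration
map covering the synthetic universe; shares are computed over
contributions, so multi-coded drugs count in each of their classes and
shares still sum to 100 within rounding.

## Problem sizes and numerical choices

The validation suite runs the full pipeline on 50,000-case corpora, 20
independent seeds each for the null-calibration and signal-recovery
studies; oracle-equivalence checks use 1,000 random tables with cells
up to 10^4 compared at relative error 10^-12 against straight-line
transcriptions of the formulas. Cell products in the chi-squared
statistic overflow 32-bit integers near the upper end of that range,
so all statistics are computed in double precision from the outset.
Deterministic outputs (ordering, file bytes, report bundles) are exact
re-run invariants given a seed.

## Limitations

* The EBGM and omega estimates use closed forms, not fitted priors;
  both under-shrink very sparse tables relative to their fully
  Bayesian counterparts.
* The pair screen cannot separate interaction from the union of two
  main effects (see above).
* The bundled shock term set, region map, synonym map and ATC map are
  small surrogates for licensed resources and should be replaced for
  any real analysis.
* Time-stratified, sex-stratified and dose/latency analyses are out of
  scope, as are MedDRA hierarchy traversal and fuzzy drug-name
  matching.
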