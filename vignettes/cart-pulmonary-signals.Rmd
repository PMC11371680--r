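---
title: "Disproportionality analysis of CAR-T pulmonary adverse events in FAERS-format data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis of CAR-T pulmonary adverse events in FAERS-format data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartpv)
```

## The problem

Chimeric antigen receptor T-cell (CAR-T) therapy is strikingly effective in
haematological malignancies but carries substantial toxicity. Pulmonary
adverse events (PAEs) — hypoxia, respiratory failure, pleural effusion,
tachypnoea and related conditions — are clinically prominent (hypoxia
severity is part of the consensus grading of cytokine release syndrome) yet
were long without a systematic post-marketing characterisation. Spontaneous
reporting databases such as the FDA Adverse Event Reporting System (FAERS)
are the standard resource for this kind of question: they contain millions
of suspected drug–event reports but no denominator of exposed patients, so
the signal-detection workhorse is *disproportionality analysis* — comparing
how often an event is reported with the target drug against how often it is
reported with everything else.

`cartpv` implements that workflow end to end for the six approved CAR-T
products (Axi-cel, Tisa-cel, Brexu-cel, Liso-cel, Ide-cel, Cilta-cel)
against pulmonary events, on data in the FAERS quarterly ASCII format, with
a seeded synthetic generator so every stage is testable without downloading
FAERS itself.

## Data model and preprocessing

A FAERS quarterly package is a set of "$"-delimited tables sharing a report
identifier (PRIMARYID): DEMO (demographics and receipt dates), DRUG (one
row per drug with a role code), REAC (one row per reported reaction, coded
as a MedDRA preferred term, PT), OUTC (outcome codes), THER (therapy
dates), INDI (indications). Columns are resolved from the header line
rather than by position, because the field set drifted across the
2017–2023 packages; files are decoded as Latin-1 with replacement since
real FAERS files contain non-UTF-8 bytes; ragged lines are right-padded,
counted and reported rather than fatal.

**Deduplication.** A case (CASEID) accumulates report revisions
(PRIMARYIDs) across quarters. Following the FDA rule, the report with the
latest receipt date (FDA_DT) is kept per case, ties broken by the higher
PRIMARYID (compared numerically when all ids are digit strings; the legacy
"ISR number" plays the same role in old-format data and is treated as
synonymous). Afterwards, any case appearing on a quarterly deletion list
(distributed since 2019Q1) is removed entirely. Records without a
parseable receipt date are excluded and counted: the retention rule is
undefined without a date.

**Cohort extraction.** Reports enter the CAR-T cohort when any *suspect*
drug (role `PS` or `SS`; configurable — concomitant-only mentions do not
qualify) matches the product synonym dictionary by case-insensitive
substring containment. The dictionary covers trade names, generic names
and development codes. One synonym, "autoleucel", occurs in two generic
names; product assignment therefore prefers the longest synonym matched in
each drug string, and reports that remain ambiguous stay in the cohort but
are excluded (and counted) from per-product stratification. PAEs are
reactions whose PT maps to the system organ class "Respiratory, thoracic
and mediastinal disorders"; the PT-to-SOC mapping is user-supplied because
MedDRA is licensed (the packaged `pt_soc_map_synthetic.tsv` is a
demonstration stand-in covering the generator's catalogue, not MedDRA, and
the mapping's version string is recorded in the run manifest).

**Counting units.** Event totals count (report, PT) pairs — one patient
can experience several events — while demographic tables and fatality
denominators count reports. Both counters are exposed in the manifest.

## The four algorithms

Every screened term gets a 2×2 table against the full remaining database:
`a` = target-drug reports with the event, `b` = target-drug reports with
other events, `c`/`d` = the same split among all other reports, `N = a+b+c+d`
(counted in (report, PT) pairs). With `E = (a+b)(a+c)/N`:

* **ROR** `= ad/bc`, 95% CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`;
  flagged when the lower bound exceeds 1.
* **PRR** `= (a/(a+b))/(c/(c+d))` with
  `χ² = (ad−bc)²·N/((a+b)(a+c)(c+d)(b+d))` (no continuity correction);
  flagged when PRR ≥ 2 and χ² ≥ 4.
* **IC** `= log₂(a/E)`, flagged when its lower 95% bound (IC025) exceeds 0.
* **EBGM** `= a/E` with log-normal Wald CI; flagged when the lower bound
  (EBGM05) exceeds 2.

All flags additionally require `n = a ≥ 3`, and a **joint signal** requires
all four flags — a deliberately conservative AND rule. `EBGM = 2^IC` holds
identically for these closed forms; the suite verifies it, together with
equivalence of every statistic to an independent arithmetic oracle at
relative error below 1e−12 on 1,000 random tables.

Three numerical decisions were genuinely open:

* **IC interval.** The variance of the IC is not specified by the closed
  forms above, so the interval model is pluggable. The default is the
  closed-form credibility approximation for the *shrunk*
  observed-to-expected ratio,
  `IC025 = log₂((a+0.5)/(E+0.5)) − 3.3(a+0.5)^{−1/2} − 2(a+0.5)^{−3/2}`
  (and the analogous upper form), a widely used and reproducible choice;
  the alternative `"delta"` model places a delta-method interval with
  `sd = 1/(√a·ln 2)` around the unshrunk point. The model is recorded in
  the manifest. Note the credibility interval brackets the shrunk estimate
  (reported as `ic_shrunk`), not the unshrunk point — with few cases and
  extreme disproportion the printed IC can exceed IC975.
* **Zero cells.** No Haldane 0.5 correction by default, matching the
  printed closed forms; undefined metrics are reported as `NA` and force
  the joint signal false. The correction is available by flag, applied to
  all cells for estimation while `n` stays the raw count.
* **EBGM05 > 2** is stricter than much common practice (EBGM05 > 1 is
  also seen); it is implemented as stated and configurable via
  `signal_thresholds()`.

**Per-product stratification.** For each product × pulmonary term with at
least 3 cases, IC025 is computed with the comparator being every report
that does not contain that product (full-database background plus the
other cohort reports). Cells below 3 cases are absent, not zero — a
false-positive guard, since tiny `a` with a huge multiplier can otherwise
dominate a heatmap.

## Temporal and outcome summaries

* **Time to onset**: event onset date minus the earliest therapy start
  date among matched product drug rows. Partial dates (yyyymm / yyyy) are
  kept as typed partials and excluded with a reason, never silently
  completed to a day; negative differences are excluded likewise.
* **Quartiles**: Tukey inclusive hinges (base `fivenum()`), which yield
  the integer-day IQRs conventional in this literature; the convention is
  recorded in the manifest. Day 30 counts as "within 30 days".
* **Fatality**: deaths are reports carrying outcome code `DE`, regardless
  of adjudicated cause; serious outcomes are `DE`, `LT`, `HO`, `DS`.
  Proportions are kept at full precision, rounded to one decimal only for
  display.
* **Annual counts** bucket by FDA receipt year — the only universally
  present date in FAERS; event-date missingness is high.
* Age strata are `<18`, `≥18 and <65`, `≥65` after unit normalisation
  (days/365.25, weeks/52.18, months/12, decades×10, hours/8766; a missing
  unit with a non-missing age is read as years).

## The synthetic generator

`generate_faers()` emits complete quarterly packages with known ground
truth. Its defaults are the study conditions the package is tested under:

* receipt dates uniform over 2017-01-01 to 2023-09-30, the window in
  which all six products were on or entering the market;
* a cohort dominated by Axi-cel (400) and Tisa-cel (350) over the four
  later products, against 5,000 background reports — far below real FAERS
  scale, which is out of scope, but large enough for stable contingency
  tables;
* each report draws `1 + Poisson(0.6)` distinct reactions from a
  20-term catalogue, so multiple events per patient occur as in real data;
* planted signals are multiplicative: a (product, term) multiplier scales
  that term's sampling weight for that product's reports, so a
  multiplier-10 pair roughly multiplies its observed/expected ratio by 10;
* onset times are log-normal with `meanlog = log 2`, `sdlog = 2` —
  median 2 days and about 90% of onsets within 30 days, matching the
  clinical course of CRS-associated pulmonary toxicity concentrated in the
  first month;
* death probability 0.35 for cohort reports with a pulmonary event and
  0.10 otherwise, within the observed per-product fatality range;
* 10% of cases carry a superseded duplicate revision (earlier-or-equal
  receipt date, lower PRIMARYID, occasional date ties to exercise the
  tie-break), and 2% of post-2019Q1 cases land on their quarter's deletion
  list.

What the generator does **not** emulate: reporting biases beyond
multiplicative rates (no notoriety waves, no stimulated reporting),
correlated reactions within a report, free-text drug-name noise and
misspellings, country- or time-varying coding practice, and real FAERS
scale. Passing tests on synthetic data therefore demonstrate correctness
of the computational pipeline under known truth — not that the published
clinical findings generalise.

`cart_reference_fixture()` is different in kind: a fully deterministic
package (no random draws at all) engineered so that the post-deduplication
cohort reproduces published marginal counts — 9,400 adverse-event records
with 940 pulmonary (10%); per-product pulmonary case and death counts;
the pulmonary-column sex, country, reporter and age-stratum counts with
engineered median age 59 and IQR 30–69; and per-product hypoxia and
respiratory-failure totals. Each cohort report carries exactly one
reaction, which is what lets record counts and report counts coincide with
the published denominators simultaneously. Everything never published —
the per-product split of non-pulmonary reports (set to 9× the pulmonary
count per product), the 1,200-report background, all dates, the onset-day
pattern, and hence every contingency cell `b`, `c`, `d` — is a documented
synthetic choice: statistics computed from the fixture beyond the
engineered marginals are properties of the fixture, not published values.
That is also why the fixture's disproportionality screen itself is *not* a
reference result.

## A worked example

```{r example}
dir <- file.path(tempdir(), "synth_faers")
g <- generate_faers(synth_config(seed = 42, n_background = 1500,
  product_counts = c("Axi-cel" = 150, "Tisa-cel" = 120),
  signal_multipliers = tibble::tibble(
    product = c("Axi-cel", "Tisa-cel"), pt = c("Hypoxia", "Hypoxia"),
    multiplier = c(10, 10))), dir = dir)
g

run <- run_pipeline(run_config(dir))
run
tidy(run)[, c("pt", "n", "ror", "ror_lo95", "ic", "ic025", "joint_signal")]
glance(run)
fatality_by_drug(run$cohort)
summarize_tto(run$tto)
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(run$signals)
autoplot(run$ic_matrix)
```

## Determinism and problem sizes

Identical configuration and inputs give byte-identical CSV/JSON outputs:
the generator is driven entirely by its seed, the pipeline is
deterministic, and the manifest's configuration hash covers the
analysis-relevant settings (not filesystem paths). The test suite runs the
statistic oracle on 1,000 random tables, the deduplication oracle on 500
randomized records, planted-signal recovery on 100 replicates of a
920-report configuration, and the full pipeline on the ~10,600-report
reference fixture — sizes chosen to exercise every code path while keeping
the default suite under a minute on one CPU.

## Known limitations

* Spontaneous-report caveats apply in full: no exposure denominator, so
  disproportionality quantifies reporting, not risk.
* The EBGM here is the printed closed form (identical to `2^IC`), not the
  MGPS empirical-Bayes gamma-mixture shrinkage estimator; with small `a`
  it is anti-conservative relative to true MGPS.
* No multiple-testing correction is applied (none is standard in this
  workflow); the four-way AND rule is the only guard.
* PT-to-SOC mapping is exact-match after normalisation; no MedDRA
  hierarchy traversal (HLT/HLGT) or standardised MedDRA queries.
* Probabilistic duplicate detection across different CASEIDs is out of
  scope; only the FDA rule is implemented.
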