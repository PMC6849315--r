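---
title: "Methods: validating register procedure codes against chart review"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating register procedure codes against chart review}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regval)
```

# The estimands

A register validation study observes two renderings of the same surgical
history: the administrative register's procedure codes, keyed to hospital
admissions, and the patient chart's codes, keyed to operation days and taken
as gold standard. Writing $V$ for the number of code occurrences present in
both sources, $C \le V$ for the concordant ones, $N_{reg}$ and $N_{chart}$
for the per-source totals among analysed surgery-positive patients, and
$TN / N_{neg}$ for surgery-negative patients without any register code, the
package estimates

* $\mathrm{PPV}_{tp} = C / V$ (validated codes only),
* $\mathrm{PPV}_{all} = C / N_{reg}$ (all register codes; never exceeds
  $\mathrm{PPV}_{tp}$ since the numerator is shared),
* sensitivity $V / N_{chart}$,
* specificity $TN / N_{neg}$ (patient level — charts, not codes, are
  negative), and
* NPV conditioned on an explicit false-negative patient count $k$:
  $TN / (TN + k)$. Register-negative patients are not chart-reviewed for
  missed surgery in this design, so the NPV is only defined under such
  conditioning; the package derives two data-driven choices of $k$ — all
  patients carrying a register-missed code, and the subset with no register
  code at all.

Patients whose charts mention surgery too vaguely to validate contribute
codes of unknown verdict. `scenario_bounds()` brackets each statistic by
assuming all $k$ such codes discordant (lower) or concordant (upper); the
codes join the relevant denominator in both scenarios and the numerator only
in the upper.

# Matching model

Matching is strictly within patient. A register event (admission date $a$)
and a chart event (surgery date $s$) can describe the same surgical occasion
when $0 \le s - a \le w$; the window $w$ defaults to 7 days because the
delay from admission to surgery is short (median 1 day in the data the
default parameters emulate), and it is exposed as an argument because the
original reviewers matched by clinical context rather than a stated rule.
Codes are compared case-insensitively after stripping trailing `-` padding
(the notation used for wildcarded NOMESCO stems).

Two passes run after canonically sorting events by (patient, date, code),
which makes the result invariant to input row order:

1. **Exact-code pairs.** Within each code present in both sources, chart
   events are processed in date order and each takes the *earliest* unused
   feasible admission. Because the feasible admissions for a chart event
   form an interval $[s - w, s]$ whose endpoints move right with $s$, an
   exchange argument shows this greedy attains the maximum possible number
   of exact pairs. (Pairing at minimal delay instead is not maximal:
   admissions {day 0, day 3} with surgeries {day 3, day 10} and $w = 7$
   strand the second surgery. The test suite checks the greedy against an
   exhaustive maximum-matching oracle on all small instances.)
2. **Same-occasion discordant pairs.** Remaining chart events pair with
   remaining feasible admissions — the transfer-error candidates — again
   earliest-first, ties broken by register code text for determinism.

Leftovers become `chart_only` (code missed by the register) or
`register_only` (register code with no chart counterpart). Duplicate
identical codes pair one-to-one, never one-to-many, so every event lands in
exactly one match result and the tabulation margins are conserved by
construction. Discordant pairs are subtyped by a character-multiset test:
equal multisets indicate a transposition (the hand-copy slip of swapping
adjacent characters, e.g. `JFB64` vs `JBF64`), unequal multisets a
substitution. The subtype split is this package's refinement; only the
transposition mechanism is documented in the source material.

Stratified tables split the code-level counts by anatomic category
(resolved from the gold-standard chart code via the code list, falling back
to the register code for register-only results) or by coding era — the
register admission year, $\le 1996$ vs $\ge 1997$, the year the procedure
classification changed; chart-only codes have no admission date and use the
surgery year. Negative patients have neither category nor era, so stratum
tables carry zeros in the patient-level cells and stratified specificity is
not defined; the additivity invariant (strata sum to the pooled table)
applies to the code-level cells.

# Two-stage clustered bootstrap

Patients cluster within hospitals, and the accuracy statistics are ratios of
cluster-correlated counts. Confidence intervals therefore resample in strict
hierarchy: stage 1 draws $H$ hospitals with replacement from the $H$
observed; stage 2 draws, for each drawn hospital, $n_h$ patients with
replacement from that hospital's $n_h$; all of a drawn patient's code events
travel intact, and repeated draws are duplicated, never deduplicated. Each
patient belongs to exactly one cluster — the hospital of their earliest
event (ties to the lexicographically smallest id), with the patient table's
hospital as fallback for event-less (negative) patients.

The interval is the percentile interval of the replicate statistics at
levels $(1 \pm \gamma)/2$; percentile was chosen over BCa/studentized for
transparency and because the interval type is a swappable detail behind
`bootstrap_ci()`. Replicates where the statistic is undefined (a resample
can lack register codes entirely) follow a configurable policy: drop and
count (default — imputing 0 or 1 would bias small strata) or impute the
full-data point estimate. The default 10,000 resamples with a recorded
Mersenne-Twister seed make runs bit-reproducible. Since matching is
within-patient, a replicate's table is a sum of per-patient count
contributions; the bootstrap therefore resamples a precomputed count matrix
and never re-runs the matcher, which keeps 10,000 replicates around a
second at a 258-patient study size.

Two caveats are inherent to the design. First, with very few errors the
statistic can be degenerate: a study observing zero discordant codes
bootstraps to the interval $[1, 1]$ (exactly as an all-concordant stratum
prints `100 (100-100)`), and no resampling interval around such data can
cover a true value below 1. The coverage study in the test suite therefore
injects discordance at 5% — where 500 simulated studies of 30 hospitals
by 10 patients are a meaningful calibration check — rather than at the
study-scale rate of about 1.3%, where roughly one replicate study in eight
is degenerate. Second, published interval widths from other data are not
reproducible without the per-hospital distribution of patients and codes,
which is typically unpublished; point estimates, not CI endpoints, are the
reproduction targets.

# Reconstructing a study from its printed tables

`build_fixture()` turns a counts configuration — per (anatomic category,
coding era) cell: codes in both sources, concordant among them, chart-only
and register-only counts, plus patient-level totals — into an exact event
dataset: its matched tabulation reproduces every configured cell, overall
and per stratum. Choices a published table does not pin down are made
deterministically and do not affect any reported ratio:

* patients spread round-robin over the configured hospitals (the true
  allocation being unpublished), with one surgical patient's later occasions
  at a second hospital to exercise the earliest-event clustering rule;
* paired codes packed round-robin onto the surgical patients that have
  register codes; chart-only codes onto designated "missing-code" patients,
  a configurable number of whom carry nothing else (these counts drive the
  conditioned NPVs);
* occasions within a patient spaced 40 days apart so a 7-day window never
  couples distinct occasions; paired admissions precede surgery by one day;
* synthetic code vocabularies (4-digit tokens for the pre-1997 numeric
  system, letter-letter-letter-digit-digit tokens for 1997+) with the
  handful of real codes named in public footnotes, and a matching code list.

The default configuration encodes the published joint allocation consistent
with all printed row and column marginals. One printed inconsistency had to
be adjudicated: the stratified table's missing-code row (2/4/3 by anatomy)
conflicts with the prose footnote (six perianal and two abdominal among the
pre-1997 missing codes); the fixture follows the table, whose marginals the
denominators of the published ratios require.

# The synthetic-data generator

`simulate_dataset()` emulates the study conditions rather than any
particular dataset. Defaults (all overridable in `simulation_config()`):

* **258 patients, 27 hospitals**, hospital weights drawn from a gamma with
  shape 0.5 — small shape gives the strong size skew implied by a
  per-hospital code SD (13.2) more than twice its mean (6.1); the shape is a
  knob because the true hospital distribution is unpublished.
* **Surgery prevalence 0.20** (Bernoulli per patient).
* **Codes per surgical patient**: $1 + \mathrm{NB}$, moment-matched to mean
  3.1 / SD 4.5. A zero-truncated negative binomial cannot reach these
  moments — at mean 3.1 its SD is bounded near 3.5 (the logarithmic-series
  limit) — so the shifted family, which matches both exactly, is used.
* **Sessions**: each additional code opens a new surgical session with
  probability 0.43, targeting 1.9 sessions per surgical patient at 3.1
  codes; codes in one session share a surgery date and an admission.
  Sessions sit on a 60-day grid so a 7-day window never couples them.
* **Coding era**: each session is pre-1997 with probability 85/164 (the
  chart-code era split); vocabularies are era- and category-specific and
  constructed so that an adjacent transposition never collides with a
  vocabulary code.
* **Delays**: geometric on {0, 1, 2, ...} with mean 2.1 days (median 1). An
  optional `delay_cap` truncates the tail: with the cap at or below the
  matching window, pipeline verdicts agree with ground truth exactly and
  recovery against the analytic values is exact; uncapped (the default,
  i.e. the study condition), the tail beyond the window contributes a small
  calculable downward bias to sensitivity.
* **Error fates**, per chart code, mutually exclusive: omitted from the
  register with `p_miss` (default 9/164), transposed with `p_transfer`
  (default 2/155), else copied exactly; spurious register codes per patient
  are Poisson with mean `p_spurious` (default 3/258). Independence across
  codes is assumed — the emulated error counts are far too small to
  estimate any dependence.

Ground truth labels every chart code captured/missed and every register
code concordant/transfer/spurious, so `recovery_report()` can compare
estimates with analytic values: sensitivity $1 - p_{miss}$,
$\mathrm{PPV}_{tp} = (1 - p_{miss} - p_{transfer})/(1 - p_{miss})$,
specificity $e^{-p_{spurious}}$, and a ratio-of-expectations value for
$\mathrm{PPV}_{all}$.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: chart availability and exclusion mechanisms (all
simulated charts are available), within-hospital correlation of coding
quality, secular trends in error rates, duplicate-rich coding practices, or
any dependence between a patient's error fates. It is a calibration harness
for the estimators and the bootstrap, not a digital twin of a register.

# Numerical and interface choices

* Undefined ratios (zero denominators) return an explicit sentinel
  (`defined = FALSE`, `NA` point), never 0 — silent zeros would poison
  small-stratum bootstrap replicates.
* Display rounding is half-up to one decimal in percent, the convention of
  the reports this package renders; internal values are never rounded.
  (Published tables are not always internally consistent at the last digit —
  the reconstruction reproduces exact ratios, and its renderings can differ
  from a printed percent by one unit in the last decimal on
  exactly-half cells.)
* Files are UTF-8 CSV (TSV for code lists) with ISO-8601 dates and header
  rows; unparseable mandatory fields are row-level errors naming the line,
  never silently skipped. The patients file carries `hospital_id` and
  `chart_has_ibd_surgery` so that event-less negative patients can be
  clustered and counted.
* Code-list wildcards: `-` matches exactly one character; exact entries
  beat wildcard entries; lookups are total (unlisted codes are simply not
  IBD-related).
* Problem sizes in the shipped tests are chosen to make Monte-Carlo error
  negligible relative to each assertion: 500 simulated studies for CI
  coverage, 200 replicate studies for estimator bias, about $10^5$ codes for
  error-rate recovery (3 standard-error tolerances), and exhaustive oracle
  comparison on all matching instances up to 4 x 4 events.

# Known limitations

* The matcher assumes pre-coded chart events; it does not parse surgical
  notes, and it has no probabilistic linkage — identical patients ids are
  required across files.
* Era assignment for chart-only codes falls back to the surgery year; a
  register-keyed era is undefined for codes the register never recorded.
* The NPV is only as good as its conditioning; no chart review of
  register-negative patients is modelled.
* The percentile interval is first-order; for statistics pinned near 1 with
  few errors it degenerates (see above), and no BCa/studentized variants are
  provided.
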