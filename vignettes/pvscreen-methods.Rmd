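---
title: "Methods: disproportionality signal screening and downstream endpoint analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal screening and downstream endpoint analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvscreen)
```

## The problem

Spontaneous adverse-event reporting databases (FAERS and its peers) collect
voluntary case reports, each linking one or more drugs to one or more
reaction terms coded at the MedDRA preferred-term (PT) level. `pvscreen`
implements the analysis chain used to ask two questions about a base drug
and an adverse event — here, bevacizumab and treatment-emergent
hypertension, an event of special interest because its occurrence has been
proposed as a biomarker of anti-VEGF efficacy:

1. Is the event reported disproportionately often with the base drug
   (a *signal*)?
2. Among reports of the base drug, which co-reported drugs are associated
   with *fewer* event reports (an *inverse signal*), i.e. candidate
   modulators of the adverse event?

Downstream stages mirror how such a screening hit is then triaged: a
chart-review cohort comparison of tumour response (RECIST) and blood
pressure between users and non-users of the candidate drug class, a
two-group expression comparison on a pathway gene subset, and relative qPCR
quantification.

## Report ingestion and deduplication

Quarterly extracts are `"$"`-delimited DEMO/DRUG/REAC tables. Each report
instance carries a `report_id` unique to a submitted version and a
`case_id` shared by all versions of the same case (the primaryid/caseid
pair of the public extracts). Cases are re-reported over time, so counting
raw rows would double-count: `deduplicate()` keeps, per `case_id`, only the
rows belonging to the maximum version key, unions that version's drugs and
reactions into canonical sets, and breaks exact version ties toward the row
latest in file order (with a warning). Deduplication is idempotent and
always yields exactly one case per distinct `case_id`.

Drug names are matched exactly after canonicalization (uppercase, trimmed,
whitespace-collapsed), optionally through a user-supplied verbatim-to-
ingredient synonym table. There is deliberately no fuzzy matching: exact
matching is deterministic and reproducible, at the cost of sensitivity to
uncurated verbatims. Event definitions are plain-text PT lists; the bundled
10-term hypertension list is a stand-in for the licensed standardized query
(SMQ 20000147) and should be replaced by the licensed list where available.
Ages are converted to years at read time from the unit code (`YR`, `DEC`,
`MON`, ...); unconvertible ages become missing.

## The reporting odds ratio

Reports are cross-classified into the four groups `a` (base drug + event),
`b` (base drug, no event), `c` (event, no base drug), `d` (neither). The
reporting odds ratio is

$$\mathrm{ROR} = \frac{a/b}{c/d}, \qquad
  95\%\ \mathrm{CI} = \exp\!\left(\ln \mathrm{ROR} \pm 1.96
  \sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right).$$

Conventions, chosen to match disproportionality practice:

* at the default `alpha = 0.05` the critical value is **exactly 1.96** (as
  printed in the literature), not `qnorm(0.975)`; other alphas use the
  precise quantile;
* a zero cell triggers the Haldane–Anscombe correction (add 0.5 to all four
  cells) under the default policy, flagged `corrected = TRUE`; policy
  `"error"` refuses instead. The published tables never hit a zero cell;
* classification: lower CI limit > 1 is a *positive* signal, upper limit
  < 1 an *inverse* signal, otherwise *none*;
* a two-sided Fisher exact p-value accompanies every estimate. It is
  computed by summing hypergeometric probabilities no larger than the
  observed table's (ties detected with a 1e-7 relative guard against
  floating-point noise on symmetric tables). The implementation is written
  in log space and is verified against a brute-force enumeration oracle on
  every 2×2 table with total at most 60;
* ROR and CI are rounded to 2 decimals only at the presentation layer.

Stratified analyses repeat the computation within sex strata (`M`, `F`) and
age bands (`<40`, `40-49`, `50-59`, `60-69`, `70-100`, bounds inclusive as
labelled). Reports with a missing stratifier fall in **no** stratum, so
stratum totals are smaller than the grand total — this matches how the
published strata fail to sum to the total. A stratum with an empty margin
is flagged `insufficient` rather than corrected into a meaningless
estimate.

## The comedication screen

`screen_comedications()` restricts to reports listing the base drug and,
for every other drug co-reported on at least `min_coreports` of them,
forms the within-base 2×2 table (candidate present vs absent × event vs
not) and computes the ROR machinery above. The default
`min_coreports = 100` suppresses unstable tiny-cell odds ratios; the
published candidates have 429–898 co-reports, comfortably above it. Rows
are sorted by ascending ROR with alphabetical tie-break, making output
deterministic. No multiplicity adjustment is applied — the screen is
hypothesis-generating, and that matches the source presentation — but
`screen_summary(qvalues = TRUE)` annotates Benjamini–Hochberg q-values for
users who want them. `direction = "both"` disables the class filter
entirely (every candidate passing the count threshold is returned); the
default returns inverse signals only.

This is signal screening, not causal inference: no confounding adjustment,
no indication-bias correction. An inverse signal is a lead, not an effect
estimate.

## Chart-review endpoint statistics

* **RECIST (v1.0) classification** from lesion diameter sums: CR when the
  current sum is 0, PR at ≥30% decrease from baseline, PD at ≥20% increase
  over the nadir, SD otherwise; both cutoffs inclusive; PD beats PR when
  both trigger. The thresholds come from the RECIST 1.0 standard (the
  source applies the standard without restating numbers).
* **ORR / DCR**: (CR+PR)/n and (CR+PR+SD)/n per arm; percentages are
  rounded to the nearest integer at presentation (90%/69% in the reference
  cohort). The between-arm test follows the stated selection rule: Fisher's
  exact test when any observed cell is below 5, Pearson chi-square without
  continuity correction otherwise (the chosen test is always reported).
  Chi-square without Yates matches the stated rule's intent; R's default
  correction would silently change the statistic.
* **Mann–Whitney U** with midranks; exact p from the null distribution of
  U when the combined n ≤ 20 and there are no ties, otherwise the normal
  approximation with tie and continuity corrections.
* **Hypertension event flag** (CTCAE-style): a rise of ≥20 mmHg over
  baseline, any on-treatment systolic ≥150 mmHg, or antihypertensive
  initiation/increase. The source text prints "<20 mmHg", which cannot
  define a hypertension event; it is implemented as ≥20 and the thresholds
  are exposed as arguments rather than silently hard-coded.
* **SBP change summary**: per-arm mean ± SD of before, after and delta;
  between-arm comparison of per-patient deltas by Mann–Whitney. Baseline is
  the measurement before the first dose (pressures are recorded before
  each cycle).

## Expression comparison and qPCR quantification

`pathway_compare()` takes an already-log2 expression matrix (no
preprocessing is attempted) and a pathway gene list — the bundled list
covers the VEGF signalling pathway (KEGG map04370) keyed by the gene titles
of the reference analysis plus standard symbols. Per gene it reports both
group means on the log2 scale and the original-scale fold change
`2^(meanA − meanB)`, with a two-sided t-test on the log2 values. Welch
(unequal-variance) is the default because reference group sizes are very
unequal (n = 32 vehicle vs n = 3 treated in the emulated series); pooled is
available by flag. The reference table's values (e.g. 11.57 vs 11.07 for
VEGF) are treated as group means of log2 intensities — they are implausible
as an original-scale ratio pair — and the "inverted to the original scale"
sentence of the source is implemented as the fold-change transform; both
scales are emitted so either reading is available.

`ddct()` implements relative quantification: per sample
`dCq = Cq_target − Cq_reference` (reference defaults to 36B4), per
condition `ddCq = mean dCq − mean control dCq`, relative expression
`2^(−ddCq)`, SEM over per-sample fold changes. A constant plate offset
cancels exactly. `dunnett_test()` performs many-to-one comparisons against
a shared control under equal-variance pooling, adjusting the family-wise
error by Monte-Carlo sampling of the max-|t| null (default 1e5 draws;
Monte-Carlo error ≈ 0.003). The draws share one pooled-variance deviate
across comparisons — the correlation structure the Dunnett statistic
requires — and group draws are consumed in a fixed order so that, under a
common seed, the adjusted p is monotone in the number of comparisons.
Adjusted p-values are floored at the unadjusted t p-value.

## The synthetic world

The generators are pure functions of config + seed (byte-identical reruns)
and write truth sidecars so every estimate can be checked against the
parameters that generated it.

**Reports** (`gen_reports`): exposure to the base drug is Bernoulli
(default prevalence 0.1); the event is Bernoulli with odds
`p0/(1−p0) × OR_base^exposed × Π OR_j^comed_j` — multiplicative on the odds
scale, so the true conditional odds ratio *is* the configured multiplier
and parameter-recovery tests are well defined. Defaults state the reference
world: baseline event probability 0.05 and base-drug odds ratio 2.45 (the
published total signal). Comedications occur only among base-drug reports.
Noise drugs come from a Zipf-weighted pool (frequency ∝ 1/rank, emulating
the long-tailed drug frequency distribution of real extracts); every case
gets ≥1 noise drug and ≥1 noise reaction so sets are never empty.
Demographics: Normal(62, 15) age clamped to 18–100 with 10% missing, sex
M/F with 5% unknown. Duplication re-reports a case with probability 0.05,
adding `1 + Geometric(0.5)` *earlier* versions (possibly with incomplete
drug lists); truth is drawn before duplication, so the deduplicated output
is independent of the duplication rate — a tested invariant. What this
world does **not** emulate: stimulated reporting, the Weber effect,
indication channelling, correlated polypharmacy. A green recovery test
establishes estimator correctness under the stated model, not robustness to
reporting biases.

**Fixture mode** (`fixture_reports`, `gen_cohort(fixture = TRUE)`) is a
separate deterministic code path that reproduces the embedded published
counts exactly rather than in expectation. Only marginal counts are
published, so sex, age and comedication status are assigned by position
within each exposure-by-event cell; every published margin is reproduced
exactly and the unidentified joint distribution is irrelevant to all
statistics computed from the set. List columns share storage, so the full
3.7-million-report set builds in seconds.

**Cohort** (`gen_cohort`): arm sizes 42/16; response multinomials, SBP
baselines (130 ± 15.3 / 120 ± 5.4 mmHg) and deltas (13.55 / 13.94 mmHg,
SD 5) default to the reference cohort's reported values. Fixture mode emits
the published response and covariate counts exactly, with constant per-arm
SBP values (the published means); the published SDs appear only in
stochastic mode. Two covariate counts in the source are internally
inconsistent (performance-status counts summing to 44 in a 42-patient arm;
regimen percentages); the fixture uses count-consistent values (21/21/0)
and the counts, not the percentages.

**Expression** (`gen_expression`): `Normal(baseline_g + shift_g·1[group],
sigma)` with baselines Uniform(5, 12) and default sigma 0.2 on the log2
scale — a typical residual SD for within-study microarray replicates.
Default 3 vs 3 samples (the reference series' 32 vehicle samples are
unusual for this design; n is configurable).

## Validation thresholds and their stated worlds

* **CI coverage**: 1,000 replicates at true OR = 1, n = 20,000 cases;
  the 95% Wald CI must cover 1 in 95% ± 2%. With the default prevalence and
  event rate the expected exposed-event cell is ≈100, where the Wald
  interval is well calibrated.
* **Parameter recovery**: 500 replicates at OR = 2.45, n = 50,000; the mean
  log-ROR must sit within 0.02 of log 2.45 (Monte-Carlo SE of that mean is
  ≈ 0.002, so the band tests bias, not luck).
* **Planted inverse signal**: the criterion fixes the within-base odds
  ratio (0.5), the co-report count (~600) and "base event rate 5%", but not
  the base-cohort size — and the recovery probability depends strongly on
  it. This package states the world at the published screen's scale:
  ~28,000 base-drug reports with a 5.42% event rate and candidate
  prevalence 0.0212 (exactly the omeprazole row's setting), where recovery
  is ≈88%. At a 2,000-report base cohort the same planted effect is
  recovered only ~70% of the time; the threshold (≥80% of 200 runs) is
  unattainable there. The interpretation was fixed on fidelity grounds
  (the screen the thresholds describe is the published one) and recorded
  before the test was frozen.
* **Expression calibration**: with no planted effects, per-gene Welch
  p-values at n = 5 vs 5 pass a Kolmogorov–Smirnov uniformity test at the
  0.01 level in ≥95 of 100 seeds; with a noiseless +0.5 log2 shift the fold
  change is 2^0.5 exactly.

## Numerical choices and degenerate inputs

* Fisher ties: probabilities within a 1e-7 relative factor of the observed
  table's count as equal (both in the implementation and the enumeration
  oracle); agreement is asserted to 1e-12.
* `mann_whitney_u` returns p = 1 when the variance collapses (all values
  tied).
* `compare_categorical` refuses tables with an all-zero row or column;
  `response_rates` reports no test (rather than an error) when the
  responder table has an empty margin, e.g. an all-responder cohort.
* `classify_recist` checks CR (current sum 0) before PD: a zero sum cannot
  exceed the nadir by 20% under valid inputs, and CR is the stronger
  statement.
* Empty report sets yield an all-zero contingency table; `ror()` then
  refuses (sum must be positive) rather than returning NaN.
* Pipeline exit discipline: configuration errors abort before any work;
  missing stage inputs raise data errors; any other stage failure keeps
  partial artifacts next to a `FAILED` marker and a manifest with
  `status: "failed"`.

## Known limitations

* The bundled hypertension term list is a reproducibility stand-in, not the
  licensed 10-term query; results on real extracts depend on the licensed
  list.
* Exact-match drug normalization will under-count exposures in uncurated
  verbatim fields.
* ROR is the only disproportionality statistic provided (no PRR, EBGM, or
  Bayesian shrinkage), matching the source scope.
* The screen provides no adjustment for confounding by indication or
  co-prescription patterns.
* Raw-quarter-scale claims (the 4,331,802 → 3,724,555 dedup count) require
  the real external files and are out of scope; the package validates the
  dedup *rule*, not that count.
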