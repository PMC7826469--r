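# pvscreen

Disproportionality signal screening for drug–drug modulation of adverse
events, with the downstream clinical and molecular triage stages.

## What problem this solves, and for whom

Spontaneous adverse-event reporting databases (FAERS-style quarterly
DEMO/DRUG/REAC extracts) let pharmacoepidemiologists ask whether an adverse
event is reported disproportionately often with a drug — and, less
commonly, whether some *co-reported* drug is associated with *fewer* event
reports, i.e. a candidate modulator of the adverse event. `pvscreen`
implements that full chain for analysts working on drug-safety signal
detection:

1. **Ingestion + deduplication** of `"$"`-delimited report tables — cases
   are re-reported over time, so only the most recent version of each case
   number is analyzed;
2. **Reporting odds ratio (ROR)** signal statistics. With reports
   cross-classified as `a` (drug + event), `b` (drug, no event), `c`
   (event, no drug), `d` (neither):

   ROR = (a/b)/(c/d),  95% CI = exp( ln ROR ± 1.96 √(1/a + 1/b + 1/c + 1/d) )

   with a two-sided Fisher exact p-value, Haldane correction policy for
   zero cells, and classification *positive* (CI entirely above 1) /
   *inverse* (entirely below 1) / *none*;
3. **Stratified analysis** by sex and age bands;
4. **Comedication screen**: within reports of a base drug, every drug
   co-reported at least `min_coreports` times is tested for modification of
   the event's reporting odds — inverse signals are candidate protective
   comedications;
5. **Chart-review endpoints**: RECIST v1.0 response classification,
   ORR/DCR with the Fisher/chi-square small-cell selection rule,
   Mann–Whitney U, CTCAE-style hypertension event flagging, SBP change
   summaries;
6. **Expression stage**: two-group comparison (Welch t on log2 values,
   original-scale fold change `2^Δmean`) on a pathway gene subset, ΔΔCq
   qPCR quantification normalized to a reference gene, and Dunnett
   many-to-one testing;
7. **Synthetic data generators** with planted effects and truth sidecars,
   so every stage is testable offline — including a deterministic fixture
   mode that reproduces the embedded published count tables exactly.

The worked example below is the bevacizumab–hypertension analysis: an
anti-VEGF antibody whose induced hypertension tracks efficacy, screened for
comedications (notably the proton pump inhibitor omeprazole) that reduce
hypertension reporting and may blunt the drug's effect.

## Worked example

```r
library(pvscreen)

## total signal from the embedded deduplicated four-group counts
ror(contingency_table(1520, 26768, 83559, 3611907))
#> ROR 2.45 (95% CI 2.33-2.59), p = 1.57e-195, class: positive

## comedication screen on the fixture base-drug report set (28,288 reports)
reports <- fixture_reports("exposed")
rows <- screen_comedications(reports, "BEVACIZUMAB",
                             default_hypertension_terms(),
                             min_coreports = 100, direction = "inverse")
screen_summary(rows)
#>         drug     event_without    event_with  ror      ci95  p_value
#> 1 EPIRUBICIN 1512/27859 (5.43)  8/429 (1.86) 0.33 0.16-0.67 0.000339
#> 2 OMEPRAZOLE 1502/27692 (5.42) 18/596 (3.02) 0.54 0.34-0.87 0.007570
#> 3  ERLOTINIB 1486/27390 (5.43) 34/898 (3.79) 0.69 0.49-0.97 0.034700

## chart-review endpoints on the embedded 58-patient cohort
response_rates(gen_cohort(fixture = TRUE))
#>        resp
#> arm     CR PR SD PD
#>   FALSE  0 21 17  4
#>   TRUE   0  4  7  5
#> FALSE: ORR 50%, DCR 90%
#> TRUE: ORR 25%, DCR 69%
#> ORR comparison: fisher, p = 0.138
#> DCR comparison: fisher, p = 0.0974
```

Reading the screen table: each row is one candidate comedication among the
28,288 base-drug reports; `event_with` = hypertension reports / co-reports
(percent). All three candidates are *inverse* signals (CI upper bound
below 1): patients whose bevacizumab report also lists epirubicin,
omeprazole or erlotinib reported hypertension less often. In the cohort,
PPI users had half the objective response rate of non-users (25% vs 50%,
not significant at n = 58).

End-to-end runs (simulate → dedup → signal → screen → cohort → expression)
are wired through `run_pipeline()` and the CLI at `inst/cli/pvscreen.R`
(subcommands `simulate`, `dedup`, `signal`, `screen`, `cohort`,
`expression`, `all`; exit codes 0/2/3/4 for success/config/data/stage
failure). Every artifact directory gets a `manifest.json` with md5
checksums; identical config + seed reproduces byte-identical artifacts.

## Scope notes

Real FAERS quarters and the public expression series are never downloaded;
the bundled hypertension term list is a reproducibility stand-in for the
licensed 10-term standardized query, and the synthetic generators emulate
(not replay) the source data. See `vignettes/pvscreen-methods.Rmd` for the
model, the generators' stated worlds, numerical conventions and known
limitations.
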