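# oncotext

Rule-based oncology text mining with federated cohort queries, at desk
scale.

Most of what is clinically known about a cancer patient sits in
free-text reports, not in coded fields. Identifying a cohort — say,
every patient with a cancer of unknown primary (CUP) — therefore means
mining French-language medical reports, reconciling them with coded
hospital-discharge (PMSI) data, structuring the result into a
per-patient disease timeline, and counting matches across several
hospitals without moving patient-level data. `oncotext` implements that
whole chain on synthetic, ground-truthed data, for researchers and
students of clinical NLP and federated health informatics who want a
fully inspectable, deterministic reference implementation:

* **Corpus synthesis** — ground-truth disease courses (site, morphology,
  diagnosis and metastatic-onset dates, treatments), French-like reports
  with character-exact gold annotations (redundant history sections,
  negated/hypothetical phrases, date phrases, accent variants), and
  PMSI-like discharge records, partitioned across simulated centres.
* **Concept extraction** — deterministic lexicon matching
  (longest-match-first, accent/case/plural-insensitive), NegEx-style
  negation and hypothesis context detection, concept–date linking,
  relation linking, identifier redaction; spans always reported in
  original-text coordinates.
* **Pivot store** — document-sourced concept occurrences with full
  provenance (source, date origin, record date), plus discharge records.
* **Patient structuring** — deduplication, PMSI corroboration, primary
  tumor resolution, and the weighted sliding-interval heuristic that
  dates metastasis onset.
* **Federated queries** — per-centre query execution (textual +
  structured criteria) with count-only aggregation, including the base
  and refined ten-keyword CUP queries.
* **Evaluation** — recall, precision, F1 (with the
  poor/acceptable/excellent/outstanding bands) against reference lists
  and reviewed samples.

## The onset heuristic

For a patient with metastasis/distant-relapse occurrences at dates
`d_1 ≤ d_2 ≤ …` (concept-linked date when the text carries one, else the
document date), each distinct `d_k` opens a window `[d_k, d_k + Δ)` with
`Δ = 180` days by default. Occurrence `i` contributes weight

```
w_i = source_weight[source_i] × origin_weight[origin_i] × (h if hypothetical else 1)
```

with defaults `source_weight = (REPORT 1, PMSI 2)`,
`origin_weight = (CONCEPT_LINKED 1.5, DOCUMENT 1)`, `h = 0.25`. The
first window whose cumulative weight strictly exceeds the threshold
(default 3) dates the onset at its start; negated occurrences are
excluded. All parameters are exposed through `onset_params()`.

## Worked example

```r
library(oncotext)

cfg  <- corpus_config(n_patients = 200, seed = 7)
corp <- generate_corpus(cfg)          # courses, reports, gold, PMSI, 4 centres
res  <- run_pipeline(corp)            # extract -> ingest -> structure -> stores

fc <- federate(res$stores, cup_query(refined = TRUE))
fc$per_centre
#> centre_01 centre_02 centre_03 centre_04
#>         0         1         3         1
fc$total
#> [1] 5
```

Five CUP patients are found across the four centres; only counts cross
the federation boundary. Scoring the same query against the generator's
ground truth:

```r
truth  <- subset(corp$ground_truth, is_cup)$patient_id
pooled <- run_local(centre_store("pooled", res$profiles, corp$documents),
                    cup_query(refined = TRUE))
ev <- evaluate_cohort(pooled$patient_ids, truth,
                      setNames(pooled$patient_ids %in% truth, pooled$patient_ids))
c(ev$recall_pct, ev$precision_pct, round(ev$f1, 2))
#> [1] 100 100   1
```

The onset heuristic is inspectable per patient. For a patient whose
true metastatic onset is 2015-04-14:

```r
res$profiles[["P00004"]]$diagnostics$intervals
#>        start weight accepted
#> 1 2015-04-14   12.5     TRUE
#> 2 2015-04-25   11.0    FALSE
#> 3 2015-05-16    9.0    FALSE
#> ...
```

The first window already exceeds the threshold, so the inferred onset
is 2015-04-14 — the ground-truth date.

A command-line wrapper with `simulate`, `process`, `structure`, `query`
and `evaluate` subcommands is installed under `inst/cli/oncotext.R`.

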