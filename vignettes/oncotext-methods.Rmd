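---
title: "Methods: structuring oncology text and dating metastasis onset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structuring oncology text and dating metastasis onset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(oncotext)
```

## What the package models

`oncotext` is a desk-scale model of a federated oncology data-mining
workflow. Each simulated hospital holds French-language care reports and
coded discharge (PMSI-like) stays for its patients. The pipeline turns
reports into concept mentions, mentions into dated, sourced concept
*occurrences* (the document-centric "elementary" layer), and occurrences
into a patient-centric inferred profile: one cancer with a primary site,
a morphology, a diagnosis date, tumor events (primary, local relapse,
metastatic relapse) and treatment acts. Cohort queries then run locally
at every centre and only counts are aggregated.

Everything is deterministic: the same configuration and seed yield
byte-identical corpora, occurrence stores, profiles and counts. That is
a design goal — the package exists so that every stage can be tested
against a known ground truth.

## Concept extraction

Extraction is lexicon- and rule-based rather than statistical. A closed
vocabulary (`default_lexicon()`) maps normalized French terms to a
category and a code (ICD-10 for locations and secondary malignancies,
ICD-O-3 for morphologies, treatment/response types, the ten
unknown-primary keyword phrases). The choice is deliberate: a trained
statistical tagger would add nothing testable here — there are no
weights to ship and no annotated real corpus to fit — while a
deterministic matcher makes gold-agreement an exact, reproducible
property. The vocabulary being closed also makes heavy preprocessing
unnecessary: lemmatization reduces to a plural/feminine suffix table
(every content word of a term also matches with a trailing "s"), and no
stopword stripping is applied inside phrases, since several lexicon
phrases ("de primitif inconnu", "pas de primitif retrouve") contain
function words that are load-bearing.

Normalization lowercases, strips accents, unifies typographic
apostrophes and collapses whitespace, and returns an offset map so every
normalized position traces back to the original character. All spans in
the package are 0-based half-open offsets into the *original* text —
one convention, stated once. Identifier redaction (honorific + name,
emails, digit runs of six or more) happens before matching and returns
its own offset map; the two maps are composed, so redaction never
perturbs reported spans.

Matching is longest-match-first, left-to-right, non-overlapping, with
word-boundary checks; at equal start the longer match wins and at equal
length the earlier lexicon entry wins, for determinism. In "carcinome de
primitif inconnu" the matcher reports "de primitif inconnu", not the
embedded shorter phrase.

Context classification follows the NegEx convention: a mention is
negated (or hypothetical) when a trigger occurs within a backward window
of **5 tokens** with no intervening scope breaker (sentence punctuation
or "mais"); the nearest trigger wins. The trigger sets are small and
fixed — negation: "pas de", "absence de", "sans", "aucun(e)";
hypothesis: "suspicion", "evoque", "possible", "probable", "recherche
de". No forward-scope triggers are modelled. Date linking attaches each
mention to the nearest date phrase within the same sentence and within
**10 tokens** (ties to the earlier date); when none qualifies, the
document date is the downstream fallback. Mention-level relation links
(response → treatment, metastasis → location) are scoped to the
sentence; paragraph scope was considered and rejected because rendered
reports separate unrelated facts by sentence, and a wider scope only
adds false links. Response links prefer the nearest *preceding*
treatment and fall back to the nearest following one, so both "après
chimiothérapie, réponse partielle" and "réponse partielle après
chimiothérapie" link correctly.

## The occurrence store

Each non-date mention becomes one occurrence carrying its category,
code, context, a date with an explicit origin (`CONCEPT_LINKED` when the
text supplied one, `DOCUMENT` otherwise), the source (`REPORT` or
`PMSI`), the source id and the recording date. Discharge records yield
one occurrence per diagnosis code and per act, dated at admission — PMSI
has stay dates but no diagnosis dates — always `AFFIRMED`, since coded
billing data carries no textual context. Code ranges map as: C77–C79 →
metastasis; C80 → unknown-primary evidence (so coded data cannot
fabricate a concrete primary for a CUP patient); other C codes → tumor
location; Z51.0/Z51.1 → treatment session. Ingestion is additive and
order-independent.

## Patient structuring

Rules run in a fixed order, some conditionally:

1. **Deduplicate**: occurrences identical on (category, code, date,
   context) — the signature of history sections copied verbatim across
   reports — collapse to the representative with the richest
   provenance: concept-linked over document-dated, then PMSI over
   report, then smallest source id.
2. **Corroborate**: a report diagnosis or treatment is corroborated by a
   PMSI occurrence with the same ICD-10 three-character prefix, or the
   same treatment type, within **±90 days** (a stay and the report
   discussing it are rarely further apart; the window is a parameter).
   Session coding maps Z51.1 → chemotherapy and Z51.0 → radiotherapy;
   immunotherapy stays are coded Z51.1 in the simulation, mirroring
   that discharge data records sessions without drug detail, so
   immunotherapy mentions remain uncorroborated by design.
3. **Resolve the primary**: most frequent corroborated tumor-location
   code, falling back to the most frequent affirmed one; the diagnosis
   date is the earliest affirmed occurrence of that code. When no
   location is affirmed but unknown-primary keywords are, the primary is
   `UNKNOWN_PRIMARY` and the diagnosis date anchors on the earliest
   affirmed keyword/metastasis occurrence.
4. **Date the metastasis onset** — only when candidate occurrences
   exist (the conditional rule).
5. **Assemble acts** from affirmed report treatments, keyed by (type,
   date), carrying corroboration flags and supporting ids.

### The onset heuristic and its parameters

Candidates are metastasis occurrences plus *distant* relapses; negated
candidates are excluded outright, hypothetical ones down-weighted rather
than dropped, because a hypothesis often precedes the confirmed
diagnosis by weeks. Relapse distance is decided by code: `DISTANT`
counts, `LOCAL` does not, an ICD-coded relapse counts when its
three-character prefix differs from the primary's, and an uncoded
relapse is *not* a candidate — its distance is undeterminable, and
counting it would let local recurrences masquerade as metastases.

Each distinct candidate date opens a window of `interval_days` (default
**180 d**; 90 or 365 are reasonable alternatives and are configuration,
not code). Weights multiply a source factor (REPORT 1, PMSI 2 — coded
discharge data is deliberate, billed activity), a date-origin factor
(CONCEPT_LINKED 1.5, DOCUMENT 1 — an explicit date phrase is stronger
evidence than a fallback) and the hypothetical multiplier (0.25). The
first window, in chronological order of start, whose weight strictly
exceeds the threshold (default **3.0**) dates the onset at its start.
The defaults are calibrated so that one corroborating stay plus one
report mention (2 + 1 = 3) is *not* sufficient, while any third piece of
evidence — a second report, or a concept-linked date — tips the
balance. PMSI occurrences participate in windows as weighted evidence,
not merely as corroboration; excluding them was considered, but a
C77–C79 coded stay is exactly the kind of dated, deliberate signal the
heuristic should reward. "Moving to the next interval" advances to the
next distinct candidate date, so no potential onset is skipped.

The implementation is verified against a brute-force oracle that
enumerates every candidate start and re-sums window weights directly, on
hundreds of randomized occurrence sets, and obeys two monotonicity laws:
adding affirmed evidence can only keep or advance the onset, and raising
the threshold can only delay or remove it.

Profiles enforce `metastatic relapse ≥ diagnosis`: if the accepted
window starts before the resolved diagnosis date (possible when the
primary is poorly documented), the diagnosis date is pulled back to the
onset rather than violating the invariant.

## Federated queries

A query combines a textual criterion (any of a list of phrases,
normalized exactly like document text) with structured criteria on the
profile (diagnosis since a date, de novo metastatic status, required
site). Keyword matching runs on raw normalized text, *not* on
context-filtered mentions — the refined unknown-primary keyword list
itself contains "pas de primitif retrouve", which a context filter would
discard. "Metastatic at diagnosis" means a metastatic-relapse event
within **30 days** of the diagnosis date (`de_novo_window_days`,
configurable): "at the time of diagnosis" needs a tolerance because
work-ups take weeks. Federation is count-only: per-centre counts and
their sum; the serialized response carries no patient identifier, and a
centre that fails to evaluate is omitted and reported. Transport is
in-process over per-centre stores — the network layer is a deployment
detail outside this package's scope; the contract being modelled is the
aggregation boundary.

## Evaluation design

Recall is computed against a reference list (known positives); precision
on a manually reviewed sample of retrieved patients, because true
negatives cannot be enumerated over a whole record system — specificity
is therefore deliberately not offered. F1 is the harmonic mean, banded
as poor < 0.6 ≤ acceptable < 0.8 ≤ excellent < 0.9 ≤ outstanding, with
the boundaries assigned upward at two-decimal reporting. Percentages are
rounded half away from zero to integers, F1 to two decimals.

## What the generator emulates — and what it does not

The generator draws a ground-truth course per patient (site conditioned
on sex, morphology, diagnosis date 2010–2021, metastatic onset 60–720
days after diagnosis for the metastatic fraction, 1–3 treatments), then
renders reports from templates with exact gold spans. It reproduces the
phenomena the pipeline must survive: history sections repeated verbatim
across reports (default probability 0.6), negated and hypothetical
metastasis phrases (defaults 0.2 and 0.1 per eligible report), explicit
date phrases in two French formats versus document-date fallback
(default 0.6), accented and unaccented spellings, identifiers for the
redactor, and CUP patients (default prevalence 3%, capped at 5% to stay
consistent with how rare the entity is) whose reports use the ten
keyword phrasings and who are metastatic at diagnosis. Centres are
filled round-robin by patient index: reproducible, balanced, disjoint.

Its limits matter for interpreting green tests. Negation and hypothesis
phrasings are drawn from the same finite trigger set the classifier
knows, so context accuracy near 1.0 shows the *machinery* is correct,
not that the trigger inventory covers real clinical French. Likewise the
vocabulary is closed over the lexicon, reports are template-regular,
spelling is clean, and every patient has exactly one cancer. On real
reports, recall would be bounded by lexicon coverage and the trigger
inventory, not by the mechanics tested here. Multi-primary patients,
hematological cancers, sarcomas and skin cancers — where histology
outranks location and a location-based primary resolution is fragile —
are carried (morphology is always recorded) but not special-cased.

## Sizes, tolerances, degenerate inputs

The test suite and the acceptance script use a 500-patient study corpus
(about 3,300 reports) with 40% metastatic fraction, 20% negation and 10%
hypothesis noise — large enough that the onset-recovery and prevalence
statistics are stable, small enough to run comfortably on a laptop; the
oracle-equivalence property uses 500 randomized occurrence sets of up to
50 occurrences. Onset recovery is scored within one window length (180
days) of ground truth. Degenerate inputs are handled without error:
empty documents yield empty mention lists, unknown patients empty
occurrence sets, patients without candidates get no metastatic event,
impossible calendar dates (e.g. "31/02/2021") are dropped from date
linking with a message, malformed discharge codes skip the record with a
warning, and an unreachable centre is excluded from the federated total
and named in the response.
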