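#' Run the full pipeline on a synthetic corpus
#'
#' Convenience wrapper chaining concept extraction, occurrence ingestion,
#' patient structuring and centre-store construction — the same composition
#' the command-line interface and the acceptance script use.
#'
#' @param corpus a `synthetic_corpus` from [generate_corpus()].
#' @param lex a [lexicon()] (default [default_lexicon()]).
#' @param params an [onset_params()].
#' @return list with `structured` (structured documents), `store`
#'   (occurrence data.frame), `profiles` (named list) and `stores`
#'   (per-centre [centre_store()]s).
#' @export
run_pipeline <- function(corpus, lex = default_lexicon(), params = onset_params()) {
  structured <- process_corpus(corpus$documents, lex)
  store <- build_occurrence_store(structured, corpus$pmsi)
  profiles <- structure_patients(store, params)
  stores <- build_centre_stores(corpus, profiles)
  list(structured = structured, store = store, profiles = profiles, stores = stores)
}
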