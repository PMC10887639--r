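#' A cohort query
#'
#' Criteria combine per `combine` over the non-null ones: `keyword_terms`
#' is a textual search (any phrase, matched accent- and case-insensitively
#' against raw report text — never against context-filtered mentions, so a
#' phrase may itself embed a negation, like "pas de primitif retrouve");
#' `since_date` applies to the inferred diagnosis date;
#' `metastatic_at_diagnosis` requires a de novo metastatic profile (a
#' metastatic-relapse event within 30 days of diagnosis);
#' `required_site` matches the inferred primary site code or
#' `"UNKNOWN_PRIMARY"`.
#'
#' @param keyword_terms character vector of phrases, or `NULL`.
#' @param since_date `Date` or `NULL`.
#' @param metastatic_at_diagnosis logical or `NULL`.
#' @param required_site site code, `"UNKNOWN_PRIMARY"`, or `NULL`.
#' @param combine `"ALL"` or `"ANY"` over the non-null criteria.
#' @return a `cohort_query` list.
#' @export
cohort_query <- function(keyword_terms = NULL, since_date = NULL,
                         metastatic_at_diagnosis = NULL, required_site = NULL,
                         combine = c("ALL", "ANY")) {
  combine <- match.arg(combine)
  if (is.null(keyword_terms) && is.null(since_date) &&
      is.null(metastatic_at_diagnosis) && is.null(required_site)) {
    stop("a cohort query needs at least one criterion")
  }
  if (!is.null(since_date)) since_date <- as.Date(since_date)
  structure(
    list(keyword_terms = keyword_terms, since_date = since_date,
         metastatic_at_diagnosis = metastatic_at_diagnosis,
         required_site = required_site, combine = combine),
    class = "cohort_query"
  )
}

#' The cancer-of-unknown-primary cohort query
#'
#' The base query selects patients initially diagnosed with de novo
#' metastatic cancer whose record mentions "primitif inconnu" since
#' 1 January 2010. The refined query widens the textual criterion to the
#' full ten-phrase keyword list ("ACUP", "primitif inconnu", "de primitif
#' inconnu", "sans primitif retrouve", "sans primitif connu", "d'origine
#' indeterminee", "pas de primitif retrouve", "d'origine inconnue",
#' "recherche de la tumeur primitive", "autre primitif"); phrases combine
#' as ANY while the criterion groups still combine as ALL.
#'
#' @param refined use the ten-phrase refined keyword list?
#' @return a [cohort_query()].
#' @export
cup_query <- function(refined = FALSE) {
  terms <- if (refined) {
    c("ACUP", "primitif inconnu", "de primitif inconnu", "sans primitif retrouve",
      "sans primitif connu", "d'origine indéterminée", "pas de primitif retrouve",
      "d'origine inconnue", "recherche de la tumeur primitive", "autre primitif")
  } else {
    "primitif inconnu"
  }
  cohort_query(
    keyword_terms = terms,
    since_date = as.Date("2010-01-01"),
    metastatic_at_diagnosis = TRUE,
    combine = "ALL"
  )
}

#' Build a centre's local store
#'
#' Precomputes the normalized text index used by the keyword criterion.
#' Every profile kept must have at least one document.
#'
#' @param centre_id centre identifier.
#' @param profiles named list of `patient_profile`s.
#' @param documents list of raw document records (`doc_id`, `patient_id`,
#'   `text`).
#' @return a `centre_store`.
#' @export
centre_store <- function(centre_id, profiles, documents) {
  doc_pat <- vapply(documents, `[[`, "", "patient_id")
  norm <- vapply(documents, function(d) normalize_text(d$text)$text, character(1))
  keep <- names(profiles) %in% doc_pat
  structure(
    list(centre_id = centre_id, profiles = profiles[keep],
         doc_patient = doc_pat, doc_norm = norm),
    class = "centre_store"
  )
}

#' Split a corpus into per-centre stores
#'
#' @param corpus a `synthetic_corpus`.
#' @param profiles named list of `patient_profile`s for all patients.
#' @return list of `centre_store`s, one per centre.
#' @export
build_centre_stores <- function(corpus, profiles) {
  lapply(sort(unique(unname(corpus$centre))), function(cid) {
    pats <- names(corpus$centre)[corpus$centre == cid]
    docs <- Filter(function(d) d$patient_id %in% pats, corpus$documents)
    centre_store(sprintf("centre_%02d", cid),
                 profiles[intersect(names(profiles), pats)], docs)
  })
}

phrase_found <- function(norm_text, norm_phrase) {
  m <- gregexpr(norm_phrase, norm_text, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(FALSE)
  len <- attr(m, "match.length")
  for (j in seq_along(m)) {
    if (span_bounded(norm_text, m[j], m[j] + len[j])) return(TRUE)
  }
  FALSE
}

#' Run a cohort query against one centre
#'
#' Evaluation is local and deterministic; the keyword criterion scans the
#' centre's raw (normalized) report text, the structured criteria the
#' inferred profiles.
#'
#' @param store a [centre_store()].
#' @param q a [cohort_query()].
#' @param de_novo_window_days tolerance, in days after diagnosis, for a
#'   metastatic-relapse event to count as "metastatic at diagnosis".
#' @return list with `count` and `patient_ids` (local use only; only counts
#'   cross the federation boundary).
#' @export
run_local <- function(store, q, de_novo_window_days = 30L) {
  if (!length(store$profiles)) return(list(count = 0L, patient_ids = character(0)))
  norm_terms <- if (!is.null(q$keyword_terms)) {
    vapply(q$keyword_terms, function(t) normalize_text(t)$text, character(1))
  } else {
    NULL
  }
  hits <- vapply(names(store$profiles), function(pid) {
    pr <- store$profiles[[pid]]
    checks <- logical(0)
    if (!is.null(norm_terms)) {
      texts <- store$doc_norm[store$doc_patient == pid]
      kw <- any(vapply(norm_terms, function(t) any(vapply(texts, phrase_found,
                                                          logical(1), norm_phrase = t)),
                       logical(1)))
      checks <- c(checks, kw)
    }
    if (!is.null(q$since_date)) {
      dd <- profile_diagnosis_date(pr)
      checks <- c(checks, !is.na(dd) && dd >= q$since_date)
    }
    if (!is.null(q$metastatic_at_diagnosis)) {
      dd <- profile_diagnosis_date(pr)
      mo <- profile_metastatic_onset(pr)
      de_novo <- !is.na(dd) && !is.na(mo) &&
        as.numeric(mo - dd) <= de_novo_window_days
      checks <- c(checks, de_novo == q$metastatic_at_diagnosis)
    }
    if (!is.null(q$required_site)) {
      checks <- c(checks, identical(profile_primary_site(pr), q$required_site))
    }
    if (q$combine == "ALL") all(checks) else any(checks)
  }, logical(1))
  ids <- names(store$profiles)[hits]
  list(count = length(ids), patient_ids = ids)
}

#' Federate a cohort query over several centres
#'
#' Each centre evaluates the query locally; only per-centre counts are
#' aggregated — no patient identifier crosses the federation boundary.
#' A centre whose evaluation fails is omitted and reported; the total
#' covers the responding centres.
#'
#' @param stores list of [centre_store()]s.
#' @param q a [cohort_query()].
#' @param de_novo_window_days see [run_local()].
#' @return a `federated_counts` list with `per_centre` (named integer
#'   vector), `total`, and `unreachable` (character vector of omitted
#'   centres).
#' @export
federate <- function(stores, q, de_novo_window_days = 30L) {
  if (!length(stores)) stop("federation needs at least one centre store")
  per_centre <- integer(0)
  unreachable <- character(0)
  for (st in stores) {
    res <- tryCatch(run_local(st, q, de_novo_window_days), error = function(e) e)
    if (inherits(res, "error")) {
      warning("centre ", st$centre_id, " unreachable: ", conditionMessage(res))
      unreachable <- c(unreachable, st$centre_id)
    } else {
      per_centre[st$centre_id] <- res$count
    }
  }
  structure(
    list(per_centre = per_centre, total = sum(per_centre),
         unreachable = unreachable),
    class = "federated_counts"
  )
}

#' Serialize federated counts
#'
#' The wire format carries only centre ids and counts.
#'
#' @param counts a `federated_counts`.
#' @param path optional path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to `path`.
#' @export
write_counts <- function(counts, path = NULL) {
  payload <- list(per_centre = as.list(counts$per_centre), total = counts$total)
  json <- as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
  if (is.null(path)) return(json)
  writeLines(json, path, useBytes = TRUE)
  invisible(json)
}
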