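ICD10_REGEX <- "^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,2})?$"
CCAM_REGEX <- "^[A-Z]{4}[0-9]{3}$"

icd10_prefix <- function(code) substr(code, 1L, 3L)

#' A hospital-discharge (PMSI-like) record
#'
#' @param stay_id opaque stay identifier.
#' @param patient_id patient identifier.
#' @param admission_date,discharge_date stay dates (`admission <= discharge`).
#' @param main_dx_icd10 main diagnosis, ICD-10 (letter + two digits +
#'   optional subcode).
#' @param associated_dx_icd10 character vector of associated ICD-10 codes.
#' @param acts_ccam character vector of CCAM act codes (4 letters + 3
#'   digits).
#' @return a `discharge_record` list.
#' @export
discharge_record <- function(stay_id, patient_id, admission_date, discharge_date,
                             main_dx_icd10, associated_dx_icd10 = character(0),
                             acts_ccam = character(0)) {
  admission_date <- as.Date(admission_date)
  discharge_date <- as.Date(discharge_date)
  if (is.na(admission_date) || is.na(discharge_date) ||
      admission_date > discharge_date) {
    stop("admission_date must be on or before discharge_date")
  }
  r <- structure(
    list(stay_id = stay_id, patient_id = patient_id,
         admission_date = admission_date, discharge_date = discharge_date,
         main_dx_icd10 = main_dx_icd10,
         associated_dx_icd10 = as.character(associated_dx_icd10),
         acts_ccam = as.character(acts_ccam)),
    class = "discharge_record"
  )
  r
}

occurrence_columns <- c(
  "patient_id", "category", "code", "context", "date", "date_origin",
  "source", "source_id", "recorded_at"
)

empty_occurrences <- function() {
  data.frame(
    patient_id = character(0), category = character(0), code = character(0),
    context = character(0), date = as.Date(character(0)),
    date_origin = character(0), source = character(0), source_id = character(0),
    recorded_at = as.Date(character(0)), stringsAsFactors = FALSE
  )
}

#' Turn a structured document into concept occurrences
#'
#' One occurrence per non-DATE mention. The occurrence date is the
#' mention's concept-linked date when the text carried one (origin
#' `CONCEPT_LINKED`), otherwise the document date (origin `DOCUMENT`).
#'
#' @param sd a `structured_document` from [process_document()].
#' @return an occurrence data.frame.
#' @export
ingest_document <- function(sd) {
  m <- sd$mentions
  m <- m[m$category != "DATE", , drop = FALSE]
  if (!nrow(m)) return(empty_occurrences())
  has_linked <- !is.na(m$linked_date)
  data.frame(
    patient_id = sd$patient_id,
    category = m$category,
    code = m$code,
    context = m$context,
    date = as.Date(ifelse(has_linked, as.numeric(m$linked_date),
                          as.numeric(sd$doc_date)), origin = "1970-01-01"),
    date_origin = ifelse(has_linked, "CONCEPT_LINKED", "DOCUMENT"),
    source = "REPORT",
    source_id = sd$doc_id,
    recorded_at = sd$doc_date,
    stringsAsFactors = FALSE
  )
}

# Map a PMSI diagnosis code to a concept category: the C77-C79 block is
# secondary malignancy (metastasis), C80 is malignant neoplasm of unknown
# primary site, other C codes are tumor locations and Z51.x are treatment
# sessions (chemo/radiotherapy encounters).
pmsi_dx_category <- function(code) {
  p <- icd10_prefix(code)
  if (p %in% c("C77", "C78", "C79")) return("METASTASIS")
  if (p == "C80") return("UNKNOWN_PRIMARY_KEYWORD")
  if (substr(code, 1L, 1L) == "C") return("TUMOR_LOCATION")
  if (p %in% c("Z51")) return("TREATMENT")
  NA_character_
}

# Treatment type of a PMSI-coded occurrence, for corroboration against
# report-derived treatment mentions.
pmsi_treatment_type <- function(code) {
  if (is.na(code)) return(NA_character_)
  if (code == "Z51.1") return("CHEMO")
  if (code == "Z51.0") return("RADIO")
  if (grepl(CCAM_REGEX, code)) return("SURGERY")
  NA_character_
}

#' Turn a discharge record into concept occurrences
#'
#' One occurrence per diagnosis code and per act, dated at the admission
#' (PMSI carries stay dates, never a diagnosis date), origin `DOCUMENT`,
#' source `PMSI`, context `AFFIRMED` (coded billing data has no textual
#' context). Records with a malformed main diagnosis or act code are
#' skipped with a warning.
#'
#' @param r a [discharge_record()].
#' @return an occurrence data.frame.
#' @export
ingest_discharge <- function(r) {
  codes <- c(r$main_dx_icd10, r$associated_dx_icd10)
  if (length(codes) && !all(grepl(ICD10_REGEX, codes))) {
    warning("skipping discharge record ", r$stay_id, ": malformed ICD-10 code")
    return(empty_occurrences())
  }
  if (length(r$acts_ccam) && !all(grepl(CCAM_REGEX, r$acts_ccam))) {
    warning("skipping discharge record ", r$stay_id, ": malformed CCAM code")
    return(empty_occurrences())
  }
  cats <- vapply(codes, pmsi_dx_category, character(1), USE.NAMES = FALSE)
  keep <- !is.na(cats)
  codes <- codes[keep]; cats <- cats[keep]
  n_dx <- length(codes); n_act <- length(r$acts_ccam)
  if (n_dx + n_act == 0L) return(empty_occurrences())
  data.frame(
    patient_id = r$patient_id,
    category = c(cats, rep("TREATMENT", n_act)),
    code = c(codes, r$acts_ccam),
    context = "AFFIRMED",
    date = r$admission_date,
    date_origin = "DOCUMENT",
    source = "PMSI",
    source_id = r$stay_id,
    recorded_at = r$admission_date,
    stringsAsFactors = FALSE
  )
}

#' Build an occurrence store from structured documents and discharge records
#'
#' The store is a plain occurrence data.frame; ingestion is additive and
#' order-independent (the final state is a set of rows).
#'
#' @param structured list of `structured_document`s.
#' @param discharge list of [discharge_record()]s.
#' @return an occurrence data.frame.
#' @export
build_occurrence_store <- function(structured = list(), discharge = list()) {
  parts <- c(lapply(structured, ingest_document), lapply(discharge, ingest_discharge))
  if (!length(parts)) return(empty_occurrences())
  do.call(rbind, parts)
}

#' Chronologically sorted occurrences of one patient
#'
#' Sorted by `(date, source_id)`; the sort is stable, and an unknown
#' patient yields an empty result rather than an error.
#'
#' @param store an occurrence data.frame.
#' @param patient_id patient to query.
#' @return occurrence data.frame sorted by date then source id.
#' @export
occurrences_for_patient <- function(store, patient_id) {
  occ <- store[store$patient_id == patient_id, , drop = FALSE]
  occ <- occ[order(occ$date, occ$source_id), , drop = FALSE]
  rownames(occ) <- NULL
  occ
}

#' Dump an occurrence store to JSON Lines
#'
#' Field order is fixed so dumps are byte-stable and round-trip through
#' [read_occurrences()].
#'
#' @param store occurrence data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_occurrences <- function(store, path) {
  recs <- lapply(seq_len(nrow(store)), function(i) {
    list(
      patient_id = store$patient_id[i], category = store$category[i],
      code = if (is.na(store$code[i])) NULL else store$code[i],
      context = store$context[i], date = as_iso(store$date[i]),
      date_origin = store$date_origin[i], source = store$source[i],
      source_id = store$source_id[i], recorded_at = as_iso(store$recorded_at[i])
    )
  })
  write_jsonl(recs, path)
}

#' Load an occurrence store from JSON Lines
#'
#' @param path file written by [write_occurrences()].
#' @return occurrence data.frame.
#' @export
read_occurrences <- function(path) {
  recs <- read_jsonl(path)
  if (!length(recs)) return(empty_occurrences())
  do.call(rbind, lapply(recs, function(r) {
    data.frame(
      patient_id = r$patient_id, category = r$category,
      code = r$code %||% NA_character_, context = r$context,
      date = as.Date(r$date), date_origin = r$date_origin,
      source = r$source, source_id = r$source_id,
      recorded_at = as.Date(r$recorded_at), stringsAsFactors = FALSE
    )
  }))
}
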