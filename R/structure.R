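#' Parameters of the metastasis-onset heuristic
#'
#' The sliding window spans `interval_days` (half a year by default; three
#' months or a year are common alternatives). Each occurrence contributes
#' `source_weight[source] * date_origin_weight[date_origin]`, multiplied by
#' `hypothetical_weight` when its context is hypothetical; the first window
#' whose cumulative weight exceeds `threshold` dates the onset. The weights
#' encode that coded discharge data and concept-linked dates are stronger
#' evidence than a bare report mention dated by its document.
#'
#' @param interval_days window length in days.
#' @param source_weight named positive weights for sources `REPORT`, `PMSI`.
#' @param date_origin_weight named positive weights for `CONCEPT_LINKED`,
#'   `DOCUMENT`.
#' @param hypothetical_weight non-negative multiplier for hypothetical
#'   occurrences.
#' @param threshold positive acceptance threshold on a window's cumulative
#'   weight (strictly exceeded).
#' @return an `onset_params` list.
#' @export
onset_params <- function(interval_days = 180L,
                         source_weight = c(REPORT = 1, PMSI = 2),
                         date_origin_weight = c(CONCEPT_LINKED = 1.5, DOCUMENT = 1),
                         hypothetical_weight = 0.25,
                         threshold = 3) {
  p <- list(
    interval_days = as.integer(interval_days),
    source_weight = source_weight,
    date_origin_weight = date_origin_weight,
    hypothetical_weight = hypothetical_weight,
    threshold = threshold
  )
  if (p$interval_days <= 0L) stop_config("interval_days must be positive")
  if (p$threshold <= 0) stop_config("threshold must be positive")
  w <- c(p$source_weight, p$date_origin_weight, p$hypothetical_weight)
  if (any(!is.finite(w)) || any(w < 0)) stop_config("weights must be finite and non-negative")
  if (!all(c("REPORT", "PMSI") %in% names(p$source_weight))) {
    stop_config("source_weight needs REPORT and PMSI entries")
  }
  if (!all(c("CONCEPT_LINKED", "DOCUMENT") %in% names(p$date_origin_weight))) {
    stop_config("date_origin_weight needs CONCEPT_LINKED and DOCUMENT entries")
  }
  class(p) <- "onset_params"
  p
}

#' Collapse redundant occurrences of one patient
#'
#' Occurrences identical on `(category, code, date, context)` — typically a
#' history section repeated verbatim across reports — collapse to the
#' representative with the richest provenance: concept-linked date over
#' document date, then PMSI over report, then the smallest source id. The
#' operation is idempotent and never increases the row count.
#'
#' @param occurrences occurrence data.frame of a single patient.
#' @return deduplicated occurrence data.frame.
#' @export
deduplicate_occurrences <- function(occurrences) {
  if (!nrow(occurrences)) return(occurrences)
  key <- paste(occurrences$category, occurrences$code, as_iso(occurrences$date),
               occurrences$context, sep = "\r")
  rank <- order(
    key,
    occurrences$date_origin != "CONCEPT_LINKED",  # CONCEPT_LINKED first
    occurrences$source != "PMSI",                 # then PMSI over REPORT
    occurrences$source_id
  )
  occ <- occurrences[rank, , drop = FALSE]
  occ <- occ[!duplicated(key[rank]), , drop = FALSE]
  occ <- occ[order(occ$date, occ$source_id), , drop = FALSE]
  rownames(occ) <- NULL
  occ
}

# type of a report-side treatment occurrence (lexicon codes are the types)
report_treatment_type <- function(code) {
  ifelse(code %in% c("SURGERY", "CHEMO", "RADIO", "IMMUNO"), code, NA_character_)
}

#' Corroborate report-derived occurrences with discharge data
#'
#' A report occurrence of a diagnosis (tumor location or metastasis, coded
#' ICD-10) or of a treatment is flagged `corroborated` when a PMSI
#' occurrence with a compatible code — same ICD-10 three-character prefix,
#' or same treatment type — exists within ±90 days. PMSI occurrences are
#' corroborated by construction. Adding discharge records can only add
#' flags, never remove one.
#'
#' @param occurrences occurrence data.frame of a single patient (mixing
#'   REPORT and PMSI sources).
#' @param window_days time window in days (default 90).
#' @return `occurrences` with a logical `corroborated` column.
#' @export
corroborate_with_discharge <- function(occurrences, window_days = 90L) {
  occ <- occurrences
  occ$corroborated <- occ$source == "PMSI"
  if (!nrow(occ)) return(occ)
  pm <- occ[occ$source == "PMSI", , drop = FALSE]
  if (!nrow(pm)) return(occ)
  pm_icd <- pm[!is.na(pm$code) & grepl(ICD10_REGEX, pm$code), , drop = FALSE]
  pm_type <- vapply(pm$code, pmsi_treatment_type, character(1), USE.NAMES = FALSE)
  for (i in which(occ$source == "REPORT")) {
    code <- occ$code[i]
    if (is.na(code)) next
    if (occ$category[i] %in% c("TUMOR_LOCATION", "METASTASIS") && grepl(ICD10_REGEX, code)) {
      hit <- nrow(pm_icd) && any(
        icd10_prefix(pm_icd$code) == icd10_prefix(code) &
          abs(as.numeric(pm_icd$date - occ$date[i])) <= window_days
      )
    } else if (occ$category[i] == "TREATMENT") {
      ty <- report_treatment_type(code)
      hit <- !is.na(ty) && any(
        !is.na(pm_type) & pm_type == ty &
          abs(as.numeric(pm$date - occ$date[i])) <= window_days
      )
    } else {
      hit <- FALSE
    }
    occ$corroborated[i] <- isTRUE(hit)
  }
  occ
}

# candidate occurrences for onset dating: affirmed or hypothetical
# metastasis mentions plus relapses distant from the primary site
onset_candidates <- function(occurrences, primary_site = NULL) {
  occ <- occurrences[occurrences$context != "NEGATED", , drop = FALSE]
  is_met <- occ$category == "METASTASIS"
  is_rel <- occ$category == "RELAPSE"
  distant <- rep(FALSE, nrow(occ))
  if (any(is_rel)) {
    code <- occ$code
    distant[is_rel] <- vapply(which(is_rel), function(i) {
      if (is.na(code[i])) return(FALSE)          # undetermined distance
      if (code[i] == "DISTANT") return(TRUE)
      if (code[i] == "LOCAL") return(FALSE)
      if (!is.null(primary_site) && grepl(ICD10_REGEX, code[i])) {
        return(icd10_prefix(code[i]) != icd10_prefix(primary_site))
      }
      FALSE
    }, logical(1))
  }
  occ[is_met | distant, , drop = FALSE]
}

occurrence_weight <- function(occ, params) {
  w <- unname(params$source_weight[occ$source]) *
    unname(params$date_origin_weight[occ$date_origin])
  w * ifelse(occ$context == "HYPOTHETICAL", params$hypothetical_weight, 1)
}

#' Date the start of the metastatic phase
#'
#' Weighted sliding-interval heuristic over metastasis and distant-relapse
#' occurrences: candidates are sorted by date (concept-linked date when
#' available, else the document date), each distinct candidate date opens a
#' window of `interval_days`, each occurrence inside a window contributes
#' its source/date-origin/context weight, and the first window (in
#' chronological order of start) whose cumulative weight strictly exceeds
#' the threshold dates the onset at its start. When no window qualifies the
#' onset stays undetermined. Negated occurrences must be excluded upstream
#' (they are filtered defensively); hypothetical ones are down-weighted
#' rather than dropped, since a hypothesis often precedes the confirmed
#' diagnosis.
#'
#' @param occurrences deduplicated occurrence data.frame of one patient.
#' @param params an [onset_params()].
#' @param primary_site optional primary-site code, used to tell distant
#'   from local relapses when relapse occurrences carry ICD-10 codes.
#' @return an `onset_diagnostics` list with `intervals` (data.frame of
#'   `start`, `weight`, `accepted`) and `chosen_onset` (`Date` or `NA`).
#' @export
infer_metastasis_onset <- function(occurrences, params = onset_params(),
                                   primary_site = NULL) {
  cand <- onset_candidates(occurrences, primary_site)
  if (!nrow(cand)) {
    return(structure(
      list(intervals = data.frame(start = as.Date(character(0)), weight = numeric(0),
                                  accepted = logical(0)),
           chosen_onset = as.Date(NA)),
      class = "onset_diagnostics"
    ))
  }
  cand <- cand[order(cand$date, cand$source_id), , drop = FALSE]
  w <- occurrence_weight(cand, params)
  starts <- sort(unique(cand$date))
  weight <- vapply(seq_along(starts), function(k) {
    inside <- cand$date >= starts[k] & cand$date < starts[k] + params$interval_days
    sum(w[inside])
  }, numeric(1))
  accepted_idx <- which(weight > params$threshold)
  accepted <- logical(length(starts))
  chosen <- as.Date(NA)
  if (length(accepted_idx)) {
    accepted[accepted_idx[1]] <- TRUE
    chosen <- starts[accepted_idx[1]]
  }
  structure(
    list(intervals = data.frame(start = starts, weight = weight, accepted = accepted),
         chosen_onset = chosen),
    class = "onset_diagnostics"
  )
}

most_frequent <- function(x) {
  if (!length(x)) return(NA_character_)
  tab <- sort(table(x), decreasing = TRUE)
  # deterministic tie-break: alphabetical among the most frequent
  top <- names(tab)[tab == tab[1]]
  sort(top)[1]
}

#' Build the inferred patient profile
#'
#' Fixed rule order: deduplicate, corroborate with discharge data, resolve
#' the primary tumor (most frequent corroborated tumor-location code,
#' falling back to the most frequent affirmed one; diagnosis date = earliest
#' affirmed occurrence of that code), run the metastasis-onset heuristic
#' only when candidate occurrences exist, then assemble treatment acts.
#' When no tumor-location code is affirmed but unknown-primary keyword
#' occurrences exist, the primary site is `UNKNOWN_PRIMARY` (the CUP
#' situation: a work-up that fails to identify the site of origin).
#'
#' @param occurrences occurrence data.frame of one patient.
#' @param params an [onset_params()].
#' @return a `patient_profile` list; zero occurrences yield an empty
#'   profile, not an error.
#' @export
build_profile <- function(occurrences, params = onset_params()) {
  pid <- if (nrow(occurrences)) occurrences$patient_id[1] else NA_character_
  empty <- structure(
    list(patient_id = pid, cancers = list(), acts = list(),
         document_ids = character(0), diagnostics = NULL),
    class = "patient_profile"
  )
  if (!nrow(occurrences)) return(empty)
  occ <- deduplicate_occurrences(occurrences)
  occ <- corroborate_with_discharge(occ)

  affirmed <- occ[occ$context == "AFFIRMED", , drop = FALSE]
  loc <- affirmed[affirmed$category == "TUMOR_LOCATION" & !is.na(affirmed$code), , drop = FALSE]
  primary_site <- most_frequent(loc$code[loc$corroborated])
  if (is.na(primary_site)) primary_site <- most_frequent(loc$code)

  if (is.na(primary_site)) {
    has_cup_kw <- any(affirmed$category == "UNKNOWN_PRIMARY_KEYWORD")
    if (!has_cup_kw) return(empty)
    primary_site <- "UNKNOWN_PRIMARY"
    anchors <- affirmed[affirmed$category %in%
                          c("UNKNOWN_PRIMARY_KEYWORD", "METASTASIS"), , drop = FALSE]
    diagnosis_date <- min(anchors$date)
    primary_support <- anchors$source_id[anchors$date == diagnosis_date]
  } else {
    mine <- loc[loc$code == primary_site, , drop = FALSE]
    diagnosis_date <- min(mine$date)
    primary_support <- mine$source_id[mine$date == diagnosis_date]
  }

  morph <- affirmed[affirmed$category == "MORPHOLOGY" & !is.na(affirmed$code), , drop = FALSE]
  morphology <- most_frequent(morph$code)

  # onset heuristic runs only when candidates exist (conditional rule)
  site_arg <- if (primary_site == "UNKNOWN_PRIMARY") NULL else primary_site
  cand <- onset_candidates(occ, site_arg)
  diagnostics <- NULL
  metastatic_onset <- as.Date(NA)
  met_support <- character(0)
  if (nrow(cand)) {
    diagnostics <- infer_metastasis_onset(occ, params, site_arg)
    metastatic_onset <- diagnostics$chosen_onset
    if (!is.na(metastatic_onset)) {
      inside <- cand$date >= metastatic_onset &
        cand$date < metastatic_onset + params$interval_days
      met_support <- unique(cand$source_id[inside])
    }
  }
  # the profile invariant: metastatic relapse never precedes diagnosis
  if (!is.na(metastatic_onset) && metastatic_onset < diagnosis_date) {
    diagnosis_date <- metastatic_onset
  }

  events <- list(list(kind = "PRIMARY", date = diagnosis_date,
                      supporting = unique(primary_support)))
  local_rel <- occ[occ$category == "RELAPSE" & occ$context == "AFFIRMED" &
                     (is.na(occ$code) | occ$code == "LOCAL"), , drop = FALSE]
  lr_dates <- unique(local_rel$date)
  for (k in seq_along(lr_dates)) {
    events[[length(events) + 1L]] <- list(
      kind = "LOCAL_RELAPSE", date = lr_dates[k],
      supporting = unique(local_rel$source_id[local_rel$date == lr_dates[k]])
    )
  }
  if (!is.na(metastatic_onset)) {
    events[[length(events) + 1L]] <- list(
      kind = "METASTATIC_RELAPSE", date = metastatic_onset, supporting = met_support
    )
  }
  events <- events[order(vapply(events, function(e) as.numeric(e$date), 0),
                         vapply(events, `[[`, "", "kind"))]

  tx <- occ[occ$category == "TREATMENT" & occ$context == "AFFIRMED" &
              occ$source == "REPORT", , drop = FALSE]
  acts <- list()
  if (nrow(tx)) {
    key <- paste(tx$code, as_iso(tx$date))
    for (k in unique(key)) {
      rows <- tx[key == k, , drop = FALSE]
      acts[[length(acts) + 1L]] <- list(
        type = rows$code[1], date = rows$date[1],
        corroborated = any(rows$corroborated),
        supporting = unique(rows$source_id)
      )
    }
    acts <- acts[order(vapply(acts, function(a) as.numeric(a$date), 0),
                       vapply(acts, `[[`, "", "type"))]
  }

  structure(
    list(
      patient_id = pid,
      cancers = list(list(
        primary_site = primary_site, morphology = morphology,
        diagnosis_date = diagnosis_date, tumor_events = events
      )),
      acts = acts,
      document_ids = sort(unique(occ$source_id[occ$source == "REPORT"])),
      diagnostics = diagnostics
    ),
    class = "patient_profile"
  )
}

#' Structure every patient of an occurrence store
#'
#' @param store occurrence data.frame (all patients).
#' @param params an [onset_params()].
#' @return named list of `patient_profile`s keyed by patient id.
#' @export
structure_patients <- function(store, params = onset_params()) {
  ids <- sort(unique(store$patient_id))
  profiles <- lapply(ids, function(pid) {
    build_profile(occurrences_for_patient(store, pid), params)
  })
  names(profiles) <- ids
  profiles
}

profile_diagnosis_date <- function(profile) {
  if (!length(profile$cancers)) return(as.Date(NA))
  profile$cancers[[1]]$diagnosis_date
}

profile_metastatic_onset <- function(profile) {
  if (!length(profile$cancers)) return(as.Date(NA))
  for (e in profile$cancers[[1]]$tumor_events) {
    if (e$kind == "METASTATIC_RELAPSE") return(e$date)
  }
  as.Date(NA)
}

profile_primary_site <- function(profile) {
  if (!length(profile$cancers)) return(NA_character_)
  profile$cancers[[1]]$primary_site
}

profile_record <- function(profile) {
  list(
    patient_id = profile$patient_id,
    cancers = lapply(profile$cancers, function(cn) {
      list(
        primary_site = cn$primary_site,
        morphology = if (is.na(cn$morphology)) NULL else cn$morphology,
        diagnosis_date = as_iso(cn$diagnosis_date),
        tumor_events = lapply(cn$tumor_events, function(e) {
          list(kind = e$kind, date = as_iso(e$date), supporting = as.list(e$supporting))
        })
      )
    }),
    acts = lapply(profile$acts, function(a) {
      list(type = a$type, date = as_iso(a$date), corroborated = a$corroborated,
           supporting = as.list(a$supporting))
    }),
    document_ids = as.list(profile$document_ids)
  )
}

#' Write patient profiles to JSON Lines
#'
#' @param profiles named list of `patient_profile`s.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_profiles <- function(profiles, path) {
  write_jsonl(lapply(profiles, profile_record), path)
}
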