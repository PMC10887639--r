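PRIMARY_SITES <- data.frame(
  code = c("C50.9", "C34.9", "C18.9", "C61", "C25.9", "C56", "C16.9", "C64"),
  label = c("cancer du sein", "cancer du poumon", "cancer du colon",
            "cancer de la prostate", "cancer du pancréas", "cancer de l'ovaire",
            "cancer de l'estomac", "cancer du rein"),
  stringsAsFactors = FALSE
)

MORPHOLOGIES <- data.frame(
  code = c("8140/3", "8500/3", "8070/3", "8246/3"),
  label = c("adénocarcinome", "carcinome canalaire", "carcinome épidermoïde",
            "carcinome neuroendocrine"),
  stringsAsFactors = FALSE
)

METASTASIS_SITES <- data.frame(
  code = c("C78.7", "C79.5", "C78.0"),
  label = c("métastase hépatique", "métastase osseuse", "métastase pulmonaire"),
  stringsAsFactors = FALSE
)

# Accented surface forms of the ten CUP keyword phrases; their normalized
# forms are the UNKNOWN_PRIMARY_KEYWORD lexicon entries.
CUP_PHRASES <- c(
  "ACUP", "primitif inconnu", "de primitif inconnu", "sans primitif retrouvé",
  "sans primitif connu", "d'origine indéterminée", "pas de primitif retrouvé",
  "d'origine inconnue", "recherche de la tumeur primitive", "autre primitif"
)

TREATMENT_TYPES <- c("SURGERY", "CHEMO", "RADIO", "IMMUNO")
TREATMENT_SURFACES <- c(
  SURGERY = "intervention chirurgicale", CHEMO = "chimiothérapie",
  RADIO = "radiothérapie", IMMUNO = "immunothérapie"
)
RESPONSE_SURFACES <- c(
  PARTIAL = "réponse partielle", COMPLETE = "réponse complète",
  PROGRESSION = "progression"
)

DEACCENT_FROM <- "àáâãäåçèéêëìíîïñòóôõöùúûüýÿÀÁÂÃÄÅÇÈÉÊËÌÍÎÏÑÒÓÔÕÖÙÚÛÜÝ"
DEACCENT_TO <- "aaaaaaceeeeiiiinooooouuuuyyAAAAAACEEEEIIIINOOOOOUUUUY"

# Case-preserving accent removal, used to mix accented and unaccented
# spellings in rendered reports (forces accent-insensitive matching).
deaccent <- function(x) chartr(DEACCENT_FROM, DEACCENT_TO, x)

#' Configuration of a synthetic corpus
#'
#' Defaults define the simulated study conditions: 500 patients, a CUP
#' prevalence of 3% (CUP accounts for under 5% of all cancers), 40% of
#' non-CUP patients developing metastases, one fifth of eligible reports
#' carrying a negated metastasis phrase and one tenth a hypothetical one.
#'
#' @param n_patients number of simulated patients.
#' @param cup_prevalence fraction of patients with cancer of unknown
#'   primary; must lie in `[0, 0.05]`.
#' @param metastatic_fraction fraction of non-CUP patients whose disease
#'   becomes metastatic.
#' @param reports_per_patient integer range `c(min, max)` of reports per
#'   patient.
#' @param history_redundancy_prob probability that a report after the first
#'   repeats the patient's history section verbatim.
#' @param negation_rate probability that an eligible report carries a
#'   negated metastasis phrase.
#' @param hypothesis_rate probability that an eligible report carries a
#'   hypothetical metastasis phrase.
#' @param explicit_date_rate probability that a key mention carries its own
#'   date phrase (otherwise the document date is the downstream fallback).
#' @param n_centres number of simulated centres (round-robin partition).
#' @param seed integer seed; the same configuration yields a byte-identical
#'   corpus.
#' @return a `corpus_config` list.
#' @export
corpus_config <- function(n_patients = 500L,
                          cup_prevalence = 0.03,
                          metastatic_fraction = 0.4,
                          reports_per_patient = c(4L, 8L),
                          history_redundancy_prob = 0.6,
                          negation_rate = 0.2,
                          hypothesis_rate = 0.1,
                          explicit_date_rate = 0.6,
                          n_centres = 4L,
                          seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), cup_prevalence = cup_prevalence,
    metastatic_fraction = metastatic_fraction,
    reports_per_patient = as.integer(reports_per_patient),
    history_redundancy_prob = history_redundancy_prob,
    negation_rate = negation_rate, hypothesis_rate = hypothesis_rate,
    explicit_date_rate = explicit_date_rate,
    n_centres = as.integer(n_centres), seed = as.integer(seed)
  )
  if (cfg$n_patients < 1L) stop_config("n_patients must be positive")
  if (cfg$n_centres < 1L) stop_config("n_centres must be positive")
  fracs <- c("cup_prevalence", "metastatic_fraction", "history_redundancy_prob",
             "negation_rate", "hypothesis_rate", "explicit_date_rate")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop_config(f, " must be a fraction in [0, 1]")
    }
  }
  if (cfg$cup_prevalence > 0.05) {
    stop_config("cup_prevalence must not exceed 0.05 (CUP account for <5% of cancers)")
  }
  if (length(cfg$reports_per_patient) != 2L ||
      any(cfg$reports_per_patient < 1L) ||
      cfg$reports_per_patient[1] > cfg$reports_per_patient[2]) {
    stop_config("reports_per_patient must be an increasing positive integer range")
  }
  class(cfg) <- "corpus_config"
  cfg
}

#' Draw one ground-truth disease course
#'
#' Deterministic given `(config$seed, draw_index)`: patient `draw_index`
#' always gets the same course regardless of which other patients are drawn.
#' A CUP course has `primary_site = "UNKNOWN_PRIMARY"` and its metastatic
#' onset at the diagnosis date (a diagnostic work-up that fails to identify
#' the site of origin at the time of diagnosis).
#'
#' @param config a [corpus_config()].
#' @param draw_index patient index in `1:config$n_patients`.
#' @return a `disease_course` list.
#' @export
generate_course <- function(config, draw_index) {
  if (!inherits(config, "corpus_config")) config <- do.call(corpus_config, config)
  draw_index <- as.integer(draw_index)
  if (draw_index < 1L || draw_index > config$n_patients) {
    stop("draw_index must lie in 1:n_patients")
  }
  with_seed(derive_seed(config$seed, 1L, draw_index), {
    sex <- sample(c("F", "M"), 1L)
    birth_year <- sample(1930:1985, 1L)
    diagnosis_date <- as.Date("2010-01-01") + sample(0:4382, 1L)
    is_cup <- stats::runif(1) < config$cup_prevalence
    met_row <- sample(nrow(METASTASIS_SITES), 1L)
    if (is_cup) {
      primary_site <- "UNKNOWN_PRIMARY"
      morphology <- MORPHOLOGIES$code[sample(nrow(MORPHOLOGIES), 1L)]
      metastatic_onset <- diagnosis_date
      metastasis_code <- METASTASIS_SITES$code[met_row]
    } else {
      sites <- PRIMARY_SITES
      if (sex == "M") sites <- sites[sites$code != "C56", ]
      if (sex == "F") sites <- sites[sites$code != "C61", ]
      site_row <- sites[sample(nrow(sites), 1L), ]
      primary_site <- site_row$code
      morphology <- if (primary_site == "C50.9") {
        MORPHOLOGIES$code[sample(c(1L, 2L), 1L)]
      } else {
        MORPHOLOGIES$code[sample(nrow(MORPHOLOGIES), 1L)]
      }
      if (stats::runif(1) < config$metastatic_fraction) {
        metastatic_onset <- diagnosis_date + sample(60:720, 1L)
        metastasis_code <- METASTASIS_SITES$code[met_row]
      } else {
        metastatic_onset <- as.Date(NA)
        metastasis_code <- NA_character_
      }
    }
    n_t <- sample(1:3, 1L)
    types <- sample(TREATMENT_TYPES, n_t)
    starts <- diagnosis_date + sort(sample(10:400, n_t))
    sessions <- ifelse(types %in% c("CHEMO", "IMMUNO"), sample(3:6, n_t, replace = TRUE), 1L)
    response <- ifelse(
      types %in% c("CHEMO", "IMMUNO"),
      sample(c(NA, names(RESPONSE_SURFACES)), n_t, replace = TRUE),
      NA_character_
    )
    course <- list(
      patient_id = sprintf("P%05d", draw_index),
      draw_index = draw_index,
      sex = sex,
      birth_year = birth_year,
      primary_site = primary_site,
      morphology = morphology,
      diagnosis_date = diagnosis_date,
      metastatic_onset = metastatic_onset,
      is_cup = is_cup,
      metastasis_code = metastasis_code,
      treatments = data.frame(
        type = types, start_date = starts, sessions = as.integer(sessions),
        response = response, stringsAsFactors = FALSE
      )
    )
    class(course) <- "disease_course"
    validate_course(course)
    course
  })
}

validate_course <- function(course) {
  if (!is.na(course$metastatic_onset) &&
      course$metastatic_onset < course$diagnosis_date) {
    stop("metastatic_onset precedes diagnosis_date")
  }
  if (course$is_cup) {
    if (course$primary_site != "UNKNOWN_PRIMARY") stop("CUP course must have UNKNOWN_PRIMARY site")
    if (is.na(course$metastatic_onset) ||
        course$metastatic_onset != course$diagnosis_date) {
      stop("CUP course must be metastatic at diagnosis")
    }
  }
  if (nrow(course$treatments) &&
      any(course$treatments$start_date < course$diagnosis_date)) {
    stop("treatment starts before diagnosis")
  }
  invisible(course)
}

# --- document builder: appends text while tracking gold mention spans ------

new_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$chunks <- character(0)
  b$pos <- 0L
  b$gold <- list()
  b
}

b_text <- function(b, s) {
  b$chunks[[length(b$chunks) + 1L]] <- s
  b$pos <- b$pos + nchar(s)
  invisible(b)
}

b_mention <- function(b, s, category, context = "AFFIRMED", linked_date = as.Date(NA)) {
  b$gold[[length(b$gold) + 1L]] <- list(
    start = b$pos, end = b$pos + nchar(s), term = s,
    category = category, context = context, linked_date = linked_date
  )
  b_text(b, s)
}

b_result <- function(b) {
  gold <- if (length(b$gold)) {
    data.frame(
      start = vapply(b$gold, `[[`, 0L, "start"),
      end = vapply(b$gold, `[[`, 0L, "end"),
      term = vapply(b$gold, `[[`, "", "term"),
      category = vapply(b$gold, `[[`, "", "category"),
      context = vapply(b$gold, `[[`, "", "context"),
      linked_date = as.Date(vapply(b$gold, function(g) as_iso(g$linked_date), character(1)),
                            format = "%Y-%m-%d"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(start = integer(0), end = integer(0), term = character(0),
               category = character(0), context = character(0),
               linked_date = as.Date(character(0)), stringsAsFactors = FALSE)
  }
  list(text = paste(b$chunks, collapse = ""), gold = gold)
}

# insert a prebuilt (text, gold) fragment, shifting its gold spans
b_fragment <- function(b, frag) {
  if (nrow(frag$gold)) {
    for (i in seq_len(nrow(frag$gold))) {
      g <- frag$gold[i, ]
      b$gold[[length(b$gold) + 1L]] <- list(
        start = b$pos + g$start, end = b$pos + g$end, term = g$term,
        category = g$category, context = g$context, linked_date = g$linked_date
      )
    }
  }
  b_text(b, frag$text)
}

# --- report templates -------------------------------------------------------

maybe_deaccent <- function(s, p = 0.3) if (stats::runif(1) < p) deaccent(s) else s

date_phrase <- function(date) {
  format_date_fr(date, sample(c("prose", "numeric"), 1L))
}

capitalize <- function(s) {
  paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
}

label_for_code <- function(code, table) table$label[match(code, table$code)]

build_history <- function(course, config) {
  b <- new_builder()
  if (course$is_cup) {
    phrase <- maybe_deaccent(sample(CUP_PHRASES, 1L))
    b_text(b, "Antécédents : carcinome métastatique, ")
    b_mention(b, phrase, "UNKNOWN_PRIMARY_KEYWORD", "AFFIRMED", course$diagnosis_date)
    b_text(b, " ; ")
    if (stats::runif(1) < config$explicit_date_rate) {
      b_mention(b, maybe_deaccent("maladie métastatique"), "METASTASIS", "AFFIRMED",
                course$diagnosis_date)
      b_text(b, paste0(" d'emblée, diagnostiquée le ",
                       date_phrase(course$diagnosis_date), "."))
    } else {
      b_mention(b, maybe_deaccent("maladie métastatique"), "METASTASIS", "AFFIRMED",
                as.Date(NA))
      b_text(b, " d'emblée.")
    }
  } else {
    site <- maybe_deaccent(label_for_code(course$primary_site, PRIMARY_SITES))
    morph <- maybe_deaccent(label_for_code(course$morphology, MORPHOLOGIES))
    b_text(b, "Antécédents : ")
    if (stats::runif(1) < config$explicit_date_rate) {
      b_mention(b, capitalize(site), "TUMOR_LOCATION", "AFFIRMED", course$diagnosis_date)
      b_text(b, " (")
      b_mention(b, morph, "MORPHOLOGY", "AFFIRMED", course$diagnosis_date)
      b_text(b, paste0(") diagnostiqué le ", date_phrase(course$diagnosis_date), "."))
    } else {
      b_mention(b, capitalize(site), "TUMOR_LOCATION", "AFFIRMED", as.Date(NA))
      b_text(b, " (")
      b_mention(b, morph, "MORPHOLOGY", "AFFIRMED", as.Date(NA))
      b_text(b, ").")
    }
  }
  b_result(b)
}

DOCTOR_NAMES <- c("MARTIN", "BERNARD", "DURAND", "PETIT", "ROBERT", "MOREAU")

doc_header <- function(course, doc_date, doc_type) {
  kind <- switch(doc_type,
    CONSULTATION = "Compte rendu de consultation",
    HOSPITALISATION = "Compte rendu d'hospitalisation",
    PATHOLOGY = "Compte rendu d'anatomopathologie"
  )
  sprintf("%s du %s. Dossier %d. Médecin : Dr %s. ",
          kind, format_date_fr(doc_date, "numeric"),
          1200000L + course$draw_index * 7L,
          sample(DOCTOR_NAMES, 1L))
}

# negated / hypothetical metastasis sentences (appended to eligible reports)
add_negation_sentence <- function(b) {
  pick <- sample(3L, 1L)
  if (pick == 1L) {
    b_text(b, "Pas de ")
    b_mention(b, maybe_deaccent("métastase"), "METASTASIS", "NEGATED")
    b_text(b, " décelée. ")
  } else if (pick == 2L) {
    b_text(b, "Absence de ")
    b_mention(b, maybe_deaccent("métastase"), "METASTASIS", "NEGATED")
    b_text(b, " à l'imagerie. ")
  } else {
    b_text(b, "Aucune ")
    b_mention(b, maybe_deaccent("métastase hépatique"), "METASTASIS", "NEGATED")
    b_text(b, " visible. ")
  }
}

add_hypothesis_sentence <- function(b) {
  pick <- sample(3L, 1L)
  if (pick == 1L) {
    b_text(b, "Suspicion de ")
    b_mention(b, maybe_deaccent("métastase osseuse"), "METASTASIS", "HYPOTHETICAL")
    b_text(b, ". ")
  } else if (pick == 2L) {
    b_text(b, "Possible ")
    b_mention(b, maybe_deaccent("métastase"), "METASTASIS", "HYPOTHETICAL")
    b_text(b, ". ")
  } else {
    b_text(b, "Recherche de ")
    b_mention(b, maybe_deaccent("métastase"), "METASTASIS", "HYPOTHETICAL")
    b_text(b, " en cours. ")
  }
}

#' Render the report corpus of one disease course
#'
#' Produces chronologically ordered French-like reports with character-exact
#' gold annotations: a diagnosis report, a pathology report, one report per
#' treatment start, response follow-ups, metastasis-onset and progression
#' reports for metastatic courses, plus surveillance reports. Reports after
#' the first repeat the history section verbatim with probability
#' `history_redundancy_prob`; negated and hypothetical metastasis phrases
#' are injected at the configured rates into reports that precede the
#' metastatic onset (or any report of a never-metastatic course). Affirmed
#' metastasis mentions only appear in reports dated on or after the onset.
#'
#' @param course a `disease_course`.
#' @param config the [corpus_config()] used to draw it.
#' @return list of synthetic documents, each a list with `doc_id`,
#'   `patient_id`, `doc_date`, `doc_type`, `text` and a `gold` data.frame of
#'   (0-based half-open) annotated spans.
#' @export
render_documents <- function(course, config) {
  if (!inherits(config, "corpus_config")) config <- do.call(corpus_config, config)
  validate_course(course)
  with_seed(derive_seed(config$seed, 2L, course$draw_index), {
    history <- build_history(course, config)
    onset <- course$metastatic_onset
    met_label <- if (!is.na(course$metastasis_code)) {
      label_for_code(course$metastasis_code, METASTASIS_SITES)
    } else {
      NA_character_
    }

    specs <- list()
    push <- function(date, type, body) {
      specs[[length(specs) + 1L]] <<- list(date = date, type = type, body = body)
    }

    # diagnosis consultation
    push(course$diagnosis_date, "CONSULTATION", function(b, with_history) {
      if (with_history) { b_fragment(b, history); b_text(b, " ") }
      if (course$is_cup) {
        phrase <- maybe_deaccent(sample(CUP_PHRASES, 1L))
        b_text(b, "Bilan étiologique : ")
        b_mention(b, phrase, "UNKNOWN_PRIMARY_KEYWORD")
        b_text(b, " à ce jour. TEP-TDM : ")
        b_mention(b, maybe_deaccent(met_label), "METASTASIS", "AFFIRMED", onset)
        b_text(b, " confirmée. ")
      } else {
        b_text(b, "Examen clinique sans particularité. ")
        if (course$primary_site == "C50.9") {
          b_text(b, "Statut ")
          b_mention(b, "HER2", "BIOMARKER")
          b_text(b, " positif, ")
          b_mention(b, maybe_deaccent("récepteurs hormonaux"), "BIOMARKER")
          b_text(b, " positifs. ")
        }
      }
    })

    # pathology report
    push(course$diagnosis_date + 7L, "PATHOLOGY", function(b, with_history) {
      if (with_history) { b_fragment(b, history); b_text(b, " ") }
      morph <- maybe_deaccent(label_for_code(course$morphology, MORPHOLOGIES))
      b_text(b, "Prélèvement analysé : ")
      b_mention(b, morph, "MORPHOLOGY")
      if (course$is_cup) {
        phrase <- maybe_deaccent(sample(CUP_PHRASES, 1L))
        b_text(b, ", aspect ")
        b_mention(b, phrase, "UNKNOWN_PRIMARY_KEYWORD")
        b_text(b, ". ")
      } else {
        site <- maybe_deaccent(label_for_code(course$primary_site, PRIMARY_SITES))
        b_text(b, ", en rapport avec le ")
        b_mention(b, site, "TUMOR_LOCATION")
        b_text(b, " connu. ")
      }
    })

    # one report per treatment start, plus response follow-ups
    if (nrow(course$treatments)) {
      for (i in seq_len(nrow(course$treatments))) {
        tr <- course$treatments[i, ]
        surface <- TREATMENT_SURFACES[[tr$type]]
        push(tr$start_date, if (tr$type == "SURGERY") "HOSPITALISATION" else "CONSULTATION",
             local({
               tr <- tr; surface <- surface
               function(b, with_history) {
                 if (with_history) { b_fragment(b, history); b_text(b, " ") }
                 b_text(b, "Début de ")
                 if (stats::runif(1) < config$explicit_date_rate) {
                   b_mention(b, maybe_deaccent(surface), "TREATMENT", "AFFIRMED", tr$start_date)
                   b_text(b, paste0(" le ", date_phrase(tr$start_date), ". "))
                 } else {
                   b_mention(b, maybe_deaccent(surface), "TREATMENT")
                   b_text(b, ". ")
                 }
               }
             }))
        if (!is.na(tr$response)) {
          push(tr$start_date + 100L, "CONSULTATION",
               local({
                 tr <- tr; surface <- surface
                 function(b, with_history) {
                   if (with_history) { b_fragment(b, history); b_text(b, " ") }
                   b_text(b, "Après ")
                   b_mention(b, maybe_deaccent(surface), "TREATMENT")
                   b_text(b, ", ")
                   b_mention(b, maybe_deaccent(RESPONSE_SURFACES[[tr$response]]),
                             "TREATMENT_RESPONSE")
                   b_text(b, ". ")
                 }
               }))
        }
      }
    }

    # metastatic onset and progression reports (non-CUP; CUP reports carry
    # their metastasis mentions from diagnosis)
    if (!course$is_cup && !is.na(onset)) {
      push(onset, "CONSULTATION", function(b, with_history) {
        if (with_history) { b_fragment(b, history); b_text(b, " ") }
        b_text(b, "Apparition d'une ")
        if (stats::runif(1) < config$explicit_date_rate) {
          b_mention(b, maybe_deaccent(met_label), "METASTASIS", "AFFIRMED", onset)
          b_text(b, paste0(" diagnostiquée le ", date_phrase(onset), ". "))
        } else {
          b_mention(b, maybe_deaccent(met_label), "METASTASIS", "AFFIRMED", as.Date(NA))
          b_text(b, ". ")
        }
      })
      push(onset + 60L, "CONSULTATION", function(b, with_history) {
        if (with_history) { b_fragment(b, history); b_text(b, " ") }
        b_mention(b, capitalize("progression"), "TREATMENT_RESPONSE")
        b_text(b, " de la maladie avec ")
        b_mention(b, maybe_deaccent(met_label), "METASTASIS")
        b_text(b, " connue. ")
      })
    }
    if (course$is_cup) {
      push(course$diagnosis_date + 45L, "CONSULTATION", function(b, with_history) {
        if (with_history) { b_fragment(b, history); b_text(b, " ") }
        phrase <- maybe_deaccent(sample(CUP_PHRASES, 1L))
        b_text(b, "Carcinome, ")
        b_mention(b, phrase, "UNKNOWN_PRIMARY_KEYWORD")
        b_text(b, " ; ")
        b_mention(b, maybe_deaccent(met_label), "METASTASIS")
        b_text(b, " en aggravation radiologique. ")
      })
    }

    # surveillance fillers up to the drawn report count
    target <- sample(config$reports_per_patient[1]:config$reports_per_patient[2], 1L)
    n_fill <- max(0L, target - length(specs))
    if (n_fill > 0L) {
      fill_dates <- course$diagnosis_date + sort(sample(30:900, n_fill))
      for (d in as.list(fill_dates)) {
        push(as.Date(d, origin = "1970-01-01"), "CONSULTATION", function(b, with_history) {
          if (with_history) { b_fragment(b, history); b_text(b, " ") }
          b_text(b, "Consultation de surveillance. État général conservé. ")
        })
      }
    }

    # chronological order; stable doc ids
    ord <- order(vapply(specs, function(s) as.numeric(s$date), 0),
                 seq_along(specs))
    specs <- specs[ord]

    docs <- vector("list", length(specs))
    for (k in seq_along(specs)) {
      s <- specs[[k]]
      b <- new_builder()
      b_text(b, doc_header(course, s$date, s$type))
      with_history <- k == 1L || stats::runif(1) < config$history_redundancy_prob
      s$body(b, with_history)
      # noise injection: negation/hypothesis phrases never violate
      # gold-consistency (affirmed metastasis only on/after onset)
      eligible <- !course$is_cup && (is.na(onset) || s$date < onset)
      if (eligible && stats::runif(1) < config$negation_rate) add_negation_sentence(b)
      if (eligible && stats::runif(1) < config$hypothesis_rate) add_hypothesis_sentence(b)
      out <- b_result(b)
      docs[[k]] <- list(
        doc_id = sprintf("%s-D%02d", course$patient_id, k),
        patient_id = course$patient_id,
        doc_date = s$date,
        doc_type = s$type,
        text = out$text,
        gold = out$gold
      )
    }
    docs
  })
}

#' Simulate hospital-discharge records for a disease course
#'
#' One record per simulated stay, mirroring French PMSI coding practice:
#' surgery yields a stay with a CCAM act, each chemotherapy or immunotherapy
#' session a stay coded Z51.1 (session without drug detail), radiotherapy a
#' stay coded Z51.0; the course's tumor code appears as main or associated
#' ICD-10 diagnosis and stays on or after the metastatic onset carry a
#' secondary-malignancy (C77-C79) associated code. Records carry stay dates
#' only, never a diagnosis date. A course with no treatments and no
#' metastatic phase yields no stays.
#'
#' @param course a `disease_course`.
#' @return list of discharge records (see [discharge_record()]).
#' @export
generate_pmsi <- function(course) {
  validate_course(course)
  primary_code <- if (course$is_cup) "C80.9" else course$primary_site
  onset <- course$metastatic_onset
  stays <- list()
  k <- 0L
  add <- function(admission, discharge, main, assoc = character(0), acts = character(0)) {
    k <<- k + 1L
    stays[[k]] <<- discharge_record(
      stay_id = sprintf("%s-S%02d", course$patient_id, k),
      patient_id = course$patient_id,
      admission_date = admission, discharge_date = discharge,
      main_dx_icd10 = main, associated_dx_icd10 = assoc, acts_ccam = acts
    )
  }
  if (nrow(course$treatments)) {
    for (i in seq_len(nrow(course$treatments))) {
      tr <- course$treatments[i, ]
      if (tr$type == "SURGERY") {
        add(tr$start_date, tr$start_date + 5L, primary_code, acts = "QEFA020")
      } else if (tr$type %in% c("CHEMO", "IMMUNO")) {
        for (j in seq_len(tr$sessions)) {
          d <- tr$start_date + 21L * (j - 1L)
          add(d, d, "Z51.1", assoc = primary_code)
        }
      } else {
        add(tr$start_date, tr$start_date + 1L, "Z51.0", assoc = primary_code)
      }
    }
  }
  if (!is.na(onset)) {
    tagged <- FALSE
    for (i in seq_along(stays)) {
      if (stays[[i]]$admission_date >= onset) {
        stays[[i]]$associated_dx_icd10 <- unique(c(stays[[i]]$associated_dx_icd10,
                                                   course$metastasis_code))
        tagged <- TRUE
      }
    }
    if (!tagged) {
      add(onset + 3L, onset + 5L, primary_code, assoc = course$metastasis_code)
    }
  }
  stays
}

#' Generate a full multi-centre synthetic corpus
#'
#' Draws every patient's course, renders their reports and discharge
#' records, and partitions patients across centres round-robin by patient
#' index (disjoint, balanced, reproducible). When `out_dir` is given the
#' per-centre `documents.jsonl`, `gold.jsonl` and `pmsi.jsonl` plus the
#' top-level `ground_truth.csv` are written; identical configurations yield
#' byte-identical artifacts.
#'
#' @param config a [corpus_config()].
#' @param out_dir optional output directory.
#' @return a `synthetic_corpus` list with `config`, `courses`, `documents`,
#'   `pmsi`, `ground_truth` (data.frame) and `centre` (named integer vector
#'   mapping patient to centre).
#' @export
generate_corpus <- function(config, out_dir = NULL) {
  if (!inherits(config, "corpus_config")) config <- do.call(corpus_config, config)
  courses <- vector("list", config$n_patients)
  documents <- list()
  pmsi <- list()
  centre <- integer(config$n_patients)
  for (i in seq_len(config$n_patients)) {
    course <- generate_course(config, i)
    courses[[i]] <- course
    centre[i] <- ((i - 1L) %% config$n_centres) + 1L
    documents <- c(documents, render_documents(course, config))
    pmsi <- c(pmsi, generate_pmsi(course))
  }
  names(centre) <- vapply(courses, `[[`, "", "patient_id")
  ground_truth <- data.frame(
    patient_id = names(centre),
    centre = unname(centre),
    sex = vapply(courses, `[[`, "", "sex"),
    birth_year = vapply(courses, `[[`, 0L, "birth_year"),
    primary_site = vapply(courses, `[[`, "", "primary_site"),
    morphology = vapply(courses, `[[`, "", "morphology"),
    diagnosis_date = vapply(courses, function(cr) as_iso(cr$diagnosis_date), ""),
    metastatic_onset = vapply(courses, function(cr) {
      if (is.na(cr$metastatic_onset)) NA_character_ else as_iso(cr$metastatic_onset)
    }, ""),
    is_cup = vapply(courses, `[[`, TRUE, "is_cup"),
    metastasis_code = vapply(courses, `[[`, "", "metastasis_code"),
    n_treatments = vapply(courses, function(cr) nrow(cr$treatments), 0L),
    stringsAsFactors = FALSE
  )
  corpus <- structure(
    list(config = config, courses = courses, documents = documents,
         pmsi = pmsi, ground_truth = ground_truth, centre = centre),
    class = "synthetic_corpus"
  )
  if (!is.null(out_dir)) write_corpus(corpus, out_dir)
  corpus
}

#' Write corpus artifacts to a directory
#'
#' Creates `centre_XX/documents.jsonl`, `centre_XX/gold.jsonl`,
#' `centre_XX/pmsi.jsonl` and a top-level `ground_truth.csv`.
#'
#' @param corpus a `synthetic_corpus`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_corpus <- function(corpus, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", dir)
  centre <- corpus$centre
  for (cid in sort(unique(unname(centre)))) {
    cdir <- file.path(dir, sprintf("centre_%02d", cid))
    if (!dir.exists(cdir) && !dir.create(cdir)) stop("cannot create: ", cdir)
    pats <- names(centre)[centre == cid]
    docs <- Filter(function(d) d$patient_id %in% pats, corpus$documents)
    write_jsonl(lapply(docs, function(d) {
      list(doc_id = d$doc_id, patient_id = d$patient_id,
           doc_date = as_iso(d$doc_date), doc_type = d$doc_type, text = d$text)
    }), file.path(cdir, "documents.jsonl"))
    write_jsonl(lapply(docs, function(d) {
      g <- d$gold
      list(doc_id = d$doc_id, mentions = lapply(seq_len(nrow(g)), function(i) {
        list(start = g$start[i], end = g$end[i], term = g$term[i],
             category = g$category[i], context = g$context[i],
             linked_date = if (is.na(g$linked_date[i])) NULL else as_iso(g$linked_date[i]))
      }))
    }), file.path(cdir, "gold.jsonl"))
    recs <- Filter(function(r) r$patient_id %in% pats, corpus$pmsi)
    write_jsonl(lapply(recs, function(r) {
      list(stay_id = r$stay_id, patient_id = r$patient_id,
           admission_date = as_iso(r$admission_date),
           discharge_date = as_iso(r$discharge_date),
           main_dx_icd10 = r$main_dx_icd10,
           associated_dx_icd10 = as.list(r$associated_dx_icd10),
           acts_ccam = as.list(r$acts_ccam))
    }), file.path(cdir, "pmsi.jsonl"))
  }
  utils::write.csv(corpus$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(dir)
}
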