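CONCEPT_CATEGORIES <- c(
  "TUMOR_LOCATION", "MORPHOLOGY", "METASTASIS", "RELAPSE", "TREATMENT",
  "TREATMENT_RESPONSE", "BIOMARKER", "UNKNOWN_PRIMARY_KEYWORD", "DATE"
)

CODE_SYSTEMS <- c("ICD10", "ICDO3_TOPO", "ICDO3_MORPHO", "CCAM", "NONE")

#' Build a lexicon from a term table
#'
#' Terms are normalized (lowercase, accent-stripped, whitespace-collapsed)
#' on construction; duplicate normalized terms are an error since a term can
#' carry only one category/code pair.
#'
#' @param entries data.frame with columns `term`, `category`, `code`,
#'   `code_system`.
#' @return a `lexicon` data.frame.
#' @export
lexicon <- function(entries) {
  need <- c("term", "category", "code", "code_system")
  miss <- setdiff(need, names(entries))
  if (length(miss)) stop("lexicon is missing columns: ", paste(miss, collapse = ", "))
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)[need]
  entries$term <- gsub("[[:space:]]+", " ", trimws(strip_accents(entries$term)))
  bad <- setdiff(unique(entries$category), CONCEPT_CATEGORIES)
  if (length(bad)) stop("unknown concept categories: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(entries$code_system), CODE_SYSTEMS)
  if (length(bad)) stop("unknown code systems: ", paste(bad, collapse = ", "))
  if (anyDuplicated(entries$term)) {
    stop("duplicate lexicon terms: ",
         paste(unique(entries$term[duplicated(entries$term)]), collapse = ", "))
  }
  entries$code[is.na(entries$code) | entries$code == ""] <- NA_character_
  class(entries) <- c("lexicon", "data.frame")
  entries
}

#' Default oncology lexicon
#'
#' A closed French oncology vocabulary covering tumor locations (ICD-10 /
#' ICD-O-3 topography), morphologies (ICD-O-3), metastasis and relapse
#' phrases (secondary-malignancy ICD-10 codes), treatments, treatment
#' responses, biomarkers and the ten cancer-of-unknown-primary keyword
#' phrases used by the refined CUP cohort query.
#'
#' @return a `lexicon` data.frame.
#' @export
default_lexicon <- function() {
  e <- function(term, category, code, code_system) {
    data.frame(term = term, category = category, code = code,
               code_system = code_system, stringsAsFactors = FALSE)
  }
  entries <- rbind(
    e("cancer du sein", "TUMOR_LOCATION", "C50.9", "ICD10"),
    e("cancer du poumon", "TUMOR_LOCATION", "C34.9", "ICD10"),
    e("cancer du colon", "TUMOR_LOCATION", "C18.9", "ICD10"),
    e("cancer de la prostate", "TUMOR_LOCATION", "C61", "ICD10"),
    e("cancer du pancreas", "TUMOR_LOCATION", "C25.9", "ICD10"),
    e("cancer de l'ovaire", "TUMOR_LOCATION", "C56", "ICD10"),
    e("cancer de l'estomac", "TUMOR_LOCATION", "C16.9", "ICD10"),
    e("cancer du rein", "TUMOR_LOCATION", "C64", "ICD10"),

    e("adenocarcinome", "MORPHOLOGY", "8140/3", "ICDO3_MORPHO"),
    e("carcinome canalaire", "MORPHOLOGY", "8500/3", "ICDO3_MORPHO"),
    e("carcinome epidermoide", "MORPHOLOGY", "8070/3", "ICDO3_MORPHO"),
    e("carcinome neuroendocrine", "MORPHOLOGY", "8246/3", "ICDO3_MORPHO"),

    e("metastase", "METASTASIS", "C79.9", "ICD10"),
    e("metastase hepatique", "METASTASIS", "C78.7", "ICD10"),
    e("metastase osseuse", "METASTASIS", "C79.5", "ICD10"),
    e("metastase pulmonaire", "METASTASIS", "C78.0", "ICD10"),
    e("metastase cerebrale", "METASTASIS", "C79.3", "ICD10"),
    e("lesion secondaire", "METASTASIS", "C79.9", "ICD10"),
    e("maladie metastatique", "METASTASIS", "C79.9", "ICD10"),

    e("recidive", "RELAPSE", NA_character_, "NONE"),
    e("rechute", "RELAPSE", NA_character_, "NONE"),
    e("recidive locale", "RELAPSE", "LOCAL", "NONE"),
    e("recidive a distance", "RELAPSE", "DISTANT", "NONE"),

    e("chimiotherapie", "TREATMENT", "CHEMO", "NONE"),
    e("radiotherapie", "TREATMENT", "RADIO", "NONE"),
    e("immunotherapie", "TREATMENT", "IMMUNO", "NONE"),
    e("chirurgie", "TREATMENT", "SURGERY", "NONE"),
    e("intervention chirurgicale", "TREATMENT", "SURGERY", "NONE"),
    e("mastectomie", "TREATMENT", "SURGERY", "NONE"),

    e("reponse partielle", "TREATMENT_RESPONSE", "PARTIAL", "NONE"),
    e("reponse complete", "TREATMENT_RESPONSE", "COMPLETE", "NONE"),
    e("progression", "TREATMENT_RESPONSE", "PROGRESSION", "NONE"),

    e("her2", "BIOMARKER", NA_character_, "NONE"),
    e("recepteurs hormonaux", "BIOMARKER", NA_character_, "NONE"),

    e("acup", "UNKNOWN_PRIMARY_KEYWORD", NA_character_, "NONE"),
    e("primitif inconnu", "UNKNOWN_PRIMARY_KEYWORD", NA_character_, "NONE"),
    e("de primitif inconnu", "UNKNOWN_PRIMARY_KEYWORD", NA_character_, "NONE"),
    e("sans primitif retrouve", "UNKNOWN_PRIMARY_KEYWORD", NA_character_, "NONE"),
    e("sans primitif connu", "UNKNOWN_PRIMARY_KEYWORD", NA_character_, "NONE"),
    e("d'origine indeterminee", "UNKNOWN_PRIMARY_KEYWORD", NA_character_, "NONE"),
    e("pas de primitif retrouve", "UNKNOWN_PRIMARY_KEYWORD", NA_character_, "NONE"),
    e("d'origine inconnue", "UNKNOWN_PRIMARY_KEYWORD", NA_character_, "NONE"),
    e("recherche de la tumeur primitive", "UNKNOWN_PRIMARY_KEYWORD", NA_character_, "NONE"),
    e("autre primitif", "UNKNOWN_PRIMARY_KEYWORD", NA_character_, "NONE")
  )
  lexicon(entries)
}

#' Read a lexicon from CSV
#'
#' Expects a UTF-8 CSV with a header row `term,category,code,code_system`.
#'
#' @param path CSV path.
#' @return a `lexicon`.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = "character")
  lexicon(df)
}

#' Write a lexicon to CSV
#'
#' @param lex a `lexicon`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_lexicon <- function(lex, path) {
  utils::write.csv(as.data.frame(lex), path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

# Plural/feminine suffix table: a lexicon term also matches the surface form
# where every content word carries a plural "s" (metastases hepatiques).
# This is the only lemmatization needed for a lexicon-closed vocabulary.
term_variants <- function(term) {
  words <- strsplit(term, " ", fixed = TRUE)[[1]]
  plural <- vapply(words, function(w) {
    if (nchar(w) > 3 && !grepl("[sxz]$", w)) paste0(w, "s") else w
  }, character(1))
  unique(c(term, paste(plural, collapse = " ")))
}
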