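test_that("normalization matches the character-walk reference", {
  expect_identical(normalize_text(""), list(text = "", offsets = integer(0)))

  n <- normalize_text("Primitif  Inconnu")
  expect_identical(n$text, "primitif inconnu")
  expect_identical(n$offsets[1], 0L)    # normalized 0 -> original 0
  expect_identical(n$offsets[10], 10L)  # normalized 9 -> original 10

  n <- normalize_text("d’origine indéterminée")
  expect_identical(n$text, "d'origine indeterminee")

  cfg <- small_config(n_patients = 6L)
  corp <- generate_corpus(cfg)
  for (d in corp$documents[1:10]) {
    expect_identical(normalize_text(d$text), walk_normalize(d$text))
  }
})

test_that("identifier redaction replaces typed patterns and is idempotent", {
  expect_identical(redact_identifiers("Bilan sans anomalie."), "Bilan sans anomalie.")
  expect_identical(redact_identifiers("N° dossier 1234567"), "N° dossier <ID>")
  expect_identical(redact_identifiers("Vu par Dr Martin le 02/03/2021"),
                   "Vu par <NAME> le 02/03/2021")
  expect_identical(redact_identifiers("contact: a.b@hopital.fr"), "contact: <EMAIL>")
  corp <- generate_corpus(small_config(n_patients = 5L))
  for (d in corp$documents) {
    once <- redact_identifiers(d$text)
    expect_identical(redact_identifiers(once), once)
  }
})

test_that("mention detection is longest-match-first and accent-insensitive", {
  lex <- default_lexicon()
  expect_identical(nrow(detect_mentions("rien de notable ce jour", lex)), 0L)

  m <- detect_mentions("carcinome de primitif inconnu", lex)
  expect_identical(m$term, "de primitif inconnu")
  expect_identical(m$category, "UNKNOWN_PRIMARY_KEYWORD")
  expect_identical(substr("carcinome de primitif inconnu", m$start + 1, m$end),
                   "de primitif inconnu")

  m <- detect_mentions("Métastases hépatiques multiples", lex)
  expect_identical(m$category, "METASTASIS")
  expect_identical(m$code, "C78.7")

  # word boundaries: no match inside a longer word
  expect_identical(nrow(detect_mentions("acupuncture sans effet", lex)), 0L)

  # determinism
  t <- "cancer du sein avec métastase osseuse"
  expect_identical(detect_mentions(t, lex), detect_mentions(t, lex))
})

test_that("context classification follows trigger windows and scope breaks", {
  lex <- default_lexicon()
  ctx_of <- function(text) {
    m <- detect_mentions(text, lex)
    m <- m[m$category == "METASTASIS", , drop = FALSE][1, ]
    classify_context(m, text)
  }
  expect_identical(ctx_of("métastase hépatique confirmée"), "AFFIRMED")
  expect_identical(ctx_of("pas de métastase décelée"), "NEGATED")
  expect_identical(ctx_of("suspicion de métastase osseuse"), "HYPOTHETICAL")
  expect_identical(ctx_of("absence de nouvelle métastase"), "NEGATED")
  # scope breakers cut the trigger window
  expect_identical(ctx_of("pas de fièvre, métastase hépatique connue"), "AFFIRMED")
  expect_identical(ctx_of("aucun signe mais métastase osseuse avérée"), "AFFIRMED")
  # window limit: trigger more than five tokens back is out of scope
  expect_identical(
    ctx_of("suspicion chez un patient suivi depuis longtemps de métastase"),
    "AFFIRMED"
  )
})

test_that("date linking picks the nearest date in the same sentence", {
  lex <- default_lexicon()
  doc <- list(text = "métastase diagnostiquée le 24 mai 2022")
  m <- attach_dates(detect_mentions(doc$text, lex), doc)
  expect_identical(m$linked_date[m$category == "METASTASIS"], as.Date("2022-05-24"))

  # two dates flanking the mention at token distances 2 and 4: nearer wins
  doc <- list(text = "bilan du 01/02/2020 près de métastase revue puis contrôle prévu 15/07/2021")
  m <- attach_dates(detect_mentions(doc$text, lex), doc)
  expect_identical(m$linked_date[m$category == "METASTASIS"], as.Date("2020-02-01"))

  # sentence boundary blocks linking
  doc <- list(text = "métastase osseuse avérée. contrôle le 24/05/2022")
  m <- attach_dates(detect_mentions(doc$text, lex), doc)
  expect_true(is.na(m$linked_date[m$category == "METASTASIS"]))

  # an impossible calendar date is dropped rather than linked
  doc <- list(text = "métastase vue le 31/02/2021")
  expect_message(m <- attach_dates(detect_mentions(doc$text, lex), doc), "31/02/2021")
  expect_true(is.na(m$linked_date[m$category == "METASTASIS"]))
})

test_that("process_document composes redaction, contexts, dates and relations", {
  lex <- default_lexicon()
  mk <- function(text) list(doc_id = "D1", patient_id = "P1",
                            doc_date = as.Date("2022-06-01"), text = text)
  sd <- process_document(mk(""), lex)
  expect_identical(nrow(sd$mentions), 0L)

  expect_error(process_document(list(doc_id = "D1", text = "x"), lex), "patient_id")

  sd <- process_document(mk("Après chimiothérapie, réponse partielle."), lex)
  m <- sd$mentions
  resp <- which(m$category == "TREATMENT_RESPONSE")
  expect_identical(m$category[m$related_to[resp]], "TREATMENT")
  expect_identical(m$code[m$related_to[resp]], "CHEMO")

  # spans survive redaction: offsets refer to the original text
  txt <- "Dossier 9876543. Cancer du sein confirmé par Dr Durand."
  sd <- process_document(mk(txt), lex)
  loc <- sd$mentions[sd$mentions$category == "TUMOR_LOCATION", ]
  expect_identical(substr(txt, loc$start + 1, loc$end), "Cancer du sein")
  expect_true(grepl("<ID>", sd$redacted_text, fixed = TRUE))
  expect_true(grepl("<NAME>", sd$redacted_text, fixed = TRUE))

  # metastasis links to a tumor location in the same sentence
  sd <- process_document(mk("cancer du poumon avec métastase cérébrale."), lex)
  m <- sd$mentions
  met <- which(m$category == "METASTASIS")
  expect_identical(m$category[m$related_to[met]], "TUMOR_LOCATION")
})

test_that("pipeline output matches gold exactly on a zero-noise corpus", {
  cfg <- small_config(n_patients = 20L, negation_rate = 0, hypothesis_rate = 0,
                      metastatic_fraction = 0.5)
  corp <- generate_corpus(cfg)
  structured <- process_corpus(corp$documents, default_lexicon())
  score <- gold_agreement(corp, structured)
  expect_identical(score$detection_recall, 1)
  expect_identical(score$spurious, 0L)
  expect_identical(score$context_accuracy, 1)
})

test_that("every detected span normalizes back to a lexicon term", {
  lex <- default_lexicon()
  corp <- generate_corpus(small_config(n_patients = 8L))
  for (d in corp$documents[1:20]) {
    m <- detect_mentions(d$text, lex)
    for (i in seq_len(nrow(m))) {
      surf <- normalize_text(substr(d$text, m$start[i] + 1, m$end[i]))$text
      vars <- unlist(lapply(lex$term, oncotext:::term_variants))
      expect_true(surf %in% vars)
    }
  }
})
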