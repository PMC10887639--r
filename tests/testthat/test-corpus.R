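test_that("course generation respects forced branches and validates config", {
  cfg0 <- small_config(cup_prevalence = 0)
  courses <- lapply(1:40, generate_course, config = cfg0)
  expect_false(any(vapply(courses, `[[`, TRUE, "is_cup")))

  cfg1 <- small_config(metastatic_fraction = 1, cup_prevalence = 0)
  courses <- lapply(1:40, generate_course, config = cfg1)
  expect_true(all(!is.na(vapply(courses, function(cr) as.numeric(cr$metastatic_onset), 0))))

  expect_error(corpus_config(negation_rate = 1.2), "fraction")
  expect_error(corpus_config(cup_prevalence = 0.2), "0.05")
  expect_error(generate_course(small_config(), 0), "draw_index")
})

test_that("courses are deterministic and satisfy their invariants", {
  cfg <- small_config(n_patients = 200L, metastatic_fraction = 0.5)
  for (i in c(1L, 57L, 200L)) {
    a <- generate_course(cfg, i)
    b <- generate_course(cfg, i)
    expect_identical(a, b)
    if (!is.na(a$metastatic_onset)) {
      expect_gte(as.numeric(a$metastatic_onset - a$diagnosis_date), 0)
    }
    expect_true(all(a$treatments$start_date >= a$diagnosis_date))
    if (a$is_cup) {
      expect_identical(a$primary_site, "UNKNOWN_PRIMARY")
      expect_identical(a$metastatic_onset, a$diagnosis_date)
    }
  }
})

test_that("CUP draws fall inside exact binomial bounds", {
  cfg <- corpus_config(n_patients = 1000L, cup_prevalence = 0.04, seed = 7L)
  n_cup <- sum(vapply(1:1000, function(i) generate_course(cfg, i)$is_cup, logical(1)))
  lo <- qbinom(0.005, 1000, 0.04)
  hi <- qbinom(0.995, 1000, 0.04)
  expect_gte(n_cup, lo)
  expect_lte(n_cup, hi)
})

test_that("empirical CUP prevalence passes a binomial test at n = 5000", {
  cfg <- corpus_config(n_patients = 5000L, cup_prevalence = 0.03, seed = 19L)
  n_cup <- sum(vapply(1:5000, function(i) generate_course(cfg, i)$is_cup, logical(1)))
  expect_gt(binom.test(n_cup, 5000, p = 0.03)$p.value, 0.01)
})

test_that("rendered reports carry metastasis mentions only on or after onset", {
  cfg <- small_config(metastatic_fraction = 0.6, negation_rate = 0.3,
                      hypothesis_rate = 0.2)
  for (i in 1:15) {
    course <- generate_course(cfg, i)
    docs <- render_documents(course, cfg)
    for (d in docs) {
      g <- d$gold
      aff_met <- g[g$category == "METASTASIS" & g$context == "AFFIRMED", , drop = FALSE]
      if (nrow(aff_met)) {
        expect_false(is.na(course$metastatic_onset))
        expect_gte(as.numeric(d$doc_date - course$metastatic_onset), 0)
      }
    }
  }
})

test_that("a never-metastatic course yields no affirmed metastasis at zero noise", {
  cfg <- small_config(metastatic_fraction = 0, cup_prevalence = 0,
                      negation_rate = 0, hypothesis_rate = 0)
  for (i in 1:10) {
    docs <- render_documents(generate_course(cfg, i), cfg)
    gold <- do.call(rbind, lapply(docs, `[[`, "gold"))
    expect_identical(nrow(gold[gold$category == "METASTASIS", ]), 0L)
  }
})

test_that("a metastatic course always announces its metastasis in a dated report", {
  cfg <- small_config(metastatic_fraction = 1, cup_prevalence = 0)
  course <- generate_course(cfg, 3L)
  docs <- render_documents(course, cfg)
  hit <- FALSE
  for (d in docs) {
    g <- d$gold
    if (any(g$category == "METASTASIS" & g$context == "AFFIRMED") &&
        d$doc_date >= course$metastatic_onset) hit <- TRUE
  }
  expect_true(hit)
})

test_that("history redundancy at probability one repeats the first report verbatim", {
  cfg <- small_config(history_redundancy_prob = 1, reports_per_patient = c(4L, 6L))
  for (i in 1:8) {
    docs <- render_documents(generate_course(cfg, i), cfg)
    first <- docs[[1]]$text
    hist <- regmatches(first, regexpr("Antécédents :[^|]*?\\.", first))
    expect_length(hist, 1L)
    for (d in docs[-1]) {
      expect_true(grepl(hist, d$text, fixed = TRUE))
    }
  }
})

test_that("discharge simulation counts stays by construction", {
  base <- generate_course(small_config(metastatic_fraction = 0, cup_prevalence = 0), 1L)

  quiet <- base
  quiet$treatments <- quiet$treatments[0, ]
  quiet$metastatic_onset <- as.Date(NA)
  quiet$metastasis_code <- NA_character_
  expect_length(generate_pmsi(quiet), 0L)

  chemo2 <- quiet
  chemo2$treatments <- data.frame(
    type = c("CHEMO", "CHEMO"),
    start_date = quiet$diagnosis_date + c(30L, 200L),
    sessions = c(3L, 3L), response = NA_character_, stringsAsFactors = FALSE
  )
  stays <- generate_pmsi(chemo2)
  expect_length(stays, 6L)
  expect_true(all(vapply(stays, `[[`, "", "main_dx_icd10") == "Z51.1"))

  met <- quiet
  met$metastatic_onset <- met$diagnosis_date + 90L
  met$metastasis_code <- "C78.7"
  stays <- generate_pmsi(met)
  assoc <- unlist(lapply(stays, `[[`, "associated_dx_icd10"))
  expect_true(any(grepl("^C7[789]", assoc)))
})

test_that("corpus partitions patients disjointly and reproducibly", {
  cfg <- small_config(n_patients = 24L, n_centres = 4L, seed = 1L)
  corp <- generate_corpus(cfg)
  sets <- split(names(corp$centre), unname(corp$centre))
  expect_length(sets, 4L)
  expect_setequal(unlist(sets), corp$ground_truth$patient_id)
  for (i in seq_along(sets)) {
    for (j in seq_len(i - 1L)) expect_length(intersect(sets[[i]], sets[[j]]), 0L)
  }

  one <- generate_corpus(small_config(n_patients = 6L, n_centres = 1L))
  expect_true(all(one$centre == 1L))

  again <- generate_corpus(cfg)
  expect_identical(lapply(corp$documents, `[[`, "text"),
                   lapply(again$documents, `[[`, "text"))
  expect_identical(corp$ground_truth, again$ground_truth)
})

test_that("written corpus artifacts are byte-stable and well-formed", {
  cfg <- small_config(n_patients = 8L, n_centres = 2L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_corpus(cfg, d1)
  generate_corpus(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(all(c("centre_01/documents.jsonl", "centre_01/pmsi.jsonl",
                    "centre_01/gold.jsonl", "ground_truth.csv") %in% files))
  expect_identical(unname(tools::md5sum(file.path(d1, files))),
                   unname(tools::md5sum(file.path(d2, files))))
  docs <- read_jsonl(file.path(d1, "centre_01", "documents.jsonl"))
  expect_true(all(vapply(docs, function(d) all(c("doc_id", "patient_id", "doc_date",
                                                 "doc_type", "text") %in% names(d)),
                         logical(1))))
})

test_that("gold spans index the exact surface they annotate", {
  cfg <- small_config(n_patients = 10L, metastatic_fraction = 0.5)
  corp <- generate_corpus(cfg)
  for (d in corp$documents) {
    g <- d$gold
    for (i in seq_len(nrow(g))) {
      expect_identical(substr(d$text, g$start[i] + 1L, g$end[i]), g$term[i])
    }
  }
})
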