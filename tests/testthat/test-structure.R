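occ_row <- function(category = "METASTASIS", code = "C78.7", context = "AFFIRMED",
                    date = "2020-03-10", origin = "DOCUMENT", source = "REPORT",
                    source_id = "D1") {
  data.frame(patient_id = "P1", category = category, code = code, context = context,
             date = as.Date(date), date_origin = origin, source = source,
             source_id = source_id, recorded_at = as.Date(date),
             stringsAsFactors = FALSE)
}

test_that("deduplication keeps the richest provenance and is idempotent", {
  distinct <- rbind(occ_row(date = "2020-01-01"), occ_row(date = "2020-02-01"))
  expect_identical(nrow(deduplicate_occurrences(distinct)), 2L)

  # the same history mention copied into five reports with one linked date
  copies <- do.call(rbind, lapply(sprintf("D%02d", 1:5), function(id) {
    occ_row(origin = "CONCEPT_LINKED", source_id = id)
  }))
  dd <- deduplicate_occurrences(copies)
  expect_identical(nrow(dd), 1L)
  expect_identical(dd$source_id, "D01")  # smallest source id wins the tie

  mixed <- rbind(occ_row(origin = "DOCUMENT", source_id = "D9"),
                 occ_row(origin = "CONCEPT_LINKED", source_id = "D5"))
  dd <- deduplicate_occurrences(mixed)
  expect_identical(dd$date_origin, "CONCEPT_LINKED")

  pm <- rbind(occ_row(source = "REPORT", source_id = "D1"),
              occ_row(source = "PMSI", source_id = "S1"))
  expect_identical(deduplicate_occurrences(pm)$source, "PMSI")

  once <- deduplicate_occurrences(copies)
  expect_identical(deduplicate_occurrences(once), once)
})

test_that("discharge corroboration needs a compatible code within the window", {
  rep_dx <- occ_row(category = "TUMOR_LOCATION", code = "C50.4", date = "2021-02-01")
  pmsi_dx <- occ_row(category = "TUMOR_LOCATION", code = "C50.9",
                     date = "2021-02-10", source = "PMSI", source_id = "S1")
  both <- corroborate_with_discharge(rbind(rep_dx, pmsi_dx))
  expect_true(both$corroborated[both$source == "REPORT"])

  far <- corroborate_with_discharge(rbind(
    rep_dx, occ_row(category = "TUMOR_LOCATION", code = "C50.9",
                    date = "2022-02-10", source = "PMSI", source_id = "S1")
  ))
  expect_false(far$corroborated[far$source == "REPORT"])

  alone <- corroborate_with_discharge(rep_dx)
  expect_false(alone$corroborated)

  # treatment types match through the session coding
  tx <- rbind(occ_row(category = "TREATMENT", code = "CHEMO", date = "2021-02-01"),
              occ_row(category = "TREATMENT", code = "Z51.1", date = "2021-02-15",
                      source = "PMSI", source_id = "S2"))
  expect_true(corroborate_with_discharge(tx)$corroborated[1])

  # monotone: adding discharge data never removes a flag
  before <- corroborate_with_discharge(rbind(rep_dx, pmsi_dx))
  after <- corroborate_with_discharge(rbind(rep_dx, pmsi_dx,
                                            occ_row(category = "TUMOR_LOCATION",
                                                    code = "C34.9", date = "2021-06-01",
                                                    source = "PMSI", source_id = "S9")))
  expect_true(all(after$corroborated[seq_len(nrow(before))] >= before$corroborated))
})

test_that("onset inference handles the trivial windows", {
  none <- occ_row(category = "TUMOR_LOCATION", code = "C50.9")
  diag <- infer_metastasis_onset(none, onset_params())
  expect_identical(nrow(diag$intervals), 0L)
  expect_true(is.na(diag$chosen_onset))

  one <- occ_row(source = "PMSI", source_id = "S1")  # weight 2.0 > threshold 1.5
  diag <- infer_metastasis_onset(one, onset_params(threshold = 1.5))
  expect_identical(diag$chosen_onset, as.Date("2020-03-10"))
  expect_identical(diag$intervals$accepted, TRUE)

  below <- infer_metastasis_onset(one, onset_params(threshold = 2))  # strict >
  expect_true(is.na(below$chosen_onset))
})

test_that("onset inference equals the brute-force window oracle", {
  params <- onset_params()
  alt <- onset_params(interval_days = 90L, threshold = 2,
                      hypothetical_weight = 0.5)
  for (k in 1:60) {
    occ <- random_occurrences(n = sample(1:50, 1), seed = 1000 + k)
    for (p in list(params, alt)) {
      for (site in list(NULL, "C50.9")) {
        got <- infer_metastasis_onset(occ, p, primary_site = site)$chosen_onset
        want <- oracle_onset(occ, p, primary_site = site)
        expect_identical(got, want, label = sprintf("set %d", k))
      }
    }
  }
})

test_that("onset obeys its monotonicity laws", {
  params <- onset_params()
  for (k in 1:20) {
    occ <- random_occurrences(n = 20, seed = 2000 + k)
    base <- infer_metastasis_onset(occ, params)$chosen_onset
    # adding affirmed evidence can only keep or advance the onset
    extra <- occ_row(date = "2020-06-01", source_id = "DXX")
    more <- infer_metastasis_onset(rbind(occ, extra), params)$chosen_onset
    if (!is.na(base)) {
      expect_false(is.na(more))
      expect_lte(as.numeric(more), as.numeric(base))
    }
    # raising the threshold can only delay or remove the onset
    strict <- infer_metastasis_onset(occ, onset_params(threshold = 6))$chosen_onset
    if (!is.na(strict)) {
      expect_false(is.na(base))
      expect_gte(as.numeric(strict), as.numeric(base))
    }
  }
})

test_that("profiles resolve the primary, events and acts in rule order", {
  plain <- rbind(
    occ_row(category = "TUMOR_LOCATION", code = "C50.9", date = "2020-01-05"),
    occ_row(category = "TUMOR_LOCATION", code = "C50.9", date = "2020-02-05",
            source_id = "D2"),
    occ_row(category = "TREATMENT", code = "CHEMO", date = "2020-02-20",
            source_id = "D3")
  )
  pr <- build_profile(plain)
  expect_identical(pr$cancers[[1]]$primary_site, "C50.9")
  expect_identical(pr$cancers[[1]]$diagnosis_date, as.Date("2020-01-05"))
  kinds <- vapply(pr$cancers[[1]]$tumor_events, `[[`, "", "kind")
  expect_identical(kinds, "PRIMARY")
  expect_length(pr$acts, 1L)
  expect_false(pr$acts[[1]]$corroborated)

  empty <- build_profile(occ_row()[0, ])
  expect_length(empty$cancers, 0L)

  # events are date-sorted and the metastatic relapse never precedes diagnosis
  met <- rbind(plain,
               occ_row(date = "2020-04-01", source_id = "D4"),
               occ_row(date = "2020-05-01", source_id = "D5"),
               occ_row(date = "2020-05-15", source = "PMSI", source_id = "S1"))
  pr <- build_profile(met)
  ev <- pr$cancers[[1]]$tumor_events
  dates <- as.Date(vapply(ev, function(e) as.numeric(e$date), 0),
                   origin = "1970-01-01")
  expect_false(is.unsorted(dates))
  kinds <- vapply(ev, `[[`, "", "kind")
  expect_true("METASTATIC_RELAPSE" %in% kinds)
  expect_gte(as.numeric(dates[kinds == "METASTATIC_RELAPSE"] -
                          pr$cancers[[1]]$diagnosis_date), 0)
})

test_that("synthetic CUP patients profile as unknown primary, metastatic at diagnosis", {
  cfg <- small_config(n_patients = 80L, cup_prevalence = 0.05, seed = 7L,
                      negation_rate = 0, hypothesis_rate = 0)
  corp <- generate_corpus(cfg)
  res <- run_pipeline(corp)
  gt <- corp$ground_truth
  cups <- gt$patient_id[gt$is_cup]
  expect_gt(length(cups), 0L)
  for (pid in cups) {
    pr <- res$profiles[[pid]]
    expect_identical(pr$cancers[[1]]$primary_site, "UNKNOWN_PRIMARY")
    kinds <- vapply(pr$cancers[[1]]$tumor_events, `[[`, "", "kind")
    expect_true("METASTATIC_RELAPSE" %in% kinds)
    onset <- pr$cancers[[1]]$tumor_events[[which(kinds == "METASTATIC_RELAPSE")]]$date
    expect_lte(abs(as.numeric(onset - as.Date(gt$diagnosis_date[gt$patient_id == pid]))), 30)
  }
})

test_that("zero-noise onset recovery stays within the window for most patients", {
  cfg <- small_config(n_patients = 50L, metastatic_fraction = 0.5,
                      negation_rate = 0, hypothesis_rate = 0, seed = 5L)
  corp <- generate_corpus(cfg)
  res <- run_pipeline(corp)
  rec <- onset_recovery_rate(corp, res$profiles)
  expect_gt(rec$n, 5L)
  expect_gte(rec$rate, 0.9)
})
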