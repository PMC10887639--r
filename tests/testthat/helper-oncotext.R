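# Shared fixtures and independent oracles, built in code at test time.

small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_patients = 40L, n_centres = 2L, seed = 42L)
  do.call(corpus_config, utils::modifyList(defaults, args))
}

# Reference character-walk normalizer: independently recomputes the
# normalized string and offset map one character at a time.
walk_normalize <- function(text) {
  src <- strsplit(chartr("\u2019\u2018", "''", text), "")[[1]]
  acc_from <- strsplit("\u00e0\u00e1\u00e2\u00e3\u00e4\u00e5\u00e7\u00e8\u00e9\u00ea\u00eb\u00ec\u00ed\u00ee\u00ef\u00f1\u00f2\u00f3\u00f4\u00f5\u00f6\u00f9\u00fa\u00fb\u00fc\u00fd\u00ff", "")[[1]]
  acc_to <- strsplit("aaaaaaceeeeiiiinooooouuuuyy", "")[[1]]
  out <- character(0)
  map <- integer(0)
  run_start <- NA_integer_  # 0-based index of the first whitespace of a run
  for (i in seq_along(src)) {
    ch <- tolower(src[i])
    k <- match(ch, acc_from)
    if (!is.na(k)) ch <- acc_to[k]
    if (ch %in% c(" ", "\t", "\n", "\r", "\u00a0")) {
      if (is.na(run_start)) run_start <- i - 1L
    } else {
      if (!is.na(run_start) && length(out) > 0L) {
        out <- c(out, " ")
        map <- c(map, run_start)
      }
      run_start <- NA_integer_
      out <- c(out, ch)
      map <- c(map, i - 1L)
    }
  }
  list(text = paste(out, collapse = ""), offsets = map)
}

# Random occurrence sets for onset property tests: mixed categories,
# contexts, sources and date origins over a three-year span.
random_occurrences <- function(n, seed) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    data.frame(
      patient_id = "PX",
      category = sample(c("METASTASIS", "RELAPSE", "TUMOR_LOCATION", "TREATMENT"),
                        n, replace = TRUE, prob = c(0.45, 0.25, 0.2, 0.1)),
      code = sample(c(NA, "C78.7", "C79.5", "LOCAL", "DISTANT", "C50.9"),
                    n, replace = TRUE),
      context = sample(c("AFFIRMED", "NEGATED", "HYPOTHETICAL"),
                       n, replace = TRUE, prob = c(0.6, 0.2, 0.2)),
      date = as.Date("2019-01-01") + sample(0:1095, n, replace = TRUE),
      date_origin = sample(c("CONCEPT_LINKED", "DOCUMENT"), n, replace = TRUE),
      source = sample(c("REPORT", "PMSI"), n, replace = TRUE),
      source_id = sprintf("S%03d", seq_len(n)),
      recorded_at = as.Date("2022-06-01"),
      stringsAsFactors = FALSE
    )
  })
}

# Brute-force onset oracle: enumerates every candidate start date and
# recomputes window weights by direct summation, independently of the
# implementation.
oracle_onset <- function(occ, params, primary_site = NULL) {
  is_cand <- logical(nrow(occ))
  for (i in seq_len(nrow(occ))) {
    if (occ$context[i] == "NEGATED") next
    if (occ$category[i] == "METASTASIS") {
      is_cand[i] <- TRUE
    } else if (occ$category[i] == "RELAPSE" && !is.na(occ$code[i])) {
      if (occ$code[i] == "DISTANT") {
        is_cand[i] <- TRUE
      } else if (!is.null(primary_site) && grepl("^[A-Z][0-9]{2}", occ$code[i])) {
        is_cand[i] <- substr(occ$code[i], 1, 3) != substr(primary_site, 1, 3)
      }
    }
  }
  cand <- occ[is_cand, , drop = FALSE]
  if (!nrow(cand)) return(as.Date(NA))
  for (s in sort(unique(as.numeric(cand$date)))) {
    total <- 0
    for (i in seq_len(nrow(cand))) {
      d <- as.numeric(cand$date[i])
      if (d >= s && d < s + params$interval_days) {
        w <- params$source_weight[[cand$source[i]]] *
          params$date_origin_weight[[cand$date_origin[i]]]
        if (cand$context[i] == "HYPOTHETICAL") w <- w * params$hypothetical_weight
        total <- total + w
      }
    }
    if (total > params$threshold) return(as.Date(s, origin = "1970-01-01"))
  }
  as.Date(NA)
}

# Proportion of metastatic patients whose inferred onset falls within
# `tol` days of ground truth.
onset_recovery_rate <- function(corpus, profiles, tol = 180) {
  gt <- corpus$ground_truth
  met <- gt[!is.na(gt$metastatic_onset) & nzchar(gt$metastatic_onset), , drop = FALSE]
  hits <- vapply(seq_len(nrow(met)), function(i) {
    pr <- profiles[[met$patient_id[i]]]
    mo <- NA
    if (!is.null(pr)) {
      for (e in if (length(pr$cancers)) pr$cancers[[1]]$tumor_events else list()) {
        if (e$kind == "METASTATIC_RELAPSE") mo <- e$date
      }
    }
    !is.na(mo) && abs(as.numeric(as.Date(mo, origin = "1970-01-01") -
                                   as.Date(met$metastatic_onset[i]))) <= tol
  }, logical(1))
  list(rate = mean(hits), n = nrow(met))
}

# Gold-agreement scorer: detection completeness/purity on non-DATE spans
# and context accuracy on matched spans.
gold_agreement <- function(corpus, structured) {
  gold_n <- 0L; found <- 0L; extra <- 0L; ctx_n <- 0L; ctx_ok <- 0L
  for (i in seq_along(corpus$documents)) {
    g <- corpus$documents[[i]]$gold
    m <- structured[[i]]$mentions
    m <- m[m$category != "DATE", , drop = FALSE]
    gk <- paste(g$start, g$end, g$category)
    mk <- paste(m$start, m$end, m$category)
    gold_n <- gold_n + nrow(g)
    found <- found + sum(gk %in% mk)
    extra <- extra + sum(!(mk %in% gk))
    mm <- match(gk, mk)
    hit <- which(!is.na(mm))
    ctx_n <- ctx_n + length(hit)
    ctx_ok <- ctx_ok + sum(g$context[hit] == m$context[mm[hit]])
  }
  list(detection_recall = found / gold_n, spurious = extra,
       context_accuracy = ctx_ok / ctx_n, n_gold = gold_n)
}
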