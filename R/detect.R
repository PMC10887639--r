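NEGATION_SINGLE <- c("sans", "aucun", "aucune")
NEGATION_BIGRAM <- c("pas de", "absence de")
HYPOTHESIS_SINGLE <- c("suspicion", "evoque", "possible", "possibles", "probable", "probables")
HYPOTHESIS_BIGRAM <- c("recherche de")
SCOPE_BREAK_REGEX <- "[.,;:!?()]"
CONTEXT_WINDOW_TOKENS <- 5L
DATE_WINDOW_TOKENS <- 10L

empty_mentions <- function() {
  data.frame(
    start = integer(0), end = integer(0), term = character(0),
    category = character(0), code = character(0), context = character(0),
    linked_date = as.Date(character(0)), related_to = integer(0),
    stringsAsFactors = FALSE
  )
}

# TRUE when the normalized-text span [s, e) (1-based s, exclusive e) is not
# glued to an adjacent word character.
span_bounded <- function(norm_text, s, e) {
  before <- if (s > 1L) substr(norm_text, s - 1L, s - 1L) else ""
  after <- if (e <= nchar(norm_text)) substr(norm_text, e, e) else ""
  !grepl("[a-z0-9]", before) && !grepl("[a-z0-9]", after)
}

# Longest-match-first, left-to-right, non-overlapping matching over a
# normalized string. Returns 0-based half-open spans in normalized coords.
match_lexicon <- function(norm_text, lex) {
  out <- list()
  if (!nzchar(norm_text)) {
    return(data.frame(nstart = integer(0), nend = integer(0), entry = integer(0)))
  }
  for (i in seq_len(nrow(lex))) {
    for (v in term_variants(lex$term[i])) {
      m <- gregexpr(v, norm_text, fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      len <- attr(m, "match.length")
      for (j in seq_along(m)) {
        s <- m[j]; e <- m[j] + len[j]
        if (span_bounded(norm_text, s, e)) {
          out[[length(out) + 1L]] <- c(s - 1L, e - 1L, i)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(nstart = integer(0), nend = integer(0), entry = integer(0)))
  }
  m <- do.call(rbind, out)
  df <- data.frame(nstart = m[, 1], nend = m[, 2], entry = m[, 3])
  # same span matched through several entries/variants: keep first entry
  df <- df[order(df$nstart, -(df$nend - df$nstart), df$entry), , drop = FALSE]
  df <- df[!duplicated(df[c("nstart", "nend")]), , drop = FALSE]
  # greedy left-to-right, longest first at equal start
  keep <- logical(nrow(df))
  last_end <- -1L
  for (k in seq_len(nrow(df))) {
    if (df$nstart[k] >= last_end) {
      keep[k] <- TRUE
      last_end <- df$nend[k]
    }
  }
  df[keep, , drop = FALSE]
}

DATE_NUMERIC_REGEX <- "\\b([0-9]{1,2})/([0-9]{1,2})/([0-9]{4})\\b"
DATE_PROSE_REGEX <- paste0(
  "\\b([0-9]{1,2})(?:er)? (", paste(FRENCH_MONTHS, collapse = "|"), ") ([0-9]{4})\\b"
)

parse_date_surface <- function(surface) {
  if (grepl("/", surface, fixed = TRUE)) {
    p <- as.integer(strsplit(surface, "/", fixed = TRUE)[[1]])
    return(make_date(p[3], p[2], p[1]))
  }
  p <- strsplit(surface, " ", fixed = TRUE)[[1]]
  day <- as.integer(sub("er$", "", p[1]))
  month <- match(p[2], FRENCH_MONTHS)
  make_date(as.integer(p[3]), month, day)
}

# Date mentions over normalized text (0-based half-open spans). Surfaces
# that parse to an impossible calendar date are dropped with a message.
detect_date_mentions <- function(norm_text) {
  res <- data.frame(nstart = integer(0), nend = integer(0),
                    surface = character(0), stringsAsFactors = FALSE)
  for (pat in c(DATE_NUMERIC_REGEX, DATE_PROSE_REGEX)) {
    m <- gregexpr(pat, norm_text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    res <- rbind(res, data.frame(
      nstart = as.integer(m) - 1L, nend = as.integer(m) + len - 1L,
      surface = substring(norm_text, m, m + len - 1L), stringsAsFactors = FALSE
    ))
  }
  if (!nrow(res)) {
    res$date <- as.Date(character(0))
    return(res)
  }
  res <- res[order(res$nstart), , drop = FALSE]
  res$date <- as.Date(vapply(res$surface, function(s) as_iso(parse_date_surface(s)), character(1)),
                      format = "%Y-%m-%d")
  bad <- is.na(res$date)
  if (any(bad)) {
    message("dropping unparseable date surface(s): ",
            paste(unique(res$surface[bad]), collapse = ", "))
    res <- res[!bad, , drop = FALSE]
  }
  res
}

# Context of a mention starting at normalized offset nstart0: scan up to
# CONTEXT_WINDOW_TOKENS tokens backwards, nearest first, stopping at a scope
# breaker (punctuation or "mais"). Negation and hypothesis triggers are
# checked as single tokens and as bigrams with the following token.
classify_core <- function(norm_text, toks, nstart0) {
  before <- toks[toks$end <= nstart0, , drop = FALSE]
  n <- nrow(before)
  if (!n) return("AFFIRMED")
  lo <- max(1L, n - CONTEXT_WINDOW_TOKENS + 1L)
  for (i in seq(n, lo)) {
    gap_from <- before$end[i] + 1L
    gap <- if (gap_from <= nstart0) substr(norm_text, gap_from, nstart0) else ""
    if (grepl(SCOPE_BREAK_REGEX, gap)) break
    tok <- before$token[i]
    if (tok == "mais") break
    bigram <- if (i < n) paste(tok, before$token[i + 1L]) else NA_character_
    if (tok %in% NEGATION_SINGLE || (!is.na(bigram) && bigram %in% NEGATION_BIGRAM)) {
      return("NEGATED")
    }
    if (tok %in% HYPOTHESIS_SINGLE || (!is.na(bigram) && bigram %in% HYPOTHESIS_BIGRAM)) {
      return("HYPOTHETICAL")
    }
  }
  "AFFIRMED"
}

sentence_id <- function(norm_text, positions) {
  breaks <- gregexpr("[.!?]", norm_text)[[1]]
  if (breaks[1] == -1L) return(rep(0L, length(positions)))
  breaks0 <- as.integer(breaks) - 1L
  vapply(positions, function(p) sum(breaks0 < p), integer(1))
}

tokens_between <- function(toks, a_end, b_start) {
  sum(toks$start >= a_end & toks$end <= b_start)
}

#' Detect lexicon concept mentions in a document text
#'
#' Matching is longest-match-first, left-to-right and non-overlapping over
#' the normalized text (accent- and case-insensitive, plural suffix
#' variants); spans are reported as 0-based half-open offsets into the
#' original text. Context, dates and relations are left unset; see
#' [process_document()] for the full pipeline.
#'
#' @param text document text.
#' @param lex a [lexicon()].
#' @return a mention data.frame with columns `start`, `end`, `term`,
#'   `category`, `code`, `context`, `linked_date`, `related_to`.
#' @export
detect_mentions <- function(text, lex) {
  if (!nrow(lex)) stop("lexicon is empty")
  nm <- normalize_text(text)
  hits <- match_lexicon(nm$text, lex)
  if (!nrow(hits)) return(empty_mentions())
  data.frame(
    start = nm$offsets[hits$nstart + 1L],
    end = nm$offsets[hits$nend] + 1L,
    term = lex$term[hits$entry],
    category = lex$category[hits$entry],
    code = lex$code[hits$entry],
    context = NA_character_,
    linked_date = as.Date(NA),
    related_to = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Classify the assertion context of a mention
#'
#' A mention is `NEGATED` when a negation trigger ("pas de", "absence de",
#' "sans", "aucun(e)") occurs within a backward window of five tokens with
#' no intervening scope breaker (punctuation or "mais"), `HYPOTHETICAL`
#' likewise for hypothesis triggers ("suspicion", "evoque", "possible",
#' "probable", "recherche de"), otherwise `AFFIRMED`. The nearest trigger
#' wins.
#'
#' @param mention a list or one-row data.frame with `start` and `end`
#'   (0-based half-open offsets into `text`).
#' @param text the document text the mention was detected in.
#' @return one of `"AFFIRMED"`, `"NEGATED"`, `"HYPOTHETICAL"`.
#' @export
classify_context <- function(mention, text) {
  nm <- normalize_text(text)
  nstart <- match(mention$start, nm$offsets) - 1L
  if (is.na(nstart)) stop("mention start offset not found in document text")
  classify_core(nm$text, token_spans(nm$text), nstart)
}

# Link non-DATE mentions to the nearest DATE mention in the same sentence
# within DATE_WINDOW_TOKENS tokens; ties break towards the earlier date
# mention. Operates in normalized coordinates.
attach_dates_core <- function(norm_text, toks, mentions, dates) {
  linked <- rep(as.Date(NA), nrow(mentions))
  if (!nrow(dates) || !nrow(mentions)) return(linked)
  msent <- sentence_id(norm_text, mentions$nstart)
  dsent <- sentence_id(norm_text, dates$nstart)
  for (i in seq_len(nrow(mentions))) {
    cand <- which(dsent == msent[i])
    if (!length(cand)) next
    dist <- vapply(cand, function(j) {
      if (dates$nstart[j] >= mentions$nend[i]) {
        tokens_between(toks, mentions$nend[i], dates$nstart[j])
      } else {
        tokens_between(toks, dates$nend[j], mentions$nstart[i])
      }
    }, integer(1))
    ok <- dist <= DATE_WINDOW_TOKENS
    if (!any(ok)) next
    cand <- cand[ok]; dist <- dist[ok]
    best <- cand[order(dist, dates$nstart[cand])][1]
    linked[i] <- dates$date[best]
  }
  linked
}

#' Link each mention to the nearest date phrase
#'
#' Re-detects date phrases in `document$text` and links every non-DATE
#' mention to the nearest date mention within the same sentence and within
#' ten tokens; when no date qualifies, `linked_date` stays `NA` and the
#' document date is the downstream fallback.
#'
#' @param mentions a mention data.frame (original-text offsets).
#' @param document a list with at least `text`.
#' @return `mentions` with `linked_date` filled in.
#' @export
attach_dates <- function(mentions, document) {
  nm <- normalize_text(document$text)
  toks <- token_spans(nm$text)
  dates <- detect_date_mentions(nm$text)
  if (!nrow(mentions)) return(mentions)
  nstart <- match(mentions$start, nm$offsets) - 1L
  nend <- match(mentions$end - 1L, nm$offsets)
  mn <- data.frame(nstart = nstart, nend = nend)
  mentions$linked_date <- attach_dates_core(nm$text, toks, mn, dates)
  mentions
}

# response -> nearest preceding TREATMENT in the same sentence (nearest
# following as fallback); metastasis -> nearest TUMOR_LOCATION in the same
# sentence. Returns an integer row index per mention or NA.
link_relations <- function(norm_text, mentions_n, categories) {
  related <- rep(NA_integer_, nrow(mentions_n))
  if (!nrow(mentions_n)) return(related)
  sent <- sentence_id(norm_text, mentions_n$nstart)
  for (i in seq_len(nrow(mentions_n))) {
    target_cat <- switch(categories[i],
      TREATMENT_RESPONSE = "TREATMENT",
      METASTASIS = "TUMOR_LOCATION",
      NULL
    )
    if (is.null(target_cat)) next
    cand <- which(categories == target_cat & sent == sent[i])
    if (!length(cand)) next
    prev <- cand[mentions_n$nstart[cand] < mentions_n$nstart[i]]
    if (length(prev)) {
      related[i] <- prev[which.max(mentions_n$nstart[prev])]
    } else {
      nxt <- cand[mentions_n$nstart[cand] > mentions_n$nstart[i]]
      if (length(nxt)) related[i] <- nxt[which.min(mentions_n$nstart[nxt])]
    }
  }
  related
}

#' Run the full concept pipeline on one report
#'
#' Composes identifier redaction, normalization, lexicon and date mention
#' detection, context classification, date linking and relation linking.
#' Mention spans are reported in the coordinates of the original raw text
#' (the redaction and normalization offset maps are composed), so spans can
#' be compared directly against gold annotations.
#'
#' @param doc a list with fields `doc_id`, `patient_id`, `doc_date`, `text`
#'   (`doc_type` optional).
#' @param lex a [lexicon()].
#' @return a `structured_document`: list with `doc_id`, `patient_id`,
#'   `doc_date`, `mentions` (data.frame), `redacted_text`.
#' @export
process_document <- function(doc, lex) {
  for (f in c("doc_id", "patient_id", "doc_date", "text")) {
    if (is.null(doc[[f]]) || is.na(doc[[f]][1])) {
      stop("document record is missing field: ", f)
    }
  }
  doc_date <- as.Date(doc$doc_date)
  rd <- redact_with_map(doc$text)
  nm <- normalize_text(rd$text)
  # compose: normalized offset -> redacted offset -> original offset
  orig_of <- if (length(nm$offsets)) rd$offsets[nm$offsets + 1L] else integer(0)

  hits <- match_lexicon(nm$text, lex)
  dates <- detect_date_mentions(nm$text)
  toks <- token_spans(nm$text)

  n_lex <- nrow(hits); n_date <- nrow(dates)
  if (n_lex + n_date == 0L) {
    return(structure(
      list(doc_id = doc$doc_id, patient_id = doc$patient_id,
           doc_date = doc_date, mentions = empty_mentions(),
           redacted_text = rd$text),
      class = "structured_document"
    ))
  }
  mn <- data.frame(
    nstart = c(hits$nstart, dates$nstart),
    nend = c(hits$nend, dates$nend)
  )
  term <- c(if (n_lex) lex$term[hits$entry], if (n_date) dates$surface)
  category <- c(if (n_lex) lex$category[hits$entry], rep("DATE", n_date))
  code <- c(if (n_lex) lex$code[hits$entry], rep(NA_character_, n_date))

  ord <- order(mn$nstart)
  mn <- mn[ord, , drop = FALSE]
  term <- term[ord]; category <- category[ord]; code <- code[ord]

  context <- vapply(seq_len(nrow(mn)), function(i) {
    if (category[i] == "DATE") "AFFIRMED" else classify_core(nm$text, toks, mn$nstart[i])
  }, character(1))

  linked <- attach_dates_core(nm$text, toks, mn, dates)
  is_date <- category == "DATE"
  if (any(is_date)) {
    linked[is_date] <- dates$date[match(mn$nstart[is_date], dates$nstart)]
  }
  related <- link_relations(nm$text, mn, category)

  mentions <- data.frame(
    start = orig_of[mn$nstart + 1L],
    end = orig_of[mn$nend] + 1L,
    term = term, category = category, code = code, context = context,
    linked_date = linked, related_to = related,
    stringsAsFactors = FALSE
  )
  rownames(mentions) <- NULL
  structure(
    list(doc_id = doc$doc_id, patient_id = doc$patient_id,
         doc_date = doc_date, mentions = mentions, redacted_text = rd$text),
    class = "structured_document"
  )
}

#' Process every document of a corpus
#'
#' @param docs list of raw document records (as produced by
#'   [generate_corpus()] or read from `documents.jsonl`).
#' @param lex a [lexicon()].
#' @return list of `structured_document`s.
#' @export
process_corpus <- function(docs, lex) {
  lapply(docs, process_document, lex = lex)
}
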