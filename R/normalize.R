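strip_accents <- function(x) chartr(ACCENT_FROM, ACCENT_TO, tolower(chartr("’‘", "''", x)))

#' Normalize clinical text for matching
#'
#' Lowercases, strips French accents, unifies typographic apostrophes and
#' collapses whitespace runs to a single space. The returned offset map lets
#' every position in the normalized string be traced back to the original
#' text, so concept spans are always reported in original coordinates.
#' Stopword handling and the plural/feminine suffix table are applied inside
#' lexicon matching only; this function never mutates content characters.
#'
#' @param text a single character string.
#' @return a list with `text` (normalized string) and `offsets`, an integer
#'   vector with one entry per normalized character giving the 0-based offset
#'   of the original character it came from.
#' @examples
#' normalize_text("Primitif  Inconnu")
#' @export
normalize_text <- function(text) {
  if (length(text) != 1L || !is.character(text)) stop("text must be a single string")
  if (is.na(text) || !nzchar(text)) {
    return(list(text = "", offsets = integer(0)))
  }
  x <- strip_accents(text)  # 1:1 character mapping, length preserved
  chars <- strsplit(x, "", fixed = FALSE)[[1]]
  ws <- chars %in% c(" ", "\t", "\n", "\r", "\u00a0")
  chars[ws] <- " "
  # keep a whitespace char only when the previous character is not whitespace
  prev_ws <- c(TRUE, ws[-length(ws)])
  keep <- !(ws & prev_ws)
  # drop a trailing space
  kept_idx <- which(keep)
  if (length(kept_idx) && ws[kept_idx[length(kept_idx)]]) {
    keep[kept_idx[length(kept_idx)]] <- FALSE
    kept_idx <- kept_idx[-length(kept_idx)]
  }
  list(
    text = paste(chars[keep], collapse = ""),
    offsets = kept_idx - 1L
  )
}

REDACTION_PATTERNS <- list(
  EMAIL = "[A-Za-z0-9._%-]+@[A-Za-z0-9.-]+\\.[A-Za-z]{2,}",
  NAME  = "\\b(M\\.|Mme|Mlle|Dr|Pr)[ \t]+[A-ZÀ-Þ][A-Za-zÀ-ÿ-]+",
  ID    = "[0-9]{6,}"
)

# Redact and keep, for every character of the redacted text, the 0-based
# offset of the original character it stands for (placeholder characters all
# map to the start of the replaced region).
redact_with_map <- function(text) {
  if (is.na(text) || !nzchar(text)) return(list(text = text %||% "", offsets = integer(0)))
  spans <- list()
  for (tag in names(REDACTION_PATTERNS)) {
    m <- gregexpr(REDACTION_PATTERNS[[tag]], text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    for (j in seq_along(m)) {
      spans[[length(spans) + 1L]] <- list(start = m[j], end = m[j] + len[j] - 1L, tag = tag)
    }
  }
  if (!length(spans)) {
    return(list(text = text, offsets = seq_len(nchar(text)) - 1L))
  }
  ord <- order(vapply(spans, `[[`, 0L, "start"))
  spans <- spans[ord]
  # drop spans overlapping an earlier (higher-priority, leftmost-first) one
  kept <- list(); last_end <- 0L
  for (s in spans) {
    if (s$start > last_end) {
      kept[[length(kept) + 1L]] <- s
      last_end <- s$end
    }
  }
  out_chars <- character(0)
  out_off <- integer(0)
  cursor <- 1L
  orig_chars <- strsplit(text, "")[[1]]
  for (s in kept) {
    if (s$start > cursor) {
      seg <- cursor:(s$start - 1L)
      out_chars <- c(out_chars, orig_chars[seg])
      out_off <- c(out_off, seg - 1L)
    }
    ph <- paste0("<", s$tag, ">")
    out_chars <- c(out_chars, strsplit(ph, "")[[1]])
    out_off <- c(out_off, rep.int(s$start - 1L, nchar(ph)))
    cursor <- s$end + 1L
  }
  if (cursor <= length(orig_chars)) {
    seg <- cursor:length(orig_chars)
    out_chars <- c(out_chars, orig_chars[seg])
    out_off <- c(out_off, seg - 1L)
  }
  list(text = paste(out_chars, collapse = ""), offsets = out_off)
}

#' Replace identifying tokens with typed placeholders
#'
#' Person-name patterns following a French honorific (`M.`, `Mme`, `Dr`, ...)
#' become `<NAME>`, email-like tokens become `<EMAIL>` and digit runs of six
#' or more become `<ID>`. The operation is idempotent: placeholders contain
#' none of the triggering patterns.
#'
#' @param text a single character string.
#' @return the redacted string.
#' @examples
#' redact_identifiers("N° dossier 1234567, vu par Dr Martin")
#' @export
redact_identifiers <- function(text) {
  if (length(text) != 1L || !is.character(text)) stop("text must be a single string")
  redact_with_map(text)$text
}

# Token spans over normalized text; tokens are maximal [a-z0-9'] runs.
# Returns a data.frame with 0-based half-open spans and the token string.
token_spans <- function(norm_text) {
  if (!nzchar(norm_text)) {
    return(data.frame(start = integer(0), end = integer(0), token = character(0)))
  }
  m <- gregexpr("[a-z0-9']+", norm_text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0), token = character(0)))
  }
  len <- attr(m, "match.length")
  data.frame(
    start = as.integer(m) - 1L,
    end = as.integer(m) + len - 1L,
    token = substring(norm_text, m, m + len - 1L),
    stringsAsFactors = FALSE
  )
}
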