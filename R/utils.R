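`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded draws inside the package
#' never disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Mix a base seed with stream identifiers into a 31-bit sub-seed, so each
# patient/stage pair gets an independent, reproducible stream.
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), vapply(list(...), as.numeric, 0))
  h <- 0
  for (p in parts) h <- (h * 69069 + p + 1) %% 2147483629
  as.integer(h)
}

#' Format a date as a French prose or numeric phrase
#'
#' @param date a `Date`.
#' @param style `"prose"` for "24 mai 2022", `"numeric"` for "24/05/2022".
#' @return character scalar. Month names are rendered without relying on the
#'   session locale, so output is byte-stable across systems.
#' @keywords internal
format_date_fr <- function(date, style = c("prose", "numeric")) {
  style <- match.arg(style)
  lt <- as.POSIXlt(date)
  if (style == "numeric") {
    sprintf("%02d/%02d/%04d", lt$mday, lt$mon + 1L, lt$year + 1900L)
  } else {
    sprintf("%d %s %d", lt$mday, FRENCH_MONTHS_ACCENTED[lt$mon + 1L], lt$year + 1900L)
  }
}

# Parse a day/month/year triple defensively; returns NA for impossible dates
# (e.g. 31/02/2020) rather than rolling over.
make_date <- function(year, month, day) {
  d <- as.Date(sprintf("%04d-%02d-%02d", year, month, day), format = "%Y-%m-%d")
  if (length(d) && !is.na(d)) {
    lt <- as.POSIXlt(d)
    if (lt$mday != day || lt$mon + 1L != month) d <- as.Date(NA)
  }
  d
}

as_iso <- function(date) {
  ifelse(is.na(date), NA_character_, format(date, "%Y-%m-%d"))
}

#' Write records as JSON Lines
#'
#' One JSON object per line, field order as given, `Date` fields must be
#' pre-converted to ISO strings by the caller. Used for all corpus and
#' pipeline artifacts so outputs are byte-stable under a fixed seed.
#'
#' @param records list of named lists.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_jsonl <- function(records, path) {
  lines <- vapply(
    records,
    function(r) as.character(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null", digits = NA)),
    character(1)
  )
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON Lines file
#'
#' @param path file path.
#' @return list of records (named lists).
#' @export
read_jsonl <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
}

stop_config <- function(...) stop("configuration error: ", ..., call. = FALSE)
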