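check_counts <- function(tp, fp = 0, fn = 0) {
  v <- c(tp, fp, fn)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
    stop("confusion counts must be non-negative integers")
  }
}

#' Recall (sensitivity)
#'
#' True positives over true positives plus false negatives.
#'
#' @param tp,fn non-negative integer counts.
#' @return fraction in `[0, 1]`.
#' @export
recall <- function(tp, fn) {
  check_counts(tp, fn = fn)
  if (tp + fn == 0) stop("recall undefined: tp + fn = 0")
  tp / (tp + fn)
}

#' Precision (positive predictive value)
#'
#' True positives over true positives plus false positives.
#'
#' @param tp,fp non-negative integer counts.
#' @return fraction in `[0, 1]`.
#' @export
precision <- function(tp, fp) {
  check_counts(tp, fp = fp)
  if (tp + fp == 0) stop("precision undefined: tp + fp = 0")
  tp / (tp + fp)
}

#' F1 score
#'
#' Harmonic mean of recall and precision:
#' `2 * recall * precision / (recall + precision)`.
#'
#' @param recall,precision fractions in `[0, 1]`.
#' @return fraction in `[0, 1]`.
#' @export
f1_score <- function(recall, precision) {
  if (any(c(recall, precision) < 0) || any(c(recall, precision) > 1)) {
    stop("recall and precision must lie in [0, 1]")
  }
  if (recall + precision == 0) stop("F1 undefined: recall + precision = 0")
  2 * recall * precision / (recall + precision)
}

F1_BANDS <- c("POOR", "ACCEPTABLE", "EXCELLENT", "OUTSTANDING")

#' Qualitative interpretation band of an F1 score
#'
#' Below 0.6 is poor, `[0.6, 0.8)` acceptable, `[0.8, 0.9)` excellent and
#' 0.9 or more outstanding.
#'
#' @param f1 a fraction in `[0, 1]`.
#' @return one of `"POOR"`, `"ACCEPTABLE"`, `"EXCELLENT"`, `"OUTSTANDING"`.
#' @export
interpret_f1 <- function(f1) {
  if (is.na(f1) || f1 < 0 || f1 > 1) stop("f1 must lie in [0, 1]")
  if (f1 < 0.6) "POOR" else if (f1 < 0.8) "ACCEPTABLE" else if (f1 < 0.9) "EXCELLENT" else "OUTSTANDING"
}

#' Round a fraction to integer percent
#'
#' Half away from zero, matching how retrieval percentages are usually
#' printed (0.9931 -> 99, 0.5702 -> 57).
#'
#' @param x fraction in `[0, 1]`.
#' @return integer percent.
#' @export
as_percent <- function(x) {
  as.integer(floor(100 * x + 0.5))
}

#' Evaluate a retrieved cohort against a reference list
#'
#' Recall is computed against the reference list (`fn` = reference patients
#' the query missed). Precision cannot use the full retrieved set — true
#' negatives are not enumerable over a whole record system — so it is
#' computed on a manually reviewed sample of retrieved patients when one is
#' supplied. Inputs have set semantics: duplicate ids are ignored.
#'
#' @param predicted character vector of retrieved patient ids.
#' @param reference character vector of reference (known-positive) ids;
#'   must be non-empty.
#' @param reviewed optional named logical vector: names are reviewed
#'   patient ids (all of which must have been retrieved), values whether
#'   review confirmed the diagnosis.
#' @return list with `counts` (`tp`, `fp`, `fn`, `tn = NA`), `recall`,
#'   `precision`, `f1`, `band`, and the rounded `recall_pct`,
#'   `precision_pct` used for reporting.
#' @export
evaluate_cohort <- function(predicted, reference, reviewed = NULL) {
  predicted <- unique(as.character(predicted))
  reference <- unique(as.character(reference))
  if (!length(reference)) stop("reference list must be non-empty")
  tp <- length(intersect(reference, predicted))
  fn <- length(setdiff(reference, predicted))
  r <- recall(tp, fn)
  p <- NA_real_
  fp <- NA_integer_
  if (!is.null(reviewed)) {
    if (is.null(names(reviewed)) || any(!nzchar(names(reviewed)))) {
      stop("reviewed must be a named logical vector")
    }
    stray <- setdiff(names(reviewed), predicted)
    if (length(stray)) {
      stop("reviewed ids not among predicted: ", paste(stray, collapse = ", "))
    }
    reviewed <- reviewed[!duplicated(names(reviewed))]
    tp_rev <- sum(reviewed)
    fp <- as.integer(sum(!reviewed))
    p <- precision(tp_rev, fp)
  }
  f1 <- if (!is.na(p)) f1_score(r, p) else NA_real_
  list(
    counts = list(tp = tp, fp = fp, fn = fn, tn = NA_integer_),
    recall = r,
    precision = p,
    f1 = f1,
    band = if (!is.na(f1)) interpret_f1(round(f1, 2)) else NA_character_,
    recall_pct = as_percent(r),
    precision_pct = if (!is.na(p)) as_percent(p) else NA_integer_
  )
}
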