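# Concordance of tool / structural predictions with clinical
# assessment, and cohort-level summary rates.

#' Three-tool agreement for one prediction record
#'
#' @param ddig_in,sift_indel,provean Tool calls, `"D"`
#'   (disease-associated / damaging / deleterious) or `"N"` (neutral).
#' @return `TRUE` when all three calls agree, `FALSE` when they
#'   differ, `NA` when any call is missing.
#' @export
compute_agreement <- function(ddig_in, sift_indel, provean) {
  calls <- c(ddig_in, sift_indel, provean)
  if (anyNA(calls) || any(!nzchar(calls))) return(NA)
  stopifnot(all(calls %in% c("D", "N")))
  length(unique(calls)) == 1L
}

binarize <- list(
  tool = function(x) ifelse(x == "D", TRUE, ifelse(x == "N", FALSE, NA)),
  structural = function(x) ifelse(x %in% c("probably", "unclear"), TRUE,
                                  ifelse(x == "unlikely", FALSE, NA)),
  clinical = function(x) ifelse(x == "probably", TRUE,
                                ifelse(x == "unlikely", FALSE, NA))
)

#' Evaluate predictors against the clinical assessment
#'
#' Takes the clinical report as the reference standard. Records whose
#' clinical call is `"possibly"` are excluded throughout; tool calls
#' map `D` to positive and `N` to negative; the structural verdict maps
#' `probably` and `unclear` to positive and `unlikely` to negative
#' (an inconclusive structural call is treated damaging-side, the same
#' reading the tools' `D` receives), with `unassessable` records
#' excluded for the structural predictor only.
#'
#' @param records Data frame with columns `variant_id`, `ddig_in`,
#'   `sift_indel`, `provean` (each `D`/`N`), `structural`
#'   (`probably`/`unclear`/`unlikely`/`unassessable`) and `clinical`
#'   (`probably`/`possibly`/`unlikely`).
#' @return Data frame with one row per predictor: `n_evaluated`, `TP`,
#'   `FP`, `TN`, `FN`, `accuracy`, `sensitivity`, `specificity`
#'   (metrics rounded to 2 decimals; `NA` when a denominator is zero).
#' @export
evaluate_against_clinical <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("ddig_in", "sift_indel", "provean", "structural", "clinical")
  stopifnot(all(needed %in% names(records)))
  keep <- records$clinical != "possibly"
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) stop("no evaluable records after exclusions")
  truth <- binarize$clinical(records$clinical)
  predictors <- list(
    ddig_in = binarize$tool(records$ddig_in),
    sift_indel = binarize$tool(records$sift_indel),
    provean = binarize$tool(records$provean),
    structural = binarize$structural(records$structural))
  out <- lapply(names(predictors), function(p) {
    pred <- predictors[[p]]
    ok <- !is.na(pred) & !is.na(truth)
    tp <- sum(pred[ok] & truth[ok])
    fp <- sum(pred[ok] & !truth[ok])
    tn <- sum(!pred[ok] & !truth[ok])
    fn <- sum(!pred[ok] & truth[ok])
    n <- sum(ok)
    if (n == 0L) stop("no evaluable records for predictor ", p)
    data.frame(predictor = p, n_evaluated = n,
               TP = tp, FP = fp, TN = tn, FN = fn,
               accuracy = round_metric((tp + tn) / n),
               sensitivity = if (tp + fn > 0)
                 round_metric(tp / (tp + fn)) else NA_real_,
               specificity = if (tn + fp > 0)
                 round_metric(tn / (tn + fp)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cohort summary rates
#'
#' @param counts Data frame (or single-row list) with columns
#'   `probands_tested`, `probands_with_indel`, `indels_detected`,
#'   `indels_clinically_reported`, `indels_modelable`,
#'   `tool_agreement_count` (all non-negative; subset counts must not
#'   exceed their totals).
#' @return Data frame with, per input row: `carrier_rate_pct`
#'   (probands with an indel per probands tested, percent to 1
#'   decimal), `reported_per_tested` (probands tested per clinically
#'   reported indel, rounded to the nearest integer -- the "1 in N"
#'   figure), `modelable_pct` and `agreement_pct` (percent of detected
#'   indels). Zero denominators give `NA` with a warning.
#' @export
summarize_cohort <- function(counts) {
  counts <- as.data.frame(counts)
  need <- c("probands_tested", "probands_with_indel", "indels_detected",
            "indels_clinically_reported", "indels_modelable",
            "tool_agreement_count")
  stopifnot(all(need %in% names(counts)))
  if (any(counts[need] < 0)) stop("counts must be non-negative")
  if (any(counts$probands_with_indel > counts$probands_tested) ||
      any(counts$indels_modelable > counts$indels_detected) ||
      any(counts$tool_agreement_count > counts$indels_detected)) {
    stop("subset counts exceed their totals")
  }
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) warning("zero denominator for ", what, "; reporting NA")
    ifelse(bad, NA_real_, num / den)
  }
  data.frame(
    group = counts$group %||% rep(NA_character_, nrow(counts)),
    carrier_rate_pct = round_percent(
      100 * safe_div(counts$probands_with_indel, counts$probands_tested,
                     "carrier rate")),
    reported_per_tested = round(
      safe_div(counts$probands_tested, counts$indels_clinically_reported,
               "reported-per-tested")),
    modelable_pct = round_percent(
      100 * safe_div(counts$indels_modelable, counts$indels_detected,
                     "modelable fraction")),
    agreement_pct = round_percent(
      100 * safe_div(counts$tool_agreement_count, counts$indels_detected,
                     "tool agreement")),
    stringsAsFactors = FALSE)
}
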