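#' Read a clinical outcomes table
#'
#' CSV with columns `patient`, `pdo`, `drug`, `best_response`; best response
#' is the RECIST-style best outcome on the drug the patient actually
#' received: `PR` (partial response), `SD` (stable disease) or `PD`
#' (disease progression). When a patient received a multi-drug regimen
#' containing one panel drug, the record names the panel drug.
#'
#' @param path CSV file path.
#' @return A validated data frame of clinical records.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("patient", "pdo", "drug", "best_response")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("clinical table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, required]
  df$best_response <- toupper(trimws(df$best_response))
  bad <- which(!df$best_response %in% c("PR", "SD", "PD"))
  if (length(bad) > 0) {
    stop("row ", bad[1], ": best_response must be PR, SD or PD, got ",
         sQuote(df$best_response[bad[1]]))
  }
  df
}

#' Pair PDO hit calls with clinical responses
#'
#' For each clinical record, the PDO is called *sensitive* when its final
#' score for the drug the patient received strictly exceeds the hit
#' threshold, and the patient is called a *responder* under the clinical
#' benefit definition: best response of partial response or stable disease
#' (`responder_def = "benefit"`, default), versus disease progression.
#' `responder_def = "strict"` counts only PR as response. Records whose
#' PDO x drug score is missing are skipped with a warning.
#'
#' @param scores A `score_matrix` or [chemogram()] fit.
#' @param records Clinical records ([read_clinical_table()]).
#' @param threshold Hit threshold; defaults to the matrix's own.
#' @param responder_def `"benefit"` (PR or SD) or `"strict"` (PR only).
#' @return A data frame of classified pairs: `patient`, `pdo`, `drug`,
#'   `final_score`, `pdo_call` (`sensitive`/`non_sensitive`),
#'   `clinical_call` (`responder`/`non_responder`), `concordant`.
#' @export
classify_pairs <- function(scores, records, threshold = NULL,
                           responder_def = c("benefit", "strict")) {
  responder_def <- match.arg(responder_def)
  sm <- if (inherits(scores, "chemogram")) scores$scores else scores
  if (is.null(threshold)) threshold <- sm$threshold
  drug_idx <- match(tolower(trimws(records$drug)), tolower(sm$drugs))
  pdo_idx <- match(records$pdo, sm$pdo_ids)
  fs <- rep(NA_real_, nrow(records))
  ok <- !is.na(drug_idx) & !is.na(pdo_idx)
  fs[ok] <- sm$final_score[cbind(pdo_idx[ok], drug_idx[ok])]
  if (anyNA(fs)) {
    skipped <- records[is.na(fs), , drop = FALSE]
    warning(nrow(skipped), " record(s) without a present PDO x drug score ",
            "skipped: ", paste(paste(skipped$pdo, skipped$drug, sep = "/"),
                               collapse = ", "))
  }
  keep <- !is.na(fs)
  records <- records[keep, , drop = FALSE]
  fs <- fs[keep]
  responder_set <- if (responder_def == "benefit") c("PR", "SD") else "PR"
  out <- data.frame(
    patient = records$patient, pdo = records$pdo,
    drug = sm$drugs[drug_idx[keep]], final_score = fs,
    pdo_call = ifelse(fs > threshold, "sensitive", "non_sensitive"),
    clinical_call = ifelse(records$best_response %in% responder_set,
                           "responder", "non_responder"),
    stringsAsFactors = FALSE)
  out$concordant <- (out$pdo_call == "sensitive") ==
    (out$clinical_call == "responder")
  rownames(out) <- NULL
  out
}

#' Diagnostic concordance of PDO calls against clinical response
#'
#' Tabulates the classified pairs into the 2x2 table (sensitive/responder =
#' true positive; non-sensitive/responder = false negative;
#' sensitive/non-responder = false positive; non-sensitive/non-responder =
#' true negative) and computes sensitivity, specificity, positive and
#' negative predictive values as percentages. A metric with a zero
#' denominator is NA and flagged undefined, never silently 0.
#'
#' @param pairs Output of [classify_pairs()], or a data frame with
#'   `pdo_call` and `clinical_call` columns.
#' @return A `concordance_result`: counts `tp`, `fn`, `fp`, `tn`,
#'   `n_concordant`, metrics `sensitivity`, `specificity`, `ppv`, `npv`
#'   (percent, NA when undefined) and the logical vector `defined`.
#' @examples
#' pairs <- data.frame(
#'   pdo_call = rep(c("sensitive", "non_sensitive"), each = 4),
#'   clinical_call = c("responder", "responder", "responder", "non_responder",
#'                     "responder", "non_responder", "non_responder",
#'                     "non_responder"))
#' concordance(pairs)  # 3/1/1/3: all four metrics 75%
#' @export
concordance <- function(pairs) {
  if (nrow(pairs) == 0) stop("no classified pairs")
  s <- pairs$pdo_call == "sensitive"
  r <- pairs$clinical_call == "responder"
  concordance_from_counts(tp = sum(s & r), fn = sum(!s & r),
                          fp = sum(s & !r), tn = sum(!s & !r))
}

#' @rdname concordance
#' @param tp,fn,fp,tn Non-negative cell counts of the 2x2 table.
#' @export
concordance_from_counts <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  metrics <- c(sensitivity = pct(tp, tp + fn),
               specificity = pct(tn, tn + fp),
               ppv = pct(tp, tp + fp),
               npv = pct(tn, tn + fn))
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 n = sum(counts), n_concordant = tp + tn,
                 sensitivity = metrics[["sensitivity"]],
                 specificity = metrics[["specificity"]],
                 ppv = metrics[["ppv"]], npv = metrics[["npv"]],
                 defined = !is.na(metrics)),
            class = "concordance_result")
}

#' Packaged worked example of matched PDO-patient pairs
#'
#' A small synthetic cohort of 8 PDOs with final scores for the drug their
#' matched patient received, and the patients' best clinical responses.
#' The data are constructed (not measured) to exercise the full
#' classification path: with the default threshold (1.9) and the clinical
#' benefit responder definition they yield the 2x2 table
#' (tp = 3, fn = 1, fp = 1, tn = 3) — 6 of 8 pairs concordant and all four
#' predictive metrics at 75%.
#'
#' @return A list with `scores` (a `score_matrix`) and `clinical` (a record
#'   data frame).
#' @examples
#' ex <- matched_example()
#' concordance(classify_pairs(ex$scores, ex$clinical, threshold = 1.9))
#' @export
matched_example <- function() {
  list(scores = read_score_matrix(
         system.file("extdata", "synthetic_matched_scores.csv",
                     package = "chemogram", mustWork = TRUE)),
       clinical = read_clinical_table(
         system.file("extdata", "synthetic_matched_clinical.csv",
                     package = "chemogram", mustWork = TRUE)))
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("PDO-vs-clinical concordance (", x$n, " matched pairs, ",
      x$n_concordant, " concordant)\n", sep = "")
  cat("                 Responder  Non-responder\n")
  cat(sprintf("  Sensitive      %9d  %13d\n", x$tp, x$fp))
  cat(sprintf("  Non-sensitive  %9d  %13d\n", x$fn, x$tn))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", v)
  cat("  sensitivity ", fmt(x$sensitivity), ", specificity ",
      fmt(x$specificity), ", PPV ", fmt(x$ppv), ", NPV ", fmt(x$npv),
      "\n", sep = "")
  invisible(x)
}
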