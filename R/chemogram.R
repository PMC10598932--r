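#' Fit a chemogram: score a PDO drug screen end to end
#'
#' The chemogram is the per-patient drug-test readout of an ex vivo screen:
#' a panel of final sensitivity scores, one per drug, with hits flagged.
#' `chemogram()` runs the whole pipeline on a raw well table:
#'
#' 1. triplicate wells are collapsed and normalized to the solvent controls
#'    in scope ([summarize_screen()]);
#' 2. conditions whose relative-viability standard error exceeds the QC
#'    threshold are excluded ([apply_qc()]);
#' 3. complete dose-response profiles are assembled ([build_profiles()]);
#' 4. every available PDO x drug pair is scored against the cohort-average
#'    curve and hits are called ([score_cohort()]).
#'
#' The final score of a pair is `auc_score + sensitivity_score`: the
#' cohort-relative AUC ratio (how much more responsive than the collection)
#' plus the absolute fraction of viability lost across the three tested
#' concentrations. A drug is a hit when the final score strictly exceeds the
#' threshold (default 1.9).
#'
#' @param wells A validated well data frame ([read_well_table()]) or a path
#'   to a wells CSV.
#' @param panel A [drug panel][as_drug_panel]; defaults to the packaged
#'   25-drug library.
#' @param qc A [qc_config()].
#' @param scoring A [scoring_config()].
#' @param leave_one_out Exclude each PDO from its own cohort reference; see
#'   [score_cohort()].
#' @return An object of class `chemogram`: a list with `summaries`,
#'   `excluded`, `profiles`, `reference`, `scores` (a `score_matrix`),
#'   `threshold`, and the configs used.
#' @examples
#' cfg <- sim_config(n_pdos = 4, seed = 7,
#'                   panel = default_panel()[1:3, ])
#' scr <- simulate_screen(cfg)
#' fit <- chemogram(scr$wells)
#' fit
#' coef(fit)[, 1:3]
#' @export
chemogram <- function(wells, panel = default_panel(), qc = qc_config(),
                      scoring = scoring_config(), leave_one_out = FALSE) {
  if (is.character(wells) && length(wells) == 1) {
    wells <- read_well_table(wells)
  }
  summaries <- summarize_screen(wells, qc)
  parts <- apply_qc(summaries, qc)
  profiles <- build_profiles(parts$retained, panel)
  scores <- score_cohort(profiles, panel, scoring,
                         leave_one_out = leave_one_out)
  structure(list(summaries = summaries,
                 excluded = parts$excluded,
                 profiles = profiles,
                 reference = suppressWarnings(cohort_reference(profiles)),
                 scores = scores,
                 threshold = scores$threshold,
                 panel = panel, qc = qc, scoring = scoring),
            class = "chemogram")
}

#' @export
print.chemogram <- function(x, ...) {
  sm <- x$scores
  cat("Chemogram fit\n")
  cat("  PDOs: ", length(sm$pdo_ids), "; drugs: ", length(sm$drugs),
      "\n", sep = "")
  cat("  conditions excluded by QC (SE > ", format(x$qc$se_threshold),
      " points): ", nrow(x$excluded), "\n", sep = "")
  cat("  scored pairs: ", sum(!is.na(sm$final_score)), "; hits: ",
      sum(sm$hit, na.rm = TRUE), " (final score > ", format(x$threshold),
      ")\n", sep = "")
  invisible(x)
}

#' @export
summary.chemogram <- function(object, ...) {
  sm <- object$scores
  fs <- sm$final_score[!is.na(sm$final_score)]
  structure(list(
    n_pdos = length(sm$pdo_ids),
    n_drugs = length(sm$drugs),
    n_excluded = nrow(object$excluded),
    n_scored = length(fs),
    n_missing = sum(is.na(sm$final_score)),
    threshold = object$threshold,
    score_quartiles = stats::quantile(fs, c(0.25, 0.5, 0.75), type = 7),
    hits_per_pdo = hits_per_pdo(sm),
    heterogeneity = suppressWarnings(heterogeneity_score(sm))),
    class = "summary.chemogram")
}

#' @export
print.summary.chemogram <- function(x, ...) {
  cat("Chemogram summary: ", x$n_pdos, " PDOs x ", x$n_drugs, " drugs\n",
      sep = "")
  cat("  scored pairs: ", x$n_scored, " (", x$n_missing, " missing); ",
      x$n_excluded, " condition(s) excluded by QC\n", sep = "")
  q <- x$score_quartiles
  cat(sprintf("  final score quartiles: Q1 %.3f, median %.3f, Q3 %.3f\n",
              q[1], q[2], q[3]))
  h <- x$hits_per_pdo
  cat(sprintf("  hits per PDO (threshold %s): mean %.2f, range %d-%d; %d%% of PDOs with >= 1 hit\n",
              format(x$threshold), mean(h), min(h), max(h),
              round(100 * mean(h >= 1))))
  invisible(x)
}

#' Extract score matrices from a chemogram fit
#'
#' @param object A [chemogram()] fit.
#' @param type Which component matrix to return.
#' @param ... Unused.
#' @return A PDO x drug numeric matrix (logical for `"hit"`).
#' @export
coef.chemogram <- function(object,
                           type = c("final", "auc", "sensitivity", "hit"),
                           ...) {
  type <- match.arg(type)
  switch(type,
         final = object$scores$final_score,
         auc = object$scores$auc_score,
         sensitivity = object$scores$sensitivity_score,
         hit = object$scores$hit)
}

#' Score new PDOs against a fitted cohort reference
#'
#' Scores prospective profiles (or a new raw well table) against the frozen
#' cohort reference of an existing fit, without re-deriving the reference or
#' the threshold. This is the intended deployment mode: the cohort defines
#' the average response, a new patient's PDO is scored against it.
#'
#' @param object A [chemogram()] fit.
#' @param newdata A well data frame / CSV path, or a profile data frame with
#'   columns `pdo`, `drug`, `v_low`, `v_medium`, `v_high`, `available`.
#' @param ... Unused.
#' @return A long data frame: `pdo`, `drug`, `auc_score`,
#'   `sensitivity_score`, `final_score`, `hit` (NA scores where the drug has
#'   no reference or the profile is unavailable).
#' @export
predict.chemogram <- function(object, newdata, ...) {
  if (is.character(newdata) && length(newdata) == 1) {
    newdata <- read_well_table(newdata)
  }
  if (!all(c("v_low", "v_medium", "v_high") %in% names(newdata))) {
    summaries <- summarize_screen(newdata, object$qc)
    newdata <- build_profiles(apply_qc(summaries, object$qc)$retained,
                              object$panel)
  }
  ref <- object$reference
  cfg <- object$scoring
  out <- newdata[, c("pdo", "drug")]
  out$auc_score <- out$sensitivity_score <- out$final_score <- NA_real_
  for (i in seq_len(nrow(newdata))) {
    if (!newdata$available[i]) next
    j <- match(newdata$drug[i], ref$drug)
    if (is.na(j)) {
      warning("no cohort reference for drug ", newdata$drug[i],
              "; left unscored")
      next
    }
    x <- score_axis(cfg, object$panel, newdata$drug[i])
    v <- as.numeric(newdata[i, c("v_low", "v_medium", "v_high")])
    ref_v <- as.numeric(ref[j, c("v_low", "v_medium", "v_high")])
    fs <- final_score(v, ref_v, x = x, config = cfg)
    out$auc_score[i] <- fs$auc_score
    out$sensitivity_score[i] <- fs$sensitivity_score
    out$final_score[i] <- fs$final_score
  }
  out$hit <- out$final_score > object$threshold
  out[, c("pdo", "drug", "auc_score", "sensitivity_score", "final_score",
          "hit")]
}

#' Heatmap of a chemogram score matrix
#'
#' Base-graphics heatmap of final scores (PDO rows, drug columns), missing
#' pairs in grey, with drugs optionally ordered by the correlation
#' clustering.
#'
#' @param x A [chemogram()] fit or a `score_matrix`.
#' @param cluster_drugs Order drug columns by hierarchical clustering of the
#'   drug-drug Pearson correlation (when computable).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the plotted matrix.
#' @export
plot.chemogram <- function(x, cluster_drugs = TRUE, ...) {
  sm <- if (inherits(x, "score_matrix")) x else x$scores
  m <- sm$final_score
  if (cluster_drugs && ncol(m) >= 3) {
    ord <- tryCatch(drug_correlation(sm)$order, error = function(e) NULL,
                    warning = function(w) NULL)
    if (!is.null(ord)) m <- m[, ord, drop = FALSE]
  }
  z <- t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(64)
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), z, col = pal,
                  axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(nrow(z)), labels = rownames(z), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(ncol(z)), labels = colnames(z), las = 1,
                 cex.axis = 0.6)
  graphics::title(main = "Chemogram final scores")
  invisible(m)
}
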