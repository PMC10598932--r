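#' Scoring configuration
#'
#' @param hit_threshold Final-score threshold for hit calls. A drug is a hit
#'   for a PDO when its final score strictly exceeds this value; a tie is not
#'   a hit. Default 1.9, the cohort third quartile adopted by the scoring
#'   system, so a single new PDO can be scored against a stored reference
#'   without re-deriving quartiles.
#' @param threshold_mode `"fixed"` uses `hit_threshold` as given;
#'   `"cohort_q3"` re-derives it as the third quartile of all present final
#'   scores in the matrix being scored (see [hit_threshold_from_cohort()]).
#' @param auc_floor_fraction Lower floor applied to a PDO's normalized AUC
#'   before it divides the cohort AUC, keeping scores finite and monotone
#'   for total-kill profiles. Must be in (0, 0.1]; default 0.01.
#' @param spacing x-axis used for the trapezoidal AUC: `"index"` (0, 1, 2;
#'   default) or `"log10M"` (the panel's concentrations). The packaged panel
#'   has uniformly log-spaced triples, so the two give identical scores on
#'   it; index spacing additionally tolerates non-uniform custom panels.
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(hit_threshold = 1.9,
                           threshold_mode = c("fixed", "cohort_q3"),
                           auc_floor_fraction = 0.01,
                           spacing = c("index", "log10M")) {
  threshold_mode <- match.arg(threshold_mode)
  spacing <- match.arg(spacing)
  if (!is.numeric(hit_threshold) || length(hit_threshold) != 1 ||
      hit_threshold <= 0) {
    stop("hit_threshold must be a single positive number")
  }
  if (!is.numeric(auc_floor_fraction) || length(auc_floor_fraction) != 1 ||
      auc_floor_fraction <= 0 || auc_floor_fraction > 0.1) {
    stop("auc_floor_fraction must be in (0, 0.1]")
  }
  structure(list(hit_threshold = hit_threshold,
                 threshold_mode = threshold_mode,
                 auc_floor_fraction = auc_floor_fraction,
                 spacing = spacing),
            class = "scoring_config")
}

#' Normalized area under a dose-response curve
#'
#' Trapezoidal area of the viability curve over its concentration points,
#' divided by the full-response rectangle (`full` viability times the
#' x-range). 1 means no effect at any concentration, 0 complete kill at all.
#' The trapezoid rule is linear in the viabilities, so the AUC of a cohort
#' average curve equals the mean of the individual AUCs.
#'
#' @param viability Numeric vector of relative viabilities, ordered by
#'   increasing concentration (percent of control by default).
#' @param x Optional x coordinates (e.g. log10 molar concentrations);
#'   defaults to the concentration index `0:(n-1)`.
#' @param full Full-scale viability; 100 for percent units, 1 for fractions.
#' @return The normalized AUC, a dimensionless fraction (can exceed 1 when
#'   viability exceeds `full`).
#' @examples
#' normalized_auc(c(100, 100, 100))  # 1
#' normalized_auc(c(100, 50, 0))     # 0.5
#' @export
normalized_auc <- function(viability, x = NULL, full = 100) {
  n <- length(viability)
  if (n < 2) stop("need at least two points for an area")
  if (anyNA(viability)) stop("profile unavailable: viability contains NA")
  if (any(viability < 0)) stop("viability must be non-negative")
  if (is.null(x)) x <- seq_len(n) - 1
  if (length(x) != n || is.unsorted(x, strictly = TRUE)) {
    stop("x must be strictly increasing and match viability in length")
  }
  area <- sum((viability[-n] + viability[-1]) / 2 * diff(x))
  area / (full * (x[n] - x[1]))
}

#' Cohort reference curves
#'
#' For every drug, the per-level mean relative viability across all PDOs
#' with an available profile for that drug. Drugs with fewer than two
#' available profiles are dropped with a warning (a cohort of one is no
#' reference).
#'
#' @param profiles Profile data frame from [build_profiles()].
#' @return A `cohort_reference` data frame: `drug`, `v_low`, `v_medium`,
#'   `v_high`, `n_pdos`.
#' @export
cohort_reference <- function(profiles) {
  av <- profiles[profiles$available, , drop = FALSE]
  if (nrow(av) == 0) stop("no available profiles")
  drugs <- unique(av$drug)
  ref <- data.frame(
    drug = drugs,
    v_low = tapply(av$v_low, av$drug, mean)[drugs],
    v_medium = tapply(av$v_medium, av$drug, mean)[drugs],
    v_high = tapply(av$v_high, av$drug, mean)[drugs],
    n_pdos = as.integer(tapply(av$pdo, av$drug, length)[drugs]),
    stringsAsFactors = FALSE)
  thin <- ref$n_pdos < 2
  if (any(thin)) {
    warning("drug(s) with fewer than 2 available profiles dropped from ",
            "reference: ", paste(ref$drug[thin], collapse = ", "))
    ref <- ref[!thin, , drop = FALSE]
  }
  rownames(ref) <- NULL
  class(ref) <- c("cohort_reference", "data.frame")
  ref
}

# x-axis for a drug's AUC under a scoring config.
score_axis <- function(config, panel, drug) {
  if (config$spacing == "log10M") panel_conc(panel, drug) else 0:2
}

#' Per-profile score components
#'
#' `auc_score()` is the cohort-average normalized AUC divided by the PDO's
#' own normalized AUC (floored at `auc_floor_fraction`): above 1 means more
#' sensitive than the cohort average. `sensitivity_score()` is the area over
#' the PDO's curve divided by the total area, i.e. `1 - normalized_auc`:
#' 0 for no effect, 1 for complete kill, negative when mean viability
#' exceeds 100%. `final_score()` is their sum, with a strict-`>` hit call.
#'
#' @param viability Ordered (low, medium, high) viability triple, percent of
#'   control.
#' @param ref_viability Cohort-average viability triple for the same drug.
#' @param x Optional x coordinates shared by both curves (default index).
#' @param config A [scoring_config()].
#' @param full Full-scale viability (100 for percent units).
#' @return `auc_score` and `sensitivity_score` return a single number;
#'   `final_score` returns a list with `auc_score`, `sensitivity_score`,
#'   `final_score`, `hit`.
#' @examples
#' auc_score(c(100, 50, 0), c(100, 50, 0))         # 1: equals the cohort
#' sensitivity_score(c(100, 50, 0))                # 0.5
#' final_score(c(100, 50, 0), c(100, 75, 50))      # auc 1.5 + sens 0.5, hit
#' @export
auc_score <- function(viability, ref_viability, x = NULL,
                      config = scoring_config(), full = 100) {
  ref_auc <- normalized_auc(ref_viability, x = x, full = full)
  pdo_auc <- normalized_auc(viability, x = x, full = full)
  ref_auc / max(pdo_auc, config$auc_floor_fraction)
}

#' @rdname auc_score
#' @export
sensitivity_score <- function(viability, x = NULL, full = 100) {
  1 - normalized_auc(viability, x = x, full = full)
}

#' @rdname auc_score
#' @export
final_score <- function(viability, ref_viability, x = NULL,
                        config = scoring_config(), full = 100) {
  a <- auc_score(viability, ref_viability, x = x, config = config,
                 full = full)
  s <- sensitivity_score(viability, x = x, full = full)
  f <- a + s
  list(auc_score = a, sensitivity_score = s, final_score = f,
       hit = f > config$hit_threshold)
}

#' Score a whole cohort into a score matrix
#'
#' Builds the cohort reference once (per drug, the mean curve over available
#' profiles), then scores every available PDO x drug pair. The PDO being
#' scored is part of the reference average by default — the reference is the
#' response of the whole collection; set `leave_one_out = TRUE` to exclude
#' each PDO from its own reference (useful when the cohort doubles as a
#' frozen reference for prospective scoring). Pairs whose profile is
#' unavailable stay missing; drugs with fewer than two available profiles
#' are left all-missing with a warning.
#'
#' @param profiles Profile data frame from [build_profiles()].
#' @param panel A [drug panel][as_drug_panel].
#' @param config A [scoring_config()].
#' @param leave_one_out Exclude each PDO from its own drug reference.
#' @return A `score_matrix`: list with `pdo_ids`, `drugs`, and PDO x drug
#'   matrices `auc_score`, `sensitivity_score`, `final_score`, `hit`, plus
#'   the `threshold` used and the `config`.
#' @export
score_cohort <- function(profiles, panel = default_panel(),
                         config = scoring_config(), leave_one_out = FALSE) {
  av <- profiles[profiles$available, , drop = FALSE]
  if (nrow(av) == 0) stop("no available profiles to score")
  pdo_ids <- sort(unique(profiles$pdo))
  idx <- panel_match(panel, unique(profiles$drug))
  if (anyNA(idx)) {
    stop("drug(s) not in panel: ",
         paste(unique(profiles$drug)[is.na(idx)], collapse = ", "))
  }
  drugs <- panel$drug[sort(idx)]

  blank <- matrix(NA_real_, length(pdo_ids), length(drugs),
                  dimnames = list(pdo_ids, drugs))
  auc_m <- sens_m <- final_m <- blank
  suppressWarnings(ref_all <- cohort_reference(profiles))

  for (d in drugs) {
    rows <- av[av$drug == d, , drop = FALSE]
    if (nrow(rows) < 2) {
      warning("drug ", d, " has fewer than 2 available profiles; ",
              "left missing")
      next
    }
    x <- score_axis(config, panel, d)
    ref_v <- as.numeric(ref_all[ref_all$drug == d,
                                c("v_low", "v_medium", "v_high")])
    ref_auc <- normalized_auc(ref_v, x = x)
    v <- as.matrix(rows[, c("v_low", "v_medium", "v_high")])
    pdo_auc <- apply(v, 1, normalized_auc, x = x)
    if (leave_one_out) {
      # Mean AUC over the other PDOs; trapezoid linearity makes the AUC of
      # the leave-one-out mean curve equal to this.
      n <- nrow(rows)
      ref_num <- (n * ref_auc - pdo_auc) / (n - 1)
    } else {
      ref_num <- rep(ref_auc, nrow(rows))
    }
    a <- ref_num / pmax(pdo_auc, config$auc_floor_fraction)
    s <- 1 - pdo_auc
    auc_m[cbind(rows$pdo, d)] <- a
    sens_m[cbind(rows$pdo, d)] <- s
    final_m[cbind(rows$pdo, d)] <- a + s
  }

  threshold <- config$hit_threshold
  if (config$threshold_mode == "cohort_q3") {
    threshold <- hit_threshold_from_cohort(final_m)
  }
  structure(list(pdo_ids = pdo_ids, drugs = drugs,
                 auc_score = auc_m, sensitivity_score = sens_m,
                 final_score = final_m, hit = final_m > threshold,
                 threshold = threshold, config = config),
            class = "score_matrix")
}

#' Cohort-derived hit threshold
#'
#' Third quartile of all present final scores, pooled over the whole
#' matrix, using the linear-interpolation quantile rule between order
#' statistics (the common spreadsheet-style inclusive method,
#' `stats::quantile` type 7) so a derived threshold is reproducible from a
#' published score matrix.
#'
#' @param scores A `score_matrix` or a numeric vector/matrix of final scores
#'   (NAs allowed).
#' @return The third quartile of the present scores.
#' @examples
#' hit_threshold_from_cohort(c(1, 2, 3, 4))  # 3.25
#' @export
hit_threshold_from_cohort <- function(scores) {
  if (inherits(scores, "score_matrix")) scores <- scores$final_score
  v <- as.numeric(scores)
  v <- v[!is.na(v)]
  if (length(v) < 4) {
    stop("need at least 4 present scores to derive a quartile threshold")
  }
  unname(stats::quantile(v, 0.75, type = 7))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("Chemogram score matrix: ", length(x$pdo_ids), " PDOs x ",
      length(x$drugs), " drugs\n", sep = "")
  present <- sum(!is.na(x$final_score))
  cat("  present pairs: ", present, " / ",
      length(x$final_score), "; hits: ", sum(x$hit, na.rm = TRUE),
      " (final score > ", format(x$threshold), ")\n", sep = "")
  invisible(x)
}

#' Long-format view and CSV round trip for score matrices
#'
#' One row per PDO x drug cell: `pdo`, `drug`, `auc_score`,
#' `sensitivity_score`, `final_score`, `hit`. Missing (not tested / QC
#' failed) pairs keep empty score fields. `write_score_matrix()` and
#' [read_score_matrix()] round-trip values losslessly to at least 12
#' significant digits.
#'
#' @param x A `score_matrix`.
#' @param row.names,optional,... Passed through for S3 compatibility.
#' @export
as.data.frame.score_matrix <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  grid <- expand.grid(pdo = x$pdo_ids, drug = x$drugs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- cbind(grid$pdo, grid$drug)
  out <- data.frame(grid,
                    auc_score = x$auc_score[idx],
                    sensitivity_score = x$sensitivity_score[idx],
                    final_score = x$final_score[idx],
                    hit = x$hit[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(out$pdo, match(out$drug, x$drugs)), ]
  rownames(out) <- row.names
  out
}

#' @rdname as.data.frame.score_matrix
#' @param matrix A `score_matrix`.
#' @param path CSV file path.
#' @export
write_score_matrix <- function(matrix, path) {
  df <- as.data.frame(matrix)
  num <- c("auc_score", "sensitivity_score", "final_score")
  for (col in num) df[[col]] <- format_num(df[[col]])
  df$hit <- ifelse(is.na(df$hit), "", ifelse(df$hit, "TRUE", "FALSE"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname as.data.frame.score_matrix
#' @export
read_score_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = list(pdo = "character",
                                          drug = "character"))
  required <- c("pdo", "drug", "auc_score", "sensitivity_score",
                "final_score", "hit")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("score table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  pdo_ids <- sort(unique(df$pdo))
  drugs <- unique(df$drug)
  blank <- matrix(NA_real_, length(pdo_ids), length(drugs),
                  dimnames = list(pdo_ids, drugs))
  auc_m <- sens_m <- final_m <- blank
  idx <- cbind(df$pdo, df$drug)
  auc_m[idx] <- df$auc_score
  sens_m[idx] <- df$sensitivity_score
  final_m[idx] <- df$final_score
  hit_m <- blank
  hit_m[idx] <- as.numeric(as.logical(df$hit))
  # Threshold is not stored per cell; recover the strictest consistent one.
  structure(list(pdo_ids = pdo_ids, drugs = drugs,
                 auc_score = auc_m, sensitivity_score = sens_m,
                 final_score = final_m, hit = hit_m > 0,
                 threshold = infer_threshold(final_m, hit_m > 0),
                 config = scoring_config()),
            class = "score_matrix")
}

# Largest non-hit score if consistent with a strict-> rule, else the default.
infer_threshold <- function(final, hit) {
  lo <- suppressWarnings(max(final[!is.na(hit) & !hit], na.rm = TRUE))
  hi <- suppressWarnings(min(final[!is.na(hit) & hit], na.rm = TRUE))
  if (is.finite(lo) && is.finite(hi) && lo < hi) return(lo)
  if (is.finite(lo)) return(lo)
  scoring_config()$hit_threshold
}

# Full-precision numeric formatting for CSV round trips.
format_num <- function(v) {
  out <- vapply(v, function(z) {
    if (is.na(z)) "" else format(z, digits = 15, scientific = FALSE)
  }, character(1))
  out
}
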