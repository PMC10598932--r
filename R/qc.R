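#' Quality-control configuration
#'
#' @param se_threshold Exclusion threshold on the standard error of a
#'   triplicate's relative viability, in percent-of-control points. A
#'   condition is excluded when its SE strictly exceeds this value; an SE
#'   exactly at the threshold is retained. Default 12.
#' @param control_scope Whether solvent-control wells are pooled per plate
#'   (default; robust to plate-to-plate signal drift) or across the whole
#'   screen.
#' @return A `qc_config` list.
#' @export
qc_config <- function(se_threshold = 12,
                      control_scope = c("per_plate", "per_screen")) {
  control_scope <- match.arg(control_scope)
  if (!is.numeric(se_threshold) || length(se_threshold) != 1 ||
      !is.finite(se_threshold) || se_threshold <= 0) {
    stop("se_threshold must be a single positive number")
  }
  structure(list(se_threshold = se_threshold, control_scope = control_scope),
            class = "qc_config")
}

#' Summarize one triplicate against its solvent controls
#'
#' Each condition well is normalized to the mean control luminescence
#' (percent of control); the summary reports the mean relative viability
#' and the standard error of the per-well normalized values (sample SD /
#' sqrt(n), in percent points). Normalization is invariant to uniform
#' rescaling of all signals.
#'
#' @param signals Raw luminescence of the condition wells (usually 3).
#' @param control_signals Raw luminescence of the solvent-control wells.
#' @param se_threshold QC threshold in percent points (default 12).
#' @return A list with `n_wells`, `mean_rel_viability`, `se_rel_viability`
#'   and `qc_pass`.
#' @examples
#' summarize_condition(c(4000, 5000, 6000), rep(10000, 6))
#' # mean 50%, SE = 10 / sqrt(3) ~ 5.77 points
#' @export
summarize_condition <- function(signals, control_signals, se_threshold = 12) {
  if (length(signals) < 1) stop("no condition wells")
  if (length(control_signals) < 1) stop("no control wells to normalize to")
  ctrl_mean <- mean(control_signals)
  if (!is.finite(ctrl_mean) || ctrl_mean <= 0) {
    stop("control mean luminescence must be positive")
  }
  rel <- 100 * signals / ctrl_mean
  n <- length(rel)
  se <- if (n > 1) stats::sd(rel) / sqrt(n) else 0
  list(n_wells = n,
       mean_rel_viability = mean(rel),
       se_rel_viability = se,
       qc_pass = se <= se_threshold)
}

#' Collapse a well table into per-condition summaries
#'
#' Groups the condition wells of a screen by PDO x drug x level, normalizes
#' each well to the mean of the solvent controls in scope (its plate, or
#' the whole screen), and summarizes the triplicate.
#'
#' @param wells A validated well data frame ([read_well_table()]).
#' @param config A [qc_config()].
#' @return A data frame with one row per PDO x drug x level: `pdo`, `drug`,
#'   `level`, `n_wells`, `mean_rel_viability`, `se_rel_viability`, `qc_pass`.
#' @export
summarize_screen <- function(wells, config = qc_config()) {
  is_ctrl <- wells$level == "control"
  if (!any(is_ctrl)) stop("no control wells in screen")
  cond <- wells[!is_ctrl, , drop = FALSE]
  if (nrow(cond) == 0) stop("no condition wells in screen")

  # Per-well normalization denominator: control mean in scope.
  if (config$control_scope == "per_plate") {
    ctrl_means <- tapply(wells$signal[is_ctrl], wells$plate[is_ctrl], mean)
    denom <- ctrl_means[cond$plate]
    if (any(is.na(denom))) {
      stop("plate(s) without control wells: ",
           paste(unique(cond$plate[is.na(denom)]), collapse = ", "))
    }
  } else {
    denom <- rep(mean(wells$signal[is_ctrl]), nrow(cond))
  }
  if (any(denom <= 0)) stop("control mean luminescence must be positive")
  rel <- 100 * cond$signal / as.numeric(denom)

  key <- interaction(cond$pdo, cond$drug, cond$level, drop = TRUE, sep = "\r")
  mean_rel <- tapply(rel, key, mean)
  n_wells <- tapply(rel, key, length)
  se_rel <- tapply(rel, key, function(v) {
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  })
  parts <- do.call(rbind, strsplit(names(mean_rel), "\r", fixed = TRUE))
  out <- data.frame(pdo = parts[, 1], drug = parts[, 2], level = parts[, 3],
                    n_wells = as.integer(n_wells),
                    mean_rel_viability = as.numeric(mean_rel),
                    se_rel_viability = as.numeric(se_rel),
                    stringsAsFactors = FALSE)
  out$qc_pass <- out$se_rel_viability <= config$se_threshold
  out <- out[order(out$pdo, out$drug,
                   match(out$level, c("low", "medium", "high"))), ]
  rownames(out) <- NULL
  out
}

#' Partition condition summaries by the standard-error rule
#'
#' A summary is excluded if and only if its SE strictly exceeds the
#' threshold ("over" the threshold); a tie is retained. Excluded conditions
#' make the parent dose-response profile unavailable — nothing is imputed.
#'
#' @param summaries Output of [summarize_screen()].
#' @param config A [qc_config()].
#' @return A list with `retained` and `excluded` data frames partitioning
#'   the input.
#' @export
apply_qc <- function(summaries, config = qc_config()) {
  excl <- summaries$se_rel_viability > config$se_threshold
  list(retained = summaries[!excl, , drop = FALSE],
       excluded = summaries[excl, , drop = FALSE])
}

#' Assemble dose-response profiles from retained summaries
#'
#' A PDO x drug profile exists only when all three concentration levels
#' survived QC; pairs with any missing or excluded level are recorded as
#' unavailable ("not tested"/failed). Relative viabilities are clamped at 0
#' from below (areas must not go negative); values above 100% are kept, as
#' growth stimulation is real signal.
#'
#' @param retained Retained summaries from [apply_qc()].
#' @param panel A [drug panel][as_drug_panel]; drugs absent from it raise
#'   an error.
#' @return A data frame with one row per observed PDO x drug pair: `pdo`,
#'   `drug` (panel spelling), `v_low`, `v_medium`, `v_high` (percent of
#'   control; NA when unavailable) and `available`.
#' @export
build_profiles <- function(retained, panel = default_panel()) {
  if (nrow(retained) == 0) {
    return(data.frame(pdo = character(), drug = character(),
                      v_low = numeric(), v_medium = numeric(),
                      v_high = numeric(), available = logical(),
                      stringsAsFactors = FALSE))
  }
  idx <- panel_match(panel, retained$drug)
  if (anyNA(idx)) {
    stop("drug(s) not in panel: ",
         paste(unique(retained$drug[is.na(idx)]), collapse = ", "))
  }
  retained$drug <- panel$drug[idx]

  key <- paste(retained$pdo, retained$drug, retained$level, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate summary for pdo x drug x level: ",
         gsub("\r", " / ", dup, fixed = TRUE))
  }
  pairs <- unique(retained[, c("pdo", "drug")])
  lev <- function(l) {
    i <- match(paste(pairs$pdo, pairs$drug, l, sep = "\r"), key)
    pmax(retained$mean_rel_viability[i], 0)
  }
  out <- data.frame(pdo = pairs$pdo, drug = pairs$drug,
                    v_low = lev("low"), v_medium = lev("medium"),
                    v_high = lev("high"), stringsAsFactors = FALSE)
  out$available <- !is.na(out$v_low) & !is.na(out$v_medium) &
    !is.na(out$v_high)
  out[!out$available, c("v_low", "v_medium", "v_high")] <- NA_real_
  out <- out[order(out$pdo, out$drug), ]
  rownames(out) <- NULL
  out
}
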