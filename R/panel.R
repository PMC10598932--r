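#' Drug panel objects
#'
#' A drug panel is the single source of truth for the concentration axes of a
#' screen: one row per drug with its class, its three log10 molar test
#' concentrations (low < medium < high) and its solvent. [default_panel()]
#' returns the packaged 25-drug library (15 chemotherapies, 6 kinase
#' inhibitors, 2 epigenetic drugs, 2 others), each tested at three
#' uniformly log-spaced sub-molar concentrations.
#'
#' @param x A data frame with columns `drug`, `class`, `log10M_low`,
#'   `log10M_medium`, `log10M_high`, `solvent`.
#' @return A `drug_panel`: a validated data frame with those six columns.
#' @examples
#' panel <- default_panel()
#' nrow(panel)                       # 25
#' panel_conc(panel, "Oxaliplatin")  # c(-6.5, -5.75, -5)
#' @seealso [read_panel()], [panel_conc()]
#' @export
as_drug_panel <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("drug", "class", "log10M_low", "log10M_medium",
                "log10M_high", "solvent")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  x <- x[, required]
  x$drug <- trimws(as.character(x$drug))
  if (anyDuplicated(tolower(x$drug))) {
    stop("panel drug names must be unique (case-insensitive)")
  }
  valid_classes <- c("chemotherapy", "kinase_inhibitor", "epigenetic", "other")
  bad <- setdiff(unique(x$class), valid_classes)
  if (length(bad) > 0) {
    stop("unknown drug class: ", paste(bad, collapse = ", "))
  }
  valid_solvents <- c("DMSO", "PBS_tween")
  bad <- setdiff(unique(x$solvent), valid_solvents)
  if (length(bad) > 0) {
    stop("unknown solvent: ", paste(bad, collapse = ", "))
  }
  conc <- as.matrix(x[, c("log10M_low", "log10M_medium", "log10M_high")])
  if (any(!is.finite(conc))) stop("panel concentrations must be finite")
  if (any(conc >= 0)) {
    stop("panel concentrations must be negative (sub-molar, log10 M)")
  }
  increasing <- conc[, 1] < conc[, 2] & conc[, 2] < conc[, 3]
  if (any(!increasing)) {
    stop("concentration triple not strictly increasing for: ",
         paste(x$drug[!increasing], collapse = ", "))
  }
  rownames(x) <- NULL
  class(x) <- c("drug_panel", "data.frame")
  x
}

#' @rdname as_drug_panel
#' @param path Path to a panel CSV with the six columns above.
#' @export
read_panel <- function(path) {
  as_drug_panel(utils::read.csv(path, stringsAsFactors = FALSE,
                                check.names = TRUE))
}

#' @rdname as_drug_panel
#' @export
default_panel <- function() {
  read_panel(system.file("extdata", "drug_panel.csv", package = "chemogram",
                         mustWork = TRUE))
}

#' Look up a drug's concentration triple
#'
#' Drug names are matched case-insensitively after whitespace stripping.
#'
#' @param panel A [drug panel][as_drug_panel].
#' @param drug A drug name.
#' @return Numeric triple of log10 molar concentrations (low, medium, high).
#' @export
panel_conc <- function(panel, drug) {
  i <- panel_match(panel, drug)
  if (is.na(i)) stop("drug not in panel: ", drug)
  as.numeric(panel[i, c("log10M_low", "log10M_medium", "log10M_high")])
}

# Row indices of `drugs` in the panel (NA when absent); case-insensitive,
# whitespace-stripped.
panel_match <- function(panel, drugs) {
  match(tolower(trimws(drugs)), tolower(panel$drug))
}

#' @export
print.drug_panel <- function(x, ...) {
  cat("Drug panel:", nrow(x), "drugs\n")
  cat("  classes:",
      paste(sprintf("%s (%d)", names(table(x$class)), table(x$class)),
            collapse = ", "), "\n")
  print.data.frame(x, ...)
  invisible(x)
}
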