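#' Read and write well-level plate-reader tables
#'
#' The canonical raw format is a long CSV with one row per well and columns
#' `plate`, `well`, `pdo`, `drug`, `level`, `signal`:
#' * `well` — letter-row/number-column position (`A1`..`H12`);
#' * `drug` — a panel drug name, or the sentinel `CONTROL` (case-insensitive)
#'   for solvent-only wells;
#' * `level` — one of `low`, `medium`, `high`, `control`;
#' * `signal` — non-negative raw luminescence (relative light units).
#'
#' A row has `drug = CONTROL` if and only if `level = control`. Condition
#' wells are expected in the 60 center wells (rows B-G, columns 2-11); wells
#' outside that block trigger a single warning, not an error, since the
#' plate layout is otherwise unconstrained.
#'
#' @param path CSV file path.
#' @return A data frame of validated well readings with normalized columns
#'   (`drug` upper-cased to `CONTROL` on control rows, `level` lower-cased).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("plate,well,pdo,drug,level,signal",
#'              "P1,D4,CGR0002,5FU,low,8213",
#'              "P1,B2,CGR0002,CONTROL,control,10050"), f)
#' read_well_table(f)
#' @export
read_well_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("plate", "well", "pdo", "drug", "level", "signal")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("well table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  validate_wells(raw[, required])
}

# Validates and normalizes a raw well data frame; errors name the offending
# row (1-based data row, excluding the header).
validate_wells <- function(x) {
  x$plate <- trimws(x$plate)
  x$well <- toupper(trimws(x$well))
  x$pdo <- trimws(x$pdo)
  x$drug <- trimws(x$drug)
  x$level <- tolower(trimws(x$level))

  bad <- which(!grepl("^[A-H](1[0-2]|[1-9])$", x$well))
  if (length(bad) > 0) {
    stop("malformed well position ", sQuote(x$well[bad[1]]),
         " in row ", bad[1])
  }
  bad <- which(!x$level %in% c("low", "medium", "high", "control"))
  if (length(bad) > 0) {
    stop("unknown concentration level ", sQuote(x$level[bad[1]]),
         " in row ", bad[1])
  }
  signal <- suppressWarnings(as.numeric(x$signal))
  bad <- which(is.na(signal) | signal < 0)
  if (length(bad) > 0) {
    stop("luminescence must be a non-negative number; row ", bad[1],
         " has ", sQuote(x$signal[bad[1]]))
  }
  x$signal <- signal

  is_ctrl_drug <- toupper(x$drug) == "CONTROL"
  is_ctrl_level <- x$level == "control"
  bad <- which(is_ctrl_drug != is_ctrl_level)
  if (length(bad) > 0) {
    stop("row ", bad[1], ": drug must be CONTROL exactly when level is ",
         "'control' (got drug=", sQuote(x$drug[bad[1]]), ", level=",
         sQuote(x$level[bad[1]]), ")")
  }
  x$drug[is_ctrl_drug] <- "CONTROL"

  outside <- !is_center_well(x$well)
  if (any(outside)) {
    warning(sum(outside), " well(s) outside the 60-well center block ",
            "(rows B-G, columns 2-11), e.g. ", x$well[which(outside)[1]])
  }
  rownames(x) <- NULL
  x
}

#' @rdname read_well_table
#' @param wells A well data frame as returned by [read_well_table()].
#' @export
write_well_table <- function(wells, path) {
  utils::write.csv(wells[, c("plate", "well", "pdo", "drug", "level",
                             "signal")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_well_table
#' @param well Character vector of well positions.
#' @export
is_center_well <- function(well) {
  row <- substr(well, 1, 1)
  col <- suppressWarnings(as.integer(substring(well, 2)))
  !is.na(col) & row %in% LETTERS[2:7] & col >= 2 & col <= 11
}

# The 60 center wells in row-major order (B2, B3, ..., G11).
center_wells <- function() {
  as.vector(t(outer(LETTERS[2:7], 2:11, paste0)))
}

#' Convert an 8 x 12 plate map to long-format well rows
#'
#' Convenience importer for plate-shaped data: `signal` is an 8 x 12 numeric
#' matrix (rows A-H, columns 1-12) and `layout` a same-shaped character
#' matrix with entries `"<drug>:<level>"`, `"CONTROL"`, or `NA`/`""` for
#' unused wells.
#'
#' @param signal 8 x 12 numeric matrix of raw luminescence.
#' @param layout 8 x 12 character matrix describing each well.
#' @param plate_id Plate identifier.
#' @param pdo_id PDO line identifier.
#' @return A validated long-format well data frame.
#' @export
wells_from_plate_map <- function(signal, layout, plate_id, pdo_id) {
  stopifnot(identical(dim(signal), c(8L, 12L)),
            identical(dim(layout), c(8L, 12L)))
  used <- which(!is.na(layout) & layout != "", arr.ind = TRUE)
  if (nrow(used) == 0) stop("empty plate layout")
  entry <- layout[used]
  is_ctrl <- toupper(entry) == "CONTROL"
  drug <- ifelse(is_ctrl, "CONTROL", sub(":.*$", "", entry))
  level <- ifelse(is_ctrl, "control", sub("^.*:", "", entry))
  validate_wells(data.frame(
    plate = plate_id,
    well = paste0(LETTERS[used[, 1]], used[, 2]),
    pdo = pdo_id,
    drug = drug,
    level = level,
    signal = as.character(signal[used]),
    stringsAsFactors = FALSE))
}
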