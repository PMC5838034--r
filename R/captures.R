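#' @keywords internal
capture_columns <- c("individual_id", "plot_id", "survey_date",
                     "cell_row", "cell_col", "svl_mm", "mass_g", "sex")

#' Validate a capture-record table
#'
#' Checks one row per capture event against the plot geometry: required
#' columns present, parseable ISO dates, 0-based cell indices in range,
#' positive snout-vent lengths, and sex markers in `{M, F, U}`. Violations
#' are reported with the offending row number.
#'
#' @param captures A data frame of capture records.
#' @param geometry A [plot_geometry()] object.
#' @return The validated data frame, with `survey_date` coerced to `Date`,
#'   index/measure columns coerced to numeric types, invisibly usable
#'   downstream.
#' @export
validate_captures <- function(captures, geometry = plot_geometry()) {
  missing_cols <- setdiff(setdiff(capture_columns, "mass_g"), names(captures))
  if (length(missing_cols))
    stop("missing capture columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!"mass_g" %in% names(captures)) captures$mass_g <- NA_real_

  fail <- function(rows, why)
    stop(sprintf("invalid capture record(s) at row %s: %s",
                 paste(utils::head(rows, 5L), collapse = ", "), why),
         call. = FALSE)

  d <- suppressWarnings(as.Date(as.character(captures$survey_date),
                                format = "%Y-%m-%d"))
  if (anyNA(d)) fail(which(is.na(d)), "malformed survey_date (ISO date expected)")
  captures$survey_date <- d

  for (col in c("cell_row", "cell_col", "svl_mm")) {
    v <- suppressWarnings(as.numeric(captures[[col]]))
    if (anyNA(v)) fail(which(is.na(v)), paste("non-numeric", col))
    captures[[col]] <- v
  }
  bad <- captures$cell_row < 0 | captures$cell_row >= geometry$n_rows |
    captures$cell_row != floor(captures$cell_row)
  if (any(bad)) fail(which(bad),
    sprintf("cell_row outside [0, %d]", geometry$n_rows - 1L))
  bad <- captures$cell_col < 0 | captures$cell_col >= geometry$n_cols |
    captures$cell_col != floor(captures$cell_col)
  if (any(bad)) fail(which(bad),
    sprintf("cell_col outside [0, %d]", geometry$n_cols - 1L))
  captures$cell_row <- as.integer(captures$cell_row)
  captures$cell_col <- as.integer(captures$cell_col)

  if (any(captures$svl_mm <= 0)) fail(which(captures$svl_mm <= 0),
                                      "svl_mm must be > 0")
  captures$mass_g <- suppressWarnings(as.numeric(captures$mass_g))

  captures$sex <- as.character(captures$sex)
  bad <- !captures$sex %in% c("M", "F", "U")
  if (any(bad)) fail(which(bad), "sex must be one of M, F, U")

  captures$individual_id <- as.character(captures$individual_id)
  captures$plot_id <- as.character(captures$plot_id)
  captures
}

#' Read a capture table from delimited text
#'
#' Reads a comma-delimited capture-history file (one row per capture event,
#' header `individual_id,plot_id,survey_date,cell_row,cell_col,svl_mm,
#' mass_g,sex`), validates every row against the plot geometry, and returns
#' the records sorted by (plot, date, individual).
#'
#' @param path Path to the CSV file.
#' @param geometry A [plot_geometry()] object used for validation.
#' @return A validated capture-record data frame.
#' @seealso [write_captures()], [validate_captures()]
#' @export
read_captures <- function(path, geometry = plot_geometry()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = c("NA", ""))
  captures <- validate_captures(raw, geometry)
  o <- order(captures$plot_id, captures$survey_date, captures$individual_id)
  captures <- captures[o, capture_columns, drop = FALSE]
  rownames(captures) <- NULL
  captures
}

#' Write a capture table to delimited text
#'
#' Inverse of [read_captures()]; round-trips every field exactly (dates in
#' ISO-8601, empty field for missing mass).
#'
#' @param captures A validated capture-record data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_captures <- function(captures, path) {
  out <- captures[, capture_columns, drop = FALSE]
  out$survey_date <- format(as.Date(out$survey_date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
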