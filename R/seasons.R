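#' Seasonal pooling windows
#'
#' Capture histories are pooled into three-to-four-month seasonal windows
#' chosen to track the regional wet/dry cycle. The default set of five
#' windows spans February 1982 through August 1983: the 1982 dry season
#' (Feb-May), the first and second halves of the wet season (Jun-Sep,
#' Oct-Jan), the 1983 dry season (Feb-May) and the start of the 1983 wet
#' season (Jun-Aug).
#'
#' @param labels Optional character vector of window labels.
#' @param starts,ends Optional `Date` vectors of window start/end days
#'   (inclusive). All three must have equal length; windows must be ordered
#'   and disjoint.
#'
#' @return A data frame of class `"season_windows"` with columns `label`,
#'   `start`, `end`, ordered in time.
#' @examples
#' season_windows()
#' @export
season_windows <- function(labels = NULL, starts = NULL, ends = NULL) {
  if (is.null(labels)) {
    labels <- c("dry-1982", "wet1-1982", "wet2-1982", "dry-1983", "wet1-1983")
    starts <- as.Date(c("1982-02-01", "1982-06-01", "1982-10-01",
                        "1983-02-01", "1983-06-01"))
    ends <- as.Date(c("1982-05-31", "1982-09-30", "1983-01-31",
                      "1983-05-31", "1983-08-31"))
  }
  starts <- as.Date(starts); ends <- as.Date(ends)
  stopifnot(length(labels) == length(starts), length(starts) == length(ends),
            !anyDuplicated(labels), all(starts <= ends))
  o <- order(starts)
  labels <- labels[o]; starts <- starts[o]; ends <- ends[o]
  if (length(starts) > 1L && any(starts[-1L] <= ends[-length(ends)]))
    stop("season windows must be disjoint", call. = FALSE)
  structure(data.frame(label = labels, start = starts, end = ends,
                       stringsAsFactors = FALSE),
            class = c("season_windows", "data.frame"))
}

#' Annotate captures with their season
#'
#' Assigns each capture record to the unique seasonal window containing its
#' survey date. Every date must fall inside some window.
#'
#' @param captures A capture-record data frame (see [read_captures()]) with a
#'   `Date` column `survey_date`.
#' @param windows A [season_windows()] table.
#'
#' @return `captures` with an added factor column `season` whose levels are
#'   the window labels in temporal order.
#' @export
assign_seasons <- function(captures, windows = season_windows()) {
  d <- as.Date(captures$survey_date)
  idx <- rep(NA_integer_, length(d))
  for (i in seq_len(nrow(windows)))
    idx[d >= windows$start[i] & d <= windows$end[i]] <- i
  if (anyNA(idx)) {
    bad <- d[which(is.na(idx))[1]]
    stop(sprintf("capture date %s falls outside every season window",
                 format(bad)), call. = FALSE)
  }
  captures$season <- factor(windows$label[idx], levels = windows$label)
  captures
}
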