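#' Migrant-resident class pairs
#'
#' The six focal pairs: each migrant class (J, MF, MM) against each resident
#' class (RF, RM).
#'
#' @return A data frame with character columns `migrant` and `resident`.
#' @export
cohort_pairs <- function() {
  expand.grid(migrant = c("J", "MF", "MM"), resident = c("RF", "RM"),
              stringsAsFactors = FALSE)[, c("migrant", "resident")]
}

#' Shared-site proportion for one survey
#'
#' For the captures of a single (plot, survey) and a focal migrant-resident
#' class pair: the number of grid cells simultaneously occupied by at least
#' one individual of each class of the pair, divided by the number of
#' occupied cells. An individual captured more than once in one survey
#' counts once, at its first recorded cell.
#'
#' @param survey_captures Captures from one plot and one survey date, with a
#'   `cohort` column (join from [classify_cohorts()]).
#' @param pair Character vector of length 2: (migrant class, resident class).
#' @param denominator `"pair"` (default): cells occupied by either class of
#'   the focal pair; `"all"`: cells occupied by any classified individual.
#' @return A list with `n_shared_cells`, `n_occupied_cells` and
#'   `proportion` (`NA` when no cell is occupied).
#' @export
shared_site_proportion <- function(survey_captures, pair,
                                   denominator = c("pair", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(length(pair) == 2L, "cohort" %in% names(survey_captures))
  sc <- survey_captures[!duplicated(survey_captures$individual_id), ,
                        drop = FALSE]
  cell <- paste(sc$cell_row, sc$cell_col)
  in_a <- sc$cohort == pair[1]
  in_b <- sc$cohort == pair[2]
  shared <- intersect(cell[in_a], cell[in_b])
  occ <- if (denominator == "pair") unique(cell[in_a | in_b]) else unique(cell)
  n_occ <- length(occ)
  list(n_shared_cells = length(shared), n_occupied_cells = n_occ,
       proportion = if (n_occ == 0L) NA_real_ else length(shared) / n_occ)
}

#' Per-survey shared-site proportions for all plots and pairs
#'
#' Applies [shared_site_proportion()] to every (plot, survey date, class
#' pair) combination. Surveys where the pair occupies no cell are retained
#' with `proportion = NA` and are excluded from downstream averages.
#'
#' @param captures Capture records with `season` column.
#' @param cohorts A `cohort_assignments` table; cohort labels are joined by
#'   (individual, plot, season).
#' @param pairs Data frame of class pairs as from [cohort_pairs()].
#' @param denominator Passed to [shared_site_proportion()].
#' @return A data frame with one row per (plot, survey, pair): `plot_id`,
#'   `survey_date`, `season`, `migrant`, `resident`, `n_migrant`,
#'   `n_resident`, `n_shared_cells`, `n_occupied_cells`, `proportion`.
#' @export
shared_sites_table <- function(captures, cohorts, pairs = cohort_pairs(),
                               denominator = c("pair", "all")) {
  denominator <- match.arg(denominator)
  caps <- merge(captures,
                cohorts[, c("individual_id", "plot_id", "season", "cohort")],
                by = c("individual_id", "plot_id", "season"))
  caps <- caps[order(caps$plot_id, caps$survey_date, caps$individual_id), ]
  surveys <- unique(caps[, c("plot_id", "survey_date")])
  out <- vector("list", nrow(surveys) * nrow(pairs))
  k <- 0L
  for (i in seq_len(nrow(surveys))) {
    sc <- caps[caps$plot_id == surveys$plot_id[i] &
                 caps$survey_date == surveys$survey_date[i], , drop = FALSE]
    for (j in seq_len(nrow(pairs))) {
      pr <- c(pairs$migrant[j], pairs$resident[j])
      res <- shared_site_proportion(sc, pr, denominator)
      k <- k + 1L
      out[[k]] <- data.frame(
        plot_id = surveys$plot_id[i], survey_date = surveys$survey_date[i],
        season = as.character(sc$season[1L]),
        migrant = pr[1], resident = pr[2],
        n_migrant = sum(sc$cohort[!duplicated(sc$individual_id)] == pr[1]),
        n_resident = sum(sc$cohort[!duplicated(sc$individual_id)] == pr[2]),
        n_shared_cells = res$n_shared_cells,
        n_occupied_cells = res$n_occupied_cells,
        proportion = res$proportion, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Null expectation of the shared-site proportion
#'
#' Monte-Carlo mean of the shared-site proportion when `n_a` individuals of
#' one class and `n_b` of the other independently occupy uniformly random
#' cells — the discrete, density-matched analogue of complete spatial
#' randomness used for per-survey co-occupancy. For `n_a = n_b = 1` the
#' exact value is `1/n_cells`.
#'
#' @param n_a,n_b Numbers of individuals of the two classes.
#' @param n_cells Number of grid cells (default 48).
#' @param reps Number of Monte-Carlo replicates.
#' @param seed Optional integer seed.
#' @return A list with `expectation`, `se` (Monte-Carlo standard error),
#'   `reps`, and `values` (the replicate proportions). When either count is
#'   zero the expectation is `NA` (no pair can share a site).
#' @export
null_shared_expectation <- function(n_a, n_b, n_cells = 48, reps = 1000,
                                    seed = NULL) {
  stopifnot(n_a >= 0, n_b >= 0, n_cells >= 1, reps >= 1)
  if (n_a == 0 || n_b == 0)
    return(list(expectation = NA_real_, se = NA_real_, reps = 0L,
                values = numeric(0)))
  if (!is.null(seed)) set.seed(seed)
  vals <- vapply(seq_len(reps), function(i) {
    ca <- sample.int(n_cells, n_a, replace = TRUE)
    cb <- sample.int(n_cells, n_b, replace = TRUE)
    length(intersect(ca, cb)) / length(unique(c(ca, cb)))
  }, numeric(1L))
  list(expectation = mean(vals), se = stats::sd(vals) / sqrt(reps),
       reps = reps, values = vals)
}
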