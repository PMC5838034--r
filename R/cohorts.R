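#' Maturity class from snout-vent length
#'
#' Individuals below 19 mm SVL are juveniles; individuals at or above the
#' threshold are adults.
#'
#' @param svl_mm Numeric vector of snout-vent lengths (mm), all positive.
#' @param threshold_mm Maturity threshold (mm); default 19.
#' @return Character vector, `"juvenile"` or `"adult"`.
#' @examples
#' maturity_class(c(18.9, 19, 30))
#' @export
maturity_class <- function(svl_mm, threshold_mm = 19) {
  stopifnot(all(svl_mm > 0))
  ifelse(svl_mm < threshold_mm, "juvenile", "adult")
}

#' Classify individuals into migrant and resident cohorts
#'
#' For every (individual, plot, season) with at least one capture, assigns
#' one of five cohort labels: `J` (juvenile), `RF`/`RM` (resident female /
#' male) or `MF`/`MM` (migrant female / male). The rules:
#'
#' * an individual is `J` in a plot-season iff every capture there that
#'   season is below the maturity threshold;
#' * adults are residents if the individual was observed (at any stage) in
#'   the same plot during the immediately preceding season, and also in the
#'   first season of the study, where tenure cannot be assessed; all other
#'   adults are migrants. A juvenile that matures while remaining in the
#'   same plot therefore becomes a resident automatically.
#'
#' Sex is taken from the individual's first adult-stage capture; adults
#' whose sex marker is unknown are excluded from cohort assignment and
#' reported in the `"excluded"` attribute.
#'
#' @param captures Capture records; a `season` column is added via
#'   [assign_seasons()] if absent.
#' @param windows Season windows (used when `season` is absent).
#' @param threshold_mm Maturity threshold in mm.
#' @return A data frame of class `"cohort_assignments"` with columns
#'   `individual_id`, `plot_id`, `season` (factor), `cohort` (one of J, MF,
#'   MM, RF, RM) and `n_captures`, plus attribute `excluded` listing
#'   adult plot-seasons dropped for unknown sex.
#' @export
classify_cohorts <- function(captures, windows = season_windows(),
                             threshold_mm = 19) {
  if (!"season" %in% names(captures))
    captures <- assign_seasons(captures, windows)
  season_levels <- levels(captures$season)
  captures$.season_idx <- as.integer(captures$season)

  # sex from first adult-stage capture (study-wide, by date)
  adult_caps <- captures[captures$svl_mm >= threshold_mm, , drop = FALSE]
  adult_caps <- adult_caps[order(adult_caps$survey_date), , drop = FALSE]
  sex_of <- adult_caps$sex[!duplicated(adult_caps$individual_id)]
  names(sex_of) <- adult_caps$individual_id[!duplicated(adult_caps$individual_id)]

  key <- interaction(captures$individual_id, captures$plot_id,
                     captures$.season_idx, drop = TRUE)
  agg <- data.frame(
    individual_id = tapply(captures$individual_id, key, `[`, 1L),
    plot_id = tapply(captures$plot_id, key, `[`, 1L),
    season_idx = as.integer(tapply(captures$.season_idx, key, `[`, 1L)),
    max_svl = as.numeric(tapply(captures$svl_mm, key, max)),
    n_captures = as.integer(tapply(captures$svl_mm, key, length)),
    stringsAsFactors = FALSE
  )
  rownames(agg) <- NULL

  is_juv <- agg$max_svl < threshold_mm
  # presence lookup: was (individual, plot) seen in the previous season?
  pres <- paste(agg$individual_id, agg$plot_id, agg$season_idx)
  prev <- paste(agg$individual_id, agg$plot_id, agg$season_idx - 1L)
  resident <- agg$season_idx == 1L | prev %in% pres

  sex <- unname(sex_of[agg$individual_id])
  cohort <- character(nrow(agg))
  cohort[is_juv] <- "J"
  ad <- !is_juv
  cohort[ad & resident & !is.na(sex) & sex == "F"] <- "RF"
  cohort[ad & resident & !is.na(sex) & sex == "M"] <- "RM"
  cohort[ad & !resident & !is.na(sex) & sex == "F"] <- "MF"
  cohort[ad & !resident & !is.na(sex) & sex == "M"] <- "MM"

  drop <- ad & (is.na(sex) | sex == "U")
  excluded <- agg[drop, c("individual_id", "plot_id", "season_idx")]
  out <- data.frame(
    individual_id = agg$individual_id[!drop],
    plot_id = agg$plot_id[!drop],
    season = factor(season_levels[agg$season_idx[!drop]],
                    levels = season_levels),
    cohort = cohort[!drop],
    n_captures = agg$n_captures[!drop],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$plot_id, as.integer(out$season), out$individual_id), ]
  rownames(out) <- NULL
  if (nrow(excluded)) {
    excluded$season <- season_levels[excluded$season_idx]
    excluded$season_idx <- NULL
  }
  attr(out, "excluded") <- excluded
  class(out) <- c("cohort_assignments", "data.frame")
  out
}

#' Restrict captures to frequently captured individuals
#'
#' Drops individuals whose total study-wide capture count is below `k`
#' (default 3), the standard guard against transient, non-resident visitors.
#'
#' @param captures Capture records.
#' @param k Minimum number of captures over the whole study.
#' @return The retained captures, with attribute `subset_summary`: a list
#'   with `n_individuals_full`, `n_captures_full`, `n_individuals_subset`,
#'   `n_captures_subset`.
#' @export
subset_min_captures <- function(captures, k = 3) {
  stopifnot(k >= 1)
  counts <- table(captures$individual_id)
  keep_ids <- names(counts)[counts >= k]
  out <- captures[captures$individual_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "subset_summary") <- list(
    n_individuals_full = length(counts),
    n_captures_full = nrow(captures),
    n_individuals_subset = length(keep_ids),
    n_captures_subset = nrow(out)
  )
  out
}

#' Seasonal centroids of space use
#'
#' For each (individual, plot, season), the arithmetic mean of the centres
#' of the cells where the individual was captured that season: a mean
#' centroid of seasonal space use. Cohort labels are attached from a
#' [classify_cohorts()] table; plot-seasons with no cohort (excluded
#' unknown-sex adults) are dropped.
#'
#' @param captures Capture records with a `season` column.
#' @param cohorts A `cohort_assignments` table for the same data.
#' @param geometry A [plot_geometry()] object.
#' @return A data frame with columns `individual_id`, `plot_id`, `season`,
#'   `x`, `y`, `cohort`, `n_captures`.
#' @export
seasonal_centroids <- function(captures, cohorts, geometry = plot_geometry()) {
  stopifnot("season" %in% names(captures))
  cc <- cell_center(captures$cell_row, captures$cell_col, geometry)
  key <- interaction(captures$individual_id, captures$plot_id,
                     captures$season, drop = TRUE)
  cen <- data.frame(
    individual_id = tapply(captures$individual_id, key, `[`, 1L),
    plot_id = tapply(captures$plot_id, key, `[`, 1L),
    season = tapply(as.character(captures$season), key, `[`, 1L),
    x = as.numeric(tapply(cc$x, key, mean)),
    y = as.numeric(tapply(cc$y, key, mean)),
    n_captures = as.integer(tapply(cc$x, key, length)),
    stringsAsFactors = FALSE
  )
  rownames(cen) <- NULL
  m <- merge(cen,
             cohorts[, c("individual_id", "plot_id", "season", "cohort")],
             by = c("individual_id", "plot_id", "season"))
  m$season <- factor(m$season, levels = levels(captures$season))
  m <- m[order(m$plot_id, as.integer(m$season), m$individual_id),
         c("individual_id", "plot_id", "season", "x", "y", "cohort",
           "n_captures")]
  rownames(m) <- NULL
  m
}

#' Seasonal abundance of juveniles, females and males
#'
#' Counts distinct classified individuals per plot-season in three
#' demographic groups: juveniles (cohort J), females (MF or RF) and males
#' (MM or RM). Empty combinations are reported as zero counts.
#'
#' @param cohorts A `cohort_assignments` table.
#' @return A data frame with columns `plot_id`, `season`, `group`
#'   (juvenile/female/male) and `count`.
#' @export
abundance_table <- function(cohorts) {
  group <- c(J = "juvenile", MF = "female", RF = "female",
             MM = "male", RM = "male")[cohorts$cohort]
  tab <- table(plot_id = cohorts$plot_id, season = cohorts$season,
               group = factor(group, levels = c("juvenile", "female", "male")))
  out <- as.data.frame(tab, responseName = "count", stringsAsFactors = FALSE)
  out$season <- factor(out$season, levels = levels(cohorts$season))
  out$group <- factor(out$group, levels = c("juvenile", "female", "male"))
  out <- out[order(out$plot_id, as.integer(out$season), out$group), ]
  rownames(out) <- NULL
  out
}
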