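#' Configuration for a full aggregation analysis
#'
#' Collects every setting of the end-to-end analysis. Defaults are the
#' faithful choices throughout: captures pooled into the five default
#' seasons, the >= 3-captures subset, 10 null replicates per unit,
#' cross-type R values, pair-restricted shared-site denominators, the
#' theoretical CSR curve as the MAD reference, and a one-tailed MAD
#' contrast.
#'
#' @param captures A validated capture-record data frame, or a path to a
#'   capture CSV (see [read_captures()]). Ignored when `synthetic` is given.
#' @param synthetic Optional [synthetic_config()]; when supplied the input
#'   data are generated.
#' @param windows A [season_windows()] table.
#' @param geometry A [plot_geometry()] object.
#' @param min_captures Study-wide minimum captures per retained individual.
#' @param n_null_replicates Null simulations per analysis unit.
#' @param r_steps Number of steps in the G-function evaluation grid.
#' @param r_mode Clark-Evans mode, `"cross"` or `"pooled"`.
#' @param shared_denominator `"pair"` or `"all"` occupied-cell denominator.
#' @param mad_reference `"theoretical"` CSR curve or the `"simulated"`
#'   pointwise mean of the null G-hat curves.
#' @param mad_alternative Direction of the MAD contrast (default
#'   `"greater"`, the one-tailed clustering test); R and shared-site
#'   contrasts are two-sided.
#' @param alpha Significance level used in summaries.
#' @param seed Master seed; every random stream derives from it.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(captures = NULL, synthetic = NULL,
                            windows = season_windows(),
                            geometry = plot_geometry(),
                            min_captures = 3, n_null_replicates = 10,
                            r_steps = 512,
                            r_mode = c("cross", "pooled"),
                            shared_denominator = c("pair", "all"),
                            mad_reference = c("theoretical", "simulated"),
                            mad_alternative = c("greater", "two.sided"),
                            alpha = 0.05, seed = 1) {
  if (is.null(captures) && is.null(synthetic))
    stop("supply either captures or a synthetic_config", call. = FALSE)
  structure(list(captures = captures, synthetic = synthetic,
                 windows = windows, geometry = geometry,
                 min_captures = min_captures,
                 n_null_replicates = n_null_replicates, r_steps = r_steps,
                 r_mode = match.arg(r_mode),
                 shared_denominator = match.arg(shared_denominator),
                 mad_reference = match.arg(mad_reference),
                 mad_alternative = match.arg(mad_alternative),
                 alpha = alpha, seed = seed),
            class = "pipeline_config")
}

# observed + null MAD statistics for one unit, honouring the reference mode
mad_unit <- function(from_xy, to_xy, geometry, r_grid, n_replicates,
                     reference, seed) {
  n_to <- nrow(to_xy)
  nn <- cross_nnd(from_xy, to_xy, geometry)
  gh_obs <- g_hat_km(nn$nnd, nn$border, r_grid)
  null_curves <- vapply(seq_len(n_replicates), function(i) {
    pat <- simulate_csr_pattern(nrow(from_xy), n_to, geometry,
                                seed = derive_seed(seed, "MAD", i))
    nni <- cross_nnd(pat$from, pat$to, geometry)
    g_hat_km(nni$nnd, nni$border, r_grid)
  }, numeric(length(r_grid)))
  ref <- if (reference == "theoretical")
    g_theoretical(r_grid, n_to / geometry$area)
  else rowMeans(null_curves)
  obs <- mad_statistic(gh_obs, ref, r_grid)
  u_null <- apply(null_curves, 2L, function(g)
    mad_statistic(g, ref, r_grid)$u_statistic)
  list(u_obs = obs$u_statistic, argmax_r = obs$argmax_r,
       direction = obs$direction, u_null = u_null)
}

#' Fit the full migrant-resident aggregation analysis
#'
#' The package's top-level fitting function. From a capture table (read,
#' supplied, or synthesised per the config) it: pools captures into
#' seasons; classifies migrant/resident cohorts; applies the minimum-
#' capture subset; computes seasonal centroids; evaluates, for every
#' (migrant class, resident class) pair and plot-season, the border-
#' corrected Clark-Evans R and the Kaplan-Meier-corrected G-function MAD
#' statistic against density-matched CSR null replicates; evaluates
#' per-survey shared-site proportions against multinomial cell-occupancy
#' nulls; contrasts observed and null values with paired mixed-effect
#' models (season nested within plot); and ranks the five candidate
#' seasonal-abundance models by AICc.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `"attraction_analysis"`: a list with
#'   `data_summary`, `cohorts`, `centroids`, `r_table` (per pair x plot x
#'   season observed and null R and MAD values), `shared_table` (per pair x
#'   plot x survey), `contrasts` (per pair and pooled, per statistic),
#'   `abundance`, `model_ranking`, and `config`. Methods: `print`,
#'   `summary`, `plot`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(synthetic = synthetic_config(seed = 7), seed = 7)
#' fit <- run_full_pipeline(cfg)
#' print(fit)
#' }
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  geom <- config$geometry
  captures <- if (!is.null(config$synthetic)) {
    generate_captures(config$synthetic)$captures
  } else if (is.character(config$captures)) {
    read_captures(config$captures, geom)
  } else {
    validate_captures(config$captures, geom)
  }
  if (!nrow(captures)) stop("no capture records", call. = FALSE)

  captures <- assign_seasons(captures, config$windows)
  cohorts <- classify_cohorts(captures, config$windows)
  sub <- subset_min_captures(captures, config$min_captures)
  data_summary <- attr(sub, "subset_summary")
  sub_cohorts <- cohorts[cohorts$individual_id %in%
                           unique(sub$individual_id), , drop = FALSE]
  centroids <- seasonal_centroids(sub, cohorts, geom)

  pairs <- cohort_pairs()
  r_grid <- nnd_grid(geom, config$r_steps)
  plots <- sort(unique(centroids$plot_id))
  seasons <- levels(centroids$season)

  r_rows <- list(); k <- 0L
  for (j in seq_len(nrow(pairs))) {
    mig <- pairs$migrant[j]; res <- pairs$resident[j]
    pair_lab <- paste0(mig, "-", res)
    for (pl in plots) for (se in seasons) {
      cc <- centroids[centroids$plot_id == pl & centroids$season == se, ]
      from_xy <- as.matrix(cc[cc$cohort == mig, c("x", "y")])
      to_xy <- as.matrix(cc[cc$cohort == res, c("x", "y")])
      if (nrow(from_xy) < 1L || nrow(to_xy) < 1L) next
      rv <- clark_evans_r(from_xy, to_xy, geom, mode = config$r_mode)
      r_null <- null_statistics(
        nrow(from_xy), nrow(to_xy), "R",
        n_replicates = config$n_null_replicates,
        seed = derive_seed(config$seed, pl, se, pair_lab, "R"),
        geometry = geom, mode = config$r_mode)
      md <- mad_unit(from_xy, to_xy, geom, r_grid,
                     config$n_null_replicates, config$mad_reference,
                     derive_seed(config$seed, pl, se, pair_lab, "G"))
      k <- k + 1L
      r_rows[[k]] <- data.frame(
        pair = pair_lab, migrant = mig, resident = res, plot_id = pl,
        season = se, n_from = nrow(from_xy), n_to = nrow(to_xy),
        r_obs = rv$r_value, r_null_mean = r_null$mean,
        mean_observed_nnd = rv$mean_observed_nnd,
        expected_nnd = rv$expected_nnd,
        u_obs = md$u_obs, u_null_mean = mean(md$u_null),
        mad_p = mad_test_p(md$u_obs, md$u_null),
        argmax_r = md$argmax_r, direction = md$direction,
        stringsAsFactors = FALSE)
    }
  }
  r_table <- if (k) do.call(rbind, r_rows[seq_len(k)]) else NULL

  shared_table <- shared_sites_table(sub, cohorts, pairs,
                                     config$shared_denominator)
  shared_table$null_mean <- NA_real_
  usable <- !is.na(shared_table$proportion) & shared_table$n_migrant >= 1 &
    shared_table$n_resident >= 1
  for (i in which(usable)) {
    ens <- null_statistics(
      shared_table$n_migrant[i], shared_table$n_resident[i], "shared",
      n_replicates = config$n_null_replicates,
      seed = derive_seed(config$seed, shared_table$plot_id[i],
                         format(shared_table$survey_date[i]),
                         shared_table$migrant[i], shared_table$resident[i],
                         "S"),
      geometry = geom)
    shared_table$null_mean[i] <- ens$mean
  }

  contrast_rows <- list(); k <- 0L
  add_contrast <- function(pair_lab, statistic, obs, null, plot, season,
                           alternative) {
    ok <- !is.na(obs) & !is.na(null)
    if (sum(ok) < 2L) {
      res <- list(estimate = NA_real_, p_value = NA_real_,
                  mean_observed = mean(obs[ok]), mean_null = mean(null[ok]),
                  n_units = sum(ok), method = "insufficient-units")
    } else {
      res <- paired_contrast(obs, null, plot, season,
                             alternative = alternative,
                             seed = derive_seed(config$seed, pair_lab,
                                                statistic, "contrast"))
    }
    k <<- k + 1L
    contrast_rows[[k]] <<- data.frame(
      pair = pair_lab, statistic = statistic, estimate = res$estimate,
      p_value = res$p_value, mean_observed = res$mean_observed,
      mean_null = res$mean_null, n_units = res$n_units,
      method = res$method, stringsAsFactors = FALSE)
  }

  pair_labels <- paste0(pairs$migrant, "-", pairs$resident)
  for (pair_lab in c(pair_labels, "all")) {
    rt <- if (is.null(r_table)) NULL
    else if (pair_lab == "all") r_table
    else r_table[r_table$pair == pair_lab, , drop = FALSE]
    if (!is.null(rt) && nrow(rt)) {
      add_contrast(pair_lab, "R", rt$r_obs, rt$r_null_mean, rt$plot_id,
                   rt$season, "two.sided")
      add_contrast(pair_lab, "MAD", rt$u_obs, rt$u_null_mean, rt$plot_id,
                   rt$season, config$mad_alternative)
    }
    st <- if (pair_lab == "all") shared_table
    else shared_table[paste0(shared_table$migrant, "-",
                             shared_table$resident) == pair_lab, ,
                      drop = FALSE]
    if (nrow(st)) {
      add_contrast(pair_lab, "shared", st$proportion, st$null_mean,
                   st$plot_id, st$season, "two.sided")
    }
  }
  contrasts <- do.call(rbind, contrast_rows[seq_len(k)])

  abundance <- abundance_table(sub_cohorts)
  model_ranking <- rank_abundance_models(abundance)

  structure(list(data_summary = data_summary, cohorts = cohorts,
                 centroids = centroids, r_table = r_table,
                 shared_table = shared_table, contrasts = contrasts,
                 abundance = abundance, model_ranking = model_ranking,
                 config = config),
            class = "attraction_analysis")
}

#' @export
print.attraction_analysis <- function(x, ...) {
  ds <- x$data_summary
  cat("Migrant-resident aggregation analysis\n")
  cat(sprintf("  full data: %d captures of %d individuals; subset (>= %d): %d captures of %d individuals\n",
              ds$n_captures_full, ds$n_individuals_full,
              x$config$min_captures, ds$n_captures_subset,
              ds$n_individuals_subset))
  cat(sprintf("  %d plot-season analysis units; %d null replicates per unit (seed %d)\n",
              if (is.null(x$r_table)) 0L else
                length(unique(paste(x$r_table$plot_id, x$r_table$season))),
              x$config$n_null_replicates, x$config$seed))
  cat("\nPaired observed-vs-null contrasts:\n")
  cs <- x$contrasts
  cs$estimate <- round(cs$estimate, 4)
  cs$p_value <- signif(cs$p_value, 3)
  cs$mean_observed <- round(cs$mean_observed, 4)
  cs$mean_null <- round(cs$mean_null, 4)
  print(cs, row.names = FALSE)
  invisible(x)
}

#' @export
summary.attraction_analysis <- function(object, ...) {
  x <- object
  print(x)
  if (!is.null(x$r_table)) {
    cat("\nMean Clark-Evans R by pair (observed | null):\n")
    for (pl in unique(x$r_table$pair)) {
      rt <- x$r_table[x$r_table$pair == pl, ]
      cat(sprintf("  %-6s %.3f +/- %.3f SE | %.3f  (%d units)\n", pl,
                  mean(rt$r_obs), stats::sd(rt$r_obs) / sqrt(nrow(rt)),
                  mean(rt$r_null_mean), nrow(rt)))
    }
  }
  cat("\n")
  print(x$model_ranking)
  invisible(x)
}

#' @export
plot.attraction_analysis <- function(x, statistic = c("R", "MAD", "shared"),
                                     ...) {
  statistic <- match.arg(statistic)
  if (statistic %in% c("R", "MAD")) {
    rt <- x$r_table
    if (is.null(rt)) stop("no analysis units", call. = FALSE)
    col <- if (statistic == "R") "r_obs" else "u_obs"
    nullcol <- if (statistic == "R") "r_null_mean" else "u_null_mean"
    agg <- tapply(rt[[col]], rt$pair, mean)
    se <- tapply(rt[[col]], rt$pair, function(v) stats::sd(v) / sqrt(length(v)))
    bp <- graphics::barplot(agg, ylab = if (statistic == "R")
      "Clark-Evans R" else "MAD statistic",
      ylim = c(0, max(agg + 2 * se, if (statistic == "R") 1.2 else 0) * 1.1),
      ...)
    graphics::arrows(bp, agg - se, bp, agg + se, angle = 90, code = 3,
                     length = 0.04)
    if (statistic == "R") graphics::abline(h = 1, lty = 2)
    else graphics::points(bp, tapply(rt[[nullcol]], rt$pair, mean), pch = 4)
  } else {
    st <- x$shared_table
    pair <- paste0(st$migrant, "-", st$resident)
    ok <- !is.na(st$proportion)
    agg <- tapply(st$proportion[ok], pair[ok], mean)
    graphics::barplot(agg, ylab = "proportion of shared sites", ...)
  }
  invisible(x)
}
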