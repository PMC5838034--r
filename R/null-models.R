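#' Deterministic sub-seed from a master seed and a unit key
#'
#' Derives a reproducible 31-bit sub-seed from the master seed and an
#' arbitrary set of key components (plot, season, class pair, replicate
#' index, ...), so the null-replicate stream of any analysis unit can be
#' regenerated in isolation. A simple polynomial string hash combined with
#' the master seed, reduced modulo 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param ... Key components; coerced to character and concatenated.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(vapply(list(...), function(x) paste(as.character(x),
                                                   collapse = "|"),
                      character(1L)), collapse = "|")
  m <- 2147483647
  h <- as.double(master %% m)
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% m
  as.integer(h %% (m - 2)) + 1L
}

#' Simulate a density-matched CSR point pattern
#'
#' Places `n_from` focal-class and `n_to` reference-class points uniformly
#' and independently over the continuous plot window — the null model of
#' complete spatial randomness at the observed class densities.
#'
#' @param n_from,n_to Class counts, matching the observed analysis unit.
#' @param geometry A [plot_geometry()] window.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with matrices `from` and `to` (columns x, y in metres).
#' @export
simulate_csr_pattern <- function(n_from, n_to, geometry = plot_geometry(),
                                 seed = NULL) {
  stopifnot(n_from >= 0, n_to >= 0)
  if (!is.null(seed)) set.seed(seed)
  list(
    from = cbind(x = stats::runif(n_from, 0, geometry$width),
                 y = stats::runif(n_from, 0, geometry$height)),
    to = cbind(x = stats::runif(n_to, 0, geometry$width),
               y = stats::runif(n_to, 0, geometry$height))
  )
}

#' Replicate null statistics for one analysis unit
#'
#' Generates `n_replicates` density-matched null replicates for one
#' observed unit and evaluates the requested statistic on each:
#'
#' * `"R"` — continuous CSR patterns with the unit's class counts,
#'   border-corrected [clark_evans_r()];
#' * `"MAD"` — continuous CSR patterns, [mad_statistic()] of the
#'   Kaplan-Meier `Ghat` against the theoretical CSR reference at the
#'   reference-class intensity;
#' * `"shared"` — multinomial uniform cell occupancy with the unit's class
#'   counts, shared-site proportion (discrete null; `n_cells` from the
#'   geometry).
#'
#' @param n_from,n_to Observed class counts for the unit.
#' @param statistic One of `"R"`, `"MAD"`, `"shared"`.
#' @param n_replicates Number of replicate simulations (default 10).
#' @param seed Integer seed for this unit's stream (see [derive_seed()]).
#' @param geometry A [plot_geometry()] window.
#' @param r_grid Evaluation grid for `"MAD"`.
#' @param mode Clark-Evans mode for `"R"`.
#' @return An object of class `"null_ensemble"`: list with `statistic`,
#'   `values` (length `n_replicates`), `mean`, `n_replicates`, `n_from`,
#'   `n_to`, `seed`.
#' @export
null_statistics <- function(n_from, n_to, statistic = c("R", "MAD", "shared"),
                            n_replicates = 10, seed = 1,
                            geometry = plot_geometry(),
                            r_grid = nnd_grid(geometry),
                            mode = c("cross", "pooled")) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  if (n_from < 1 || n_to < 1)
    stop("degenerate unit: both classes need at least one individual",
         call. = FALSE)
  vals <- vapply(seq_len(n_replicates), function(i) {
    rs <- derive_seed(seed, statistic, i)
    if (statistic == "shared") {
      set.seed(rs)
      ca <- sample.int(geometry$n_cells, n_from, replace = TRUE)
      cb <- sample.int(geometry$n_cells, n_to, replace = TRUE)
      length(intersect(ca, cb)) / length(unique(c(ca, cb)))
    } else {
      pat <- simulate_csr_pattern(n_from, n_to, geometry, seed = rs)
      if (statistic == "R") {
        clark_evans_r(pat$from, pat$to, geometry, mode = mode)$r_value
      } else {
        nn <- cross_nnd(pat$from, pat$to, geometry)
        gh <- g_hat_km(nn$nnd, nn$border, r_grid)
        gt <- g_theoretical(r_grid, n_to / geometry$area)
        mad_statistic(gh, gt, r_grid)$u_statistic
      }
    }
  }, numeric(1L))
  structure(list(statistic = statistic, values = vals, mean = mean(vals),
                 n_replicates = n_replicates, n_from = n_from, n_to = n_to,
                 seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("Null ensemble: %s, %d replicates (n_from = %d, n_to = %d)\n",
              x$statistic, x$n_replicates, x$n_from, x$n_to))
  cat(sprintf("  mean %.4f, range [%.4f, %.4f]\n", x$mean, min(x$values),
              max(x$values)))
  invisible(x)
}

#' Monte-Carlo goodness-of-fit test for one MAD statistic
#'
#' One-sided Monte-Carlo rank test: the observed maximum absolute deviation
#' is compared with `n_null` replicate MAD values computed identically under
#' CSR, and `p = (1 + #\{u_null >= u_obs\}) / (1 + n_null)`. Under CSR the
#' observed and null statistics are exchangeable, so the test is exact.
#'
#' @param u_observed Observed MAD statistic.
#' @param u_null Numeric vector of null-replicate MAD statistics.
#' @return The Monte-Carlo p-value.
#' @export
mad_test_p <- function(u_observed, u_null) {
  (1 + sum(u_null >= u_observed)) / (1 + length(u_null))
}
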