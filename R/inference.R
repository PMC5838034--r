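#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2*loglik + 2k + 2k(k+1)/(n-k-1)`. Undefined (error) when
#' `n <= k + 1`.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters (including variance components).
#' @param n Sample size.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1)
    stop("AICc undefined: need n > k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from information-criterion values
#'
#' `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)` with
#' `delta_i = IC_i - min(IC)`. Invariant to adding a constant to all values.
#'
#' @param ic Numeric vector of AICc (or AIC) values.
#' @return Numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(ic) {
  delta <- ic - min(ic)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Paired observed-vs-null contrast with plot and season random effects
#'
#' Tests whether an observed spatial statistic differs systematically from
#' its density-matched null expectation across analysis units. The paired
#' differences `d = observed - null` are modelled with an intercept-only
#' linear mixed model with random intercepts for plot and for season nested
#' within plot (`d ~ 1, random = ~1 | plot/season`); the intercept estimate
#' and its t-test against zero are reported. When the nested fit cannot be
#' estimated (e.g. one observation per plot-season cell leaves the nested
#' variance confounded with the residual) the model falls back to a
#' plot-only random intercept, and finally to a seeded sign-flip
#' randomization test; the route taken is recorded in `method`.
#'
#' @param observed,null Numeric vectors of per-unit observed statistics and
#'   null means, aligned; units with `NA` in either are dropped.
#' @param plot,season Unit keys (character/factor vectors, same length).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (direction of the mean difference).
#' @param n_perm Randomization replicates for the fallback test.
#' @param seed Seed for the fallback randomization.
#' @return An object of class `"paired_contrast"`: list with `estimate`
#'   (mean paired difference, intercept), `p_value`, `mean_observed`,
#'   `mean_null`, `n_units`, `method` (`"lmm-nested"`, `"lmm-plot"` or
#'   `"randomization"`) and `alternative`.
#' @export
paired_contrast <- function(observed, null, plot, season,
                            alternative = c("two.sided", "less", "greater"),
                            n_perm = 2000, seed = 1) {
  alternative <- match.arg(alternative)
  stopifnot(length(observed) == length(null), length(observed) == length(plot),
            length(observed) == length(season))
  ok <- !is.na(observed) & !is.na(null)
  observed <- observed[ok]; null <- null[ok]
  plot <- as.character(plot)[ok]; season <- as.character(season)[ok]
  n_units <- length(observed)
  if (n_units < 2L)
    stop("paired_contrast needs at least 2 units", call. = FALSE)
  d <- observed - null
  dat <- data.frame(d = d, plot = factor(plot), season = factor(season))

  one_sided_p <- function(p_two, est) {
    # convert a two-sided p around a symmetric null to the requested side
    if (alternative == "two.sided") return(p_two)
    if ((alternative == "less" && est <= 0) ||
        (alternative == "greater" && est >= 0)) p_two / 2 else 1 - p_two / 2
  }

  fit_lme <- function(random) {
    tryCatch({
      fit <- nlme::lme(d ~ 1, random = random, data = dat, method = "REML",
                       control = nlme::lmeControl(returnObject = FALSE,
                                                  opt = "optim"))
      tt <- summary(fit)$tTable
      list(estimate = unname(tt[1, "Value"]), p = unname(tt[1, "p-value"]))
    }, error = function(e) NULL, warning = function(w) NULL)
  }

  method <- "lmm-nested"
  res <- if (stats::sd(d) > 0) fit_lme(~ 1 | plot / season) else NULL
  if (is.null(res)) {
    method <- "lmm-plot"
    res <- if (stats::sd(d) > 0 && nlevels(dat$plot) > 1L)
      fit_lme(~ 1 | plot) else NULL
  }
  if (is.null(res)) {
    method <- "randomization"
    set.seed(seed)
    obs_stat <- mean(d)
    flips <- vapply(seq_len(n_perm), function(i)
      mean(d * sample(c(-1, 1), n_units, replace = TRUE)), numeric(1L))
    p_two <- (1 + sum(abs(flips) >= abs(obs_stat))) / (1 + n_perm)
    res <- list(estimate = obs_stat, p = p_two)
  }

  structure(list(estimate = res$estimate,
                 p_value = one_sided_p(res$p, res$estimate),
                 mean_observed = mean(observed), mean_null = mean(null),
                 n_units = n_units, method = method,
                 alternative = alternative),
            class = "paired_contrast")
}

#' @export
print.paired_contrast <- function(x, ...) {
  cat(sprintf(
    "Paired contrast (%s, %s): estimate %.4f, p = %.4g (%d units)\n",
    x$method, x$alternative, x$estimate, x$p_value, x$n_units))
  cat(sprintf("  mean observed %.4f vs mean null %.4f\n",
              x$mean_observed, x$mean_null))
  invisible(x)
}

#' @export
coef.paired_contrast <- function(object, ...) {
  c(estimate = object$estimate)
}

#' Rank candidate seasonal-abundance models by AICc
#'
#' Fits five a priori mean structures for observed abundance counts —
#' intercept-only, season, demographic group, group + season, and the
#' saturated group x season model — as Gaussian linear mixed models with a
#' random intercept for plot, all by maximum likelihood on the same
#' response, and ranks them by AICc with Akaike weights.
#'
#' @param abundance An [abundance_table()] data frame (columns `plot_id`,
#'   `season`, `group`, `count`) from at least 2 plots.
#' @return An object of class `"model_ranking"`: a data frame with columns
#'   `model`, `k`, `loglik`, `aicc`, `delta_aicc`, `weight`, sorted by
#'   AICc, with the fitted models in attribute `fits`.
#' @export
rank_abundance_models <- function(abundance) {
  stopifnot(all(c("plot_id", "season", "group", "count") %in%
                  names(abundance)))
  if (length(unique(abundance$plot_id)) < 2L)
    stop("need at least 2 plots for the random intercept", call. = FALSE)
  dat <- data.frame(count = abundance$count,
                    season = factor(abundance$season),
                    group = factor(abundance$group),
                    plot = factor(abundance$plot_id))
  forms <- list(null = count ~ 1, season = count ~ season,
                group = count ~ group, `group+season` = count ~ group + season,
                `group x season` = count ~ group * season)
  rows <- list(); fits <- list()
  n <- nrow(dat)
  for (nm in names(forms)) {
    fit <- tryCatch(
      nlme::lme(forms[[nm]], random = ~ 1 | plot, data = dat, method = "ML"),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning(sprintf("model '%s' could not be estimated; dropped", nm),
              call. = FALSE)
      next
    }
    ll <- stats::logLik(fit)
    k <- attr(ll, "df")
    rows[[nm]] <- data.frame(model = nm, k = k, loglik = as.numeric(ll),
                             aicc = aicc(as.numeric(ll), k, n),
                             stringsAsFactors = FALSE)
    fits[[nm]] <- fit
  }
  out <- do.call(rbind, rows)
  out$delta_aicc <- out$aicc - min(out$aicc)
  out$weight <- akaike_weights(out$aicc)
  out <- out[order(out$aicc), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "n") <- n
  class(out) <- c("model_ranking", "data.frame")
  out
}

#' @export
print.model_ranking <- function(x, ...) {
  cat(sprintf("Candidate abundance models ranked by AICc (n = %d):\n",
              attr(x, "n")))
  df <- as.data.frame(x)
  df$loglik <- round(df$loglik, 2)
  df$aicc <- round(df$aicc, 2)
  df$delta_aicc <- round(df$delta_aicc, 2)
  df$weight <- round(df$weight, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
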