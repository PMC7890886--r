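#' Step 1: pooled response-propensity model
#'
#' Fits a logistic regression of responding on a continuous wave index
#' (one unit per interval, e.g. per 2 years) and the sociodemographic
#' determinants, pooling all invitees across waves. Reference levels are
#' age 25-44, male, western. Invitee-level records are aggregated to
#' binomial cell counts before fitting; the likelihood is unchanged.
#'
#' @param frame Validated sampling frame (see [load_frame()]).
#' @param covariates Character vector of frame columns to adjust for.
#' @param include_time Include the continuous wave index? Fitting a time
#'   trend requires at least two waves.
#' @param config An [analysis_config()].
#' @return List of class `nr_response_fit` with elements `coefficients`
#'   (tibble: term, estimate, se, or, ci_low, ci_high, p_value), `loglik`
#'   (invitee-level Bernoulli log-likelihood), `n_records`, `n_waves`,
#'   and the underlying `glm` fit.
#' @export
#' @examples
#' sim <- simulate_survey(simulation_design(invitations_per_wave = 500),
#'                        seed = 1)
#' fit <- fit_pooled_response_model(sim$frame)
#' fit$coefficients
fit_pooled_response_model <- function(frame,
                                      covariates = c("age_group", "sex",
                                                     "ethnicity"),
                                      include_time = TRUE,
                                      config = analysis_config()) {
  frame <- .with_refs(frame, config)
  n_waves <- dplyr::n_distinct(frame$wave_year)
  if (include_time && n_waves < 2) {
    stop("time trend undefined: the frame spans a single wave")
  }
  for (cov in covariates) {
    if (dplyr::n_distinct(frame[[cov]]) < 2) {
      stop("rank-deficient design: covariate '", cov,
           "' is constant across the frame")
    }
  }
  terms <- c(if (include_time) "time_index", covariates)
  fit <- .fit_binomial(frame, terms, config)
  structure(
    list(coefficients = .tidy_or(fit),
         loglik = .bernoulli_loglik(fit),
         n_records = nrow(frame),
         n_waves = n_waves,
         glm = fit),
    class = "nr_response_fit"
  )
}

#' @export
print.nr_response_fit <- function(x, ...) {
  cat("Pooled response-propensity fit on", x$n_records, "invitees across",
      x$n_waves, "waves\n")
  print(x$coefficients, ...)
  invisible(x)
}

# Aggregate to binomial counts and fit cbind(r, n - r) ~ terms.
.fit_binomial <- function(frame, terms, config, extra_formula = NULL) {
  frame$time_index <- .time_index(frame$wave_year,
                                  time_unit_years = config$time_unit_years)
  agg_vars <- unique(c("time_index",
                       intersect(terms, names(frame)),
                       all.vars(extra_formula)))
  agg_vars <- intersect(agg_vars, names(frame))
  counts <- dplyr::summarise(
    frame,
    n_resp = sum(.data$responded), n_tot = dplyr::n(),
    .by = dplyr::all_of(agg_vars)
  )
  counts <- droplevels(counts)
  rhs <- paste(c(terms, if (!is.null(extra_formula)) extra_formula),
               collapse = " + ")
  form <- stats::as.formula(paste("cbind(n_resp, n_tot - n_resp) ~", rhs))
  fit <- glm(form, family = binomial(), data = counts)
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design: inestimable term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  se <- sqrt(diag(vcov(fit)))
  if (any(abs(cf) > 15 & se > 10)) {
    bad <- names(cf)[abs(cf) > 15 & se > 10]
    stop("complete separation detected for term(s): ",
         paste(bad, collapse = ", "))
  }
  fit
}

.tidy_or <- function(fit) {
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    or = exp(unname(est)),
    ci_low = exp(unname(est) - .z95 * unname(se)),
    ci_high = exp(unname(est) + .z95 * unname(se)),
    p_value = 2 * pnorm(-abs(unname(est) / unname(se)))
  )
}

# Invitee-level Bernoulli log-likelihood from an aggregated binomial fit.
.bernoulli_loglik <- function(fit) {
  p <- fit$fitted.values
  r <- fit$y * fit$prior.weights
  n <- fit$prior.weights
  sum(r * log(p) + (n - r) * log1p(-p))
}

#' Step 1: screen a covariate for a time-by-covariate interaction
#'
#' Likelihood-ratio test of the pooled response model with versus without
#' `time x covariate` terms. A significant interaction indicates that the
#' covariate's subgroups changed their probability of responding at
#' different rates. Flagged at `config$interaction_alpha` (default 0.10).
#' Per-term Wald statistics are attached as the `"wald"` attribute.
#'
#' @inheritParams fit_pooled_response_model
#' @param covariate Name of the frame column to screen.
#' @return One-row tibble: covariate, statistic, df, p_value, flagged.
#' @export
test_time_interactions <- function(frame, covariate,
                                   covariates = c("age_group", "sex",
                                                  "ethnicity"),
                                   config = analysis_config()) {
  frame <- .with_refs(frame, config)
  if (dplyr::n_distinct(frame[[covariate]]) < 2) {
    stop("rank-deficient design: covariate '", covariate,
         "' is constant across the frame")
  }
  if (dplyr::n_distinct(frame$wave_year) < 2) {
    stop("time trend undefined: the frame spans a single wave")
  }
  covariates <- union(covariates, covariate)
  base_terms <- c("time_index", covariates)
  base <- .fit_binomial(frame, base_terms, config)
  full <- .fit_binomial(frame, c(base_terms,
                                 paste0("time_index:", covariate)),
                        config)
  stat <- base$deviance - full$deviance
  df <- base$df.residual - full$df.residual
  p <- pchisq(stat, df, lower.tail = FALSE)
  out <- tibble::tibble(
    covariate = covariate,
    statistic = stat,
    df = df,
    p_value = p,
    flagged = p < config$interaction_alpha
  )
  wald <- .tidy_or(full)
  attr(out, "wald") <- wald[grepl("time_index:", wald$term, fixed = TRUE), ]
  out
}

#' Step 1: response time trends stratified by a covariate
#'
#' One logistic fit of response on the wave index per level of `covariate`,
#' adjusted for the remaining determinants, returning the per-interval
#' trend OR and 95% CI for each level.
#'
#' @inheritParams test_time_interactions
#' @param adjust Covariates adjusted for within each stratum (default: the
#'   other standard determinants). Use `NULL` for unadjusted trends.
#' @return Tibble: level, n_invited, or, ci_low, ci_high, p_value.
#' @export
fit_stratified_time_trends <- function(frame, covariate,
                                       adjust = setdiff(
                                         c("age_group", "sex", "ethnicity"),
                                         covariate
                                       ),
                                       config = analysis_config()) {
  frame <- .with_refs(frame, config)
  first_wave <- min(frame$wave_year)
  levs <- unique(as.character(frame[[covariate]]))
  levs <- levs[order(match(levs, levels(frame[[covariate]])))]
  rows <- lapply(levs, function(lev) {
    sub <- frame[as.character(frame[[covariate]]) == lev, , drop = FALSE]
    if (nrow(sub) == 0) {
      stop("empty stratum for level '", lev, "'")
    }
    if (dplyr::n_distinct(sub$wave_year) < 2) {
      stop("stratum '", lev, "' spans fewer than 2 waves; ",
           "time trend undefined")
    }
    sub$wave_year <- sub$wave_year # keep global origin for comparability
    sub$time_index <- .time_index(sub$wave_year, first_wave,
                                  config$time_unit_years)
    keep <- intersect(adjust, names(sub))
    keep <- keep[vapply(keep,
                        function(v) dplyr::n_distinct(sub[[v]]) > 1,
                        logical(1))]
    fit <- .fit_binomial(sub, c("time_index", keep), config)
    tr <- .tidy_or(fit)
    tr <- tr[tr$term == "time_index", ]
    tibble::tibble(level = lev, n_invited = nrow(sub), or = tr$or,
                   ci_low = tr$ci_low, ci_high = tr$ci_high,
                   p_value = tr$p_value)
  })
  dplyr::bind_rows(rows)
}

#' Cumulative change in response odds
#'
#' Converts a per-interval odds ratio into the percent change in response
#' odds accumulated over `n_intervals` intervals:
#' `100 * (1 - or^n_intervals)`. Positive values are decreases; negative
#' values mean the odds increased. With `n_intervals = 1` this is the
#' per-interval percent change itself.
#'
#' @param or_per_interval Odds ratio per interval (> 0).
#' @param n_intervals Number of intervals (>= 0).
#' @return Percent change in odds (vectorised).
#' @export
#' @examples
#' cumulative_change(0.96, 11) # ~36% decrease over 11 biennial intervals
cumulative_change <- function(or_per_interval, n_intervals) {
  stopifnot(all(or_per_interval > 0), all(n_intervals >= 0))
  100 * (1 - or_per_interval^n_intervals)
}

#' Per-wave response rates
#'
#' Responders over invitees per wave, optionally split by a subgroup
#' variable. Cells without invitees simply do not appear.
#'
#' @param frame Validated sampling frame.
#' @param by Optional frame column to split by.
#' @return Tibble: wave_year, (level,) n_invited, n_responded, rate_pct.
#' @export
response_rate_table <- function(frame, by = NULL) {
  groups <- c("wave_year", by)
  rates <- dplyr::summarise(
    frame,
    n_invited = dplyr::n(),
    n_responded = sum(.data$responded),
    .by = dplyr::all_of(groups)
  )
  rates$rate_pct <- 100 * rates$n_responded / rates$n_invited
  if (!is.null(by)) {
    names(rates)[names(rates) == by] <- "level"
    rates$level <- as.character(rates$level)
  }
  dplyr::arrange(rates, dplyr::across(dplyr::any_of(c("wave_year",
                                                      "level"))))
}

#' Most-to-least responsive gap per wave
#'
#' @param rates Output of [response_rate_table()] with a `level` column.
#' @return Tibble: wave_year, gap_pts (max minus min subgroup rate).
#' @export
response_gap <- function(rates) {
  if (!"level" %in% names(rates)) {
    stop("rates must be split by a subgroup (call response_rate_table ",
         "with `by`)")
  }
  dplyr::summarise(
    rates,
    gap_pts = max(.data$rate_pct, na.rm = TRUE) -
      min(.data$rate_pct, na.rm = TRUE),
    .by = "wave_year"
  )
}
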