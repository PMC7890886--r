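#' Step 4: per-wave logistic associations between an outcome and
#' demographics
#'
#' For each wave, fits an unweighted logistic regression of the
#' dichotomised outcome on the sociodemographic determinants, additionally
#' adjusted for household income band (complete-case on income for this
#' step only). Reference levels: age 25-44, male, western, low income.
#' Waves where the fit fails (empty covariate level, separation) are
#' recorded with `status = "failed"` rather than raising an error, so the
#' remaining waves can still feed the trend analysis.
#'
#' @param data Joined respondent table (see [join_respondents()]) with the
#'   derived outcome indicators and `income_band`.
#' @param outcome `"sport"`, `"tv"`, or the name of a logical column.
#' @param covariates Model covariates.
#' @param config An [analysis_config()].
#' @return Tibble: wave_year, term, estimate, se, or, ci_low, ci_high,
#'   p_value, n, status (`"ok"` rows carry estimates; `"failed"` rows
#'   carry the failure reason in `term`).
#' @export
fit_wave_association_models <- function(data,
                                        outcome = c("sport", "tv"),
                                        covariates = c("age_group", "sex",
                                                       "ethnicity",
                                                       "income_band"),
                                        config = analysis_config()) {
  col <- if (length(outcome) == 1 && !outcome %in% c("sport", "tv")) {
    outcome
  } else {
    switch(match.arg(outcome), sport = "sport_weekly", tv = "tv_3h")
  }
  if (!col %in% names(data)) {
    stop("outcome column '", col, "' not available")
  }
  data <- .with_refs(data, config)
  keep <- complete.cases(data[c(col, covariates)])
  data <- data[keep, , drop = FALSE]
  waves <- sort(unique(data$wave_year))
  rows <- lapply(waves, function(w) {
    sub <- droplevels(data[data$wave_year == w, , drop = FALSE])
    res <- tryCatch({
      for (cov in covariates) {
        if (dplyr::n_distinct(sub[[cov]]) < 2) {
          stop("covariate '", cov, "' has a single level in wave ", w)
        }
      }
      # aggregate to binomial counts per covariate cell
      counts <- dplyr::summarise(
        sub,
        n_resp = sum(.data[[col]]), n_tot = dplyr::n(),
        .by = dplyr::all_of(covariates)
      )
      form <- stats::as.formula(paste(
        "cbind(n_resp, n_tot - n_resp) ~",
        paste(covariates, collapse = " + ")
      ))
      fit <- glm(form, family = binomial(), data = counts)
      if (anyNA(coef(fit))) stop("inestimable terms in wave ", w)
      se <- sqrt(diag(vcov(fit)))
      if (any(abs(coef(fit)) > 15 & se > 10)) {
        stop("separation in wave ", w)
      }
      tidy <- .tidy_or(fit)
      tidy <- tidy[tidy$term != "(Intercept)", ]
      tidy$wave_year <- w
      tidy$n <- nrow(sub)
      tidy$status <- "ok"
      tidy
    }, error = function(e) {
      tibble::tibble(term = conditionMessage(e), estimate = NA_real_,
                     se = NA_real_, or = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, p_value = NA_real_,
                     wave_year = w, n = nrow(sub), status = "failed")
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  dplyr::relocate(out, "wave_year")
}

#' Step 4: trend in a per-wave log-odds ratio
#'
#' Inverse-variance weighted linear regression (fixed-effect
#' meta-regression) of the per-wave log-OR of `term` on the wave index.
#' An unweighted variant is available as a sensitivity analysis via
#' `weighted = FALSE`. Flagged when the slope's p-value is below
#' `significance_alpha`; `fitted_change_log_or` (slope times the index
#' span) is returned for magnitude judgements.
#'
#' @param fits Output of [fit_wave_association_models()].
#' @param term Coefficient name as it appears in `fits$term`.
#' @param weighted Weight waves by `1 / se^2`?
#' @param config An [analysis_config()].
#' @return One-row tibble: term, n_waves, slope, se, p_value,
#'   fitted_change_log_or, flagged.
#' @export
or_time_trend <- function(fits, term, weighted = TRUE,
                          config = analysis_config()) {
  sub <- fits[fits$status == "ok" & fits$term == term, , drop = FALSE]
  if (nrow(sub) < 3) {
    stop("trend in OR requires at least 3 successful wave fits for ",
         "term '", term, "'")
  }
  x <- .time_index(sub$wave_year, min(fits$wave_year),
                   config$time_unit_years)
  y <- sub$estimate
  if (weighted) {
    res <- .wls_slope(x, y, 1 / sub$se^2)
  } else {
    fit <- summary(lm(y ~ x))$coefficients
    res <- list(slope = fit["x", "Estimate"], se = fit["x", "Std. Error"],
                p_value = fit["x", "Pr(>|t|)"])
  }
  flagged <- res$p_value < config$significance_alpha
  tibble::tibble(term = term, n_waves = nrow(sub), slope = res$slope,
                 se = res$se, p_value = res$p_value,
                 fitted_change_log_or = res$slope * (max(x) - min(x)),
                 flagged = flagged)
}

# Closed-form weighted least squares with fixed-effect (known-variance)
# standard error for the slope; z-test.
.wls_slope <- function(x, y, w) {
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xb)^2)
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  se <- sqrt(1 / sxx)
  z <- slope / se
  list(slope = slope, se = se, p_value = 2 * pnorm(-abs(z)))
}
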