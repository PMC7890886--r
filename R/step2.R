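#' Step 2: per-wave variation (SD) of a continuous outcome
#'
#' Sample mean and SD (n - 1 denominator) of a raw continuous outcome per
#' wave, overall or split by a subgroup variable, computed on respondents
#' only. Waves in which the outcome was not collected are omitted from the
#' series, never zero-filled.
#'
#' @param data Joined respondent table (see [join_respondents()]).
#' @param outcome Name of the continuous outcome column, e.g.
#'   `"sport_times_per_year"`.
#' @param by Optional subgroup column to split by.
#' @return Tibble: wave_year, (level,) n, mean, sd. `sd` is `NA` when
#'   `n < 2`.
#' @export
variation_by_wave <- function(data, outcome, by = NULL) {
  if (!outcome %in% names(data)) {
    stop("outcome column '", outcome, "' not found")
  }
  data <- data[!is.na(data[[outcome]]), , drop = FALSE]
  if (nrow(data) == 0) {
    stop("outcome '", outcome, "' has no observed values")
  }
  groups <- c("wave_year", by)
  series <- dplyr::summarise(
    data,
    n = dplyr::n(),
    mean = mean(.data[[outcome]]),
    sd = sd(.data[[outcome]]),
    .by = dplyr::all_of(groups)
  )
  if (!is.null(by)) {
    names(series)[names(series) == by] <- "level"
    series$level <- as.character(series$level)
  }
  series <- dplyr::arrange(series,
                           dplyr::across(dplyr::any_of(c("level",
                                                         "wave_year"))))
  attr(series, "outcome") <- outcome
  series
}

#' Step 2: test for a change in variation over time
#'
#' Ordinary linear trend of the per-wave SD on the wave index, per level
#' when the series is split. The flag combines statistical and practical
#' significance: `p < significance_alpha` *and* the fitted first-to-last
#' relative change in SD exceeds `sd_change_threshold_pct` percent (fitted
#' endpoints, so a single noisy end wave cannot decide the magnitude).
#'
#' @param series Output of [variation_by_wave()].
#' @param config An [analysis_config()].
#' @return Tibble: (level,) n_waves, slope (SD units per interval),
#'   p_value, rel_change_pct, flagged.
#' @export
test_variation_trend <- function(series, config = analysis_config()) {
  .trend_by_level(series, value_col = "sd", config = config,
                  gate = function(fitted_first, fitted_last, fitted_change,
                                  p) {
                    rel <- 100 * fitted_change / fitted_first
                    list(rel_change_pct = rel,
                         flagged = p < config$significance_alpha &&
                           abs(rel) > config$sd_change_threshold_pct)
                  })
}

# Shared linear-trend machinery for the step-2 and step-3 series tests.
# `gate` receives the fitted endpoints, fitted change and p-value and
# returns extra columns including `flagged`.
.trend_by_level <- function(series, value_col, config, gate) {
  run <- function(sub, level = NULL) {
    sub <- sub[!is.na(sub[[value_col]]), , drop = FALSE]
    if (nrow(sub) < 3) {
      stop("trend test requires at least 3 waves",
           if (!is.null(level)) paste0(" (level '", level, "')"))
    }
    sub <- sub[order(sub$wave_year), , drop = FALSE]
    x <- .time_index(sub$wave_year,
                     time_unit_years = config$time_unit_years)
    y <- sub[[value_col]]
    fit <- lm(y ~ x)
    sm <- summary(fit)$coefficients
    slope <- sm["x", "Estimate"]
    p <- sm["x", "Pr(>|t|)"]
    fitted_change <- slope * (max(x) - min(x))
    fitted_first <- unname(coef(fit)[1] + slope * min(x))
    extra <- gate(fitted_first = fitted_first,
                  fitted_last = fitted_first + fitted_change,
                  fitted_change = fitted_change, p = p)
    out <- tibble::tibble(n_waves = nrow(sub), slope = slope, p_value = p)
    for (nm in names(extra)) out[[nm]] <- extra[[nm]]
    if (!is.null(level)) out <- dplyr::bind_cols(
      tibble::tibble(level = level), out
    )
    out
  }
  if ("level" %in% names(series)) {
    dplyr::bind_rows(lapply(unique(series$level), function(lev) {
      run(series[series$level == lev, , drop = FALSE], lev)
    }))
  } else {
    run(series)
  }
}
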