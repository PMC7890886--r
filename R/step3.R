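#' Step 3: post-stratification weights for one wave
#'
#' Computes respondent weights so that the weighted sample mirrors the
#' population over the weighting cells (age group x sex x ethnicity x
#' district by default). When every populated margin cell contains at
#' least one respondent, exact cell weighting is used:
#' `w_cell = (N_cell / N) / (n_cell / n)`. When some populated cells have
#' no respondents, the weights are instead raked (iterative proportional
#' fitting) over the one-way margins of the cell variables, run to
#' convergence. Weights are normalised to mean 1 within the wave; the
#' method used is recorded in the `"method"` attribute.
#'
#' @param respondents Respondent records of a single wave carrying the
#'   cell variables and `person_id`.
#' @param margins Population margins for the same wave (columns: the cell
#'   variables plus `population_count`).
#' @param cell_vars Weighting cell variables.
#' @param tol Convergence tolerance on margin shares for raking.
#' @return Tibble `person_id`, `weight`, with attributes `method`
#'   (`"cell"` or `"raking"`) and `iterations`.
#' @export
#' @examples
#' resp <- tibble::tibble(person_id = as.character(1:20),
#'                        g = rep(c("A", "B"), each = 10))
#' marg <- tibble::tibble(g = c("A", "B"), population_count = c(900, 100))
#' compute_poststrat_weights(resp, marg, cell_vars = "g")
compute_poststrat_weights <- function(respondents, margins,
                                      cell_vars = c("age_group", "sex",
                                                    "ethnicity",
                                                    "district"),
                                      tol = 1e-10) {
  if (nrow(respondents) == 0) {
    stop("no respondents to weight")
  }
  if ("wave_year" %in% names(respondents) &&
      dplyr::n_distinct(respondents$wave_year) > 1) {
    stop("compute_poststrat_weights expects a single wave")
  }
  resp <- respondents
  for (v in cell_vars) resp[[v]] <- as.character(resp[[v]])
  marg <- margins
  for (v in cell_vars) marg[[v]] <- as.character(marg[[v]])
  marg <- dplyr::summarise(marg,
                           population_count = sum(.data$population_count),
                           .by = dplyr::all_of(cell_vars))

  counts <- dplyr::count(resp, dplyr::across(dplyr::all_of(cell_vars)),
                         name = "n_resp")
  joined <- dplyr::left_join(counts, marg, by = cell_vars)
  if (anyNA(joined$population_count) ||
      any(joined$population_count == 0)) {
    stop("respondent cell(s) with zero or missing population count")
  }

  pop_total <- sum(marg$population_count)
  populated <- marg[marg$population_count > 0, , drop = FALSE]
  covered <- nrow(dplyr::anti_join(populated, counts,
                                   by = cell_vars)) == 0

  if (covered) {
    joined$weight <- (joined$population_count / pop_total) /
      (joined$n_resp / nrow(resp))
    w <- dplyr::left_join(resp[, c("person_id", cell_vars)], joined,
                          by = cell_vars)$weight
    method <- "cell"
    iterations <- 0L
  } else {
    raked <- .rake_weights(resp, marg, cell_vars, tol = tol)
    w <- raked$w
    method <- "raking"
    iterations <- raked$iterations
  }
  w <- w / mean(w)
  out <- tibble::tibble(person_id = resp$person_id, weight = w)
  attr(out, "method") <- method
  attr(out, "iterations") <- iterations
  out
}

# Iterative proportional fitting over the one-way margins of cell_vars.
.rake_weights <- function(resp, marg, cell_vars, tol = 1e-10,
                          max_iter = 2000L) {
  targets <- lapply(cell_vars, function(v) {
    tgt <- tapply(marg$population_count, marg[[v]], sum)
    obs_levels <- unique(resp[[v]])
    missing_lev <- setdiff(names(tgt)[tgt > 0], obs_levels)
    if (length(missing_lev) > 0) {
      warning("no respondents for ", v, " level(s) ",
              paste(missing_lev, collapse = ", "),
              "; margin renormalised over represented levels")
      tgt <- tgt[names(tgt) %in% obs_levels]
    }
    tgt / sum(tgt)
  })
  names(targets) <- cell_vars

  w <- rep(1, nrow(resp))
  for (iter in seq_len(max_iter)) {
    for (v in cell_vars) {
      cur <- tapply(w, resp[[v]], sum) / sum(w)
      adj <- targets[[v]][names(cur)] / cur
      w <- w * adj[resp[[v]]]
    }
    dev <- max(vapply(cell_vars, function(v) {
      cur <- tapply(w, resp[[v]], sum) / sum(w)
      max(abs(cur - targets[[v]][names(cur)]))
    }, numeric(1)))
    if (dev < tol) {
      return(list(w = unname(w), iterations = iter))
    }
  }
  warning("raking did not reach tolerance ", tol, " in ", max_iter,
          " iterations (deviation ", signif(dev, 3), ")")
  list(w = unname(w), iterations = max_iter)
}

#' Post-stratification weights for every wave
#'
#' @param frame Validated sampling frame.
#' @param margins Population margins table with a `wave_year` column.
#' @inheritParams compute_poststrat_weights
#' @return Tibble: person_id, wave_year, weight.
#' @export
poststrat_weights <- function(frame, margins,
                              cell_vars = c("age_group", "sex",
                                            "ethnicity", "district"),
                              tol = 1e-10) {
  responders <- dplyr::filter(frame, .data$responded)
  waves <- sort(unique(responders$wave_year))
  out <- lapply(waves, function(w) {
    m <- margins[margins$wave_year == w, , drop = FALSE]
    if (nrow(m) == 0) stop("no margins for wave ", w)
    ws <- compute_poststrat_weights(
      responders[responders$wave_year == w, , drop = FALSE],
      m, cell_vars = cell_vars, tol = tol
    )
    ws$wave_year <- w
    ws
  })
  dplyr::bind_rows(out)
}

#' Weighted prevalence of a binary outcome
#'
#' `100 * sum(w * y) / sum(w)`, ignoring missing outcome values (their
#' weights are dropped too). Equal weights reproduce the unweighted
#' prevalence.
#'
#' @param y Logical or 0/1 outcome values.
#' @param weights Positive weights (default: equal).
#' @return Prevalence in percent, `NA` for empty input.
#' @export
weighted_prevalence <- function(y, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(y))
  stopifnot(length(weights) == length(y))
  keep <- !is.na(y)
  y <- as.numeric(y[keep])
  w <- weights[keep]
  if (length(y) == 0) return(NA_real_)
  if (any(w <= 0)) stop("weights must be positive")
  100 * sum(w * y) / sum(w)
}

#' Step 3: weighted versus unweighted prevalence per wave
#'
#' For each wave (and optionally each level of a subgroup variable),
#' computes the unweighted prevalence of a dichotomised outcome among
#' respondents, the post-stratification weighted prevalence, and their
#' difference in percentage points (weighted minus unweighted). Waves in
#' which the outcome was not collected are omitted.
#'
#' @param frame Validated sampling frame.
#' @param outcomes Outcome table.
#' @param margins Population margins table.
#' @param outcome `"sport"` or `"tv"` (dichotomised with the config
#'   thresholds), or the name of any logical column already present.
#' @param by Optional subgroup column.
#' @param weights Optional precomputed [poststrat_weights()] table; when
#'   `NULL` weights are computed from `margins`.
#' @param config An [analysis_config()].
#' @return Tibble: wave_year, (level,) n, unweighted_pct, weighted_pct,
#'   diff_pts.
#' @export
prevalence_contrast_series <- function(frame, outcomes, margins,
                                       outcome = c("sport", "tv"),
                                       by = NULL, weights = NULL,
                                       config = analysis_config()) {
  col <- if (length(outcome) == 1 && !outcome %in% c("sport", "tv")) {
    outcome
  } else {
    switch(match.arg(outcome), sport = "sport_weekly", tv = "tv_3h")
  }
  data <- join_respondents(frame, outcomes, config)
  if (!col %in% names(data)) {
    stop("outcome column '", col, "' not available")
  }
  if (is.null(weights)) {
    weights <- poststrat_weights(frame, margins)
  }
  data <- dplyr::inner_join(data,
                            weights[, c("person_id", "weight")],
                            by = "person_id")
  data <- data[!is.na(data[[col]]), , drop = FALSE]
  if (nrow(data) == 0) stop("outcome '", col, "' has no observed values")
  groups <- c("wave_year", by)
  series <- dplyr::summarise(
    data,
    n = dplyr::n(),
    unweighted_pct = weighted_prevalence(.data[[col]]),
    weighted_pct = weighted_prevalence(.data[[col]], .data$weight),
    .by = dplyr::all_of(groups)
  )
  series$diff_pts <- series$weighted_pct - series$unweighted_pct
  if (!is.null(by)) {
    names(series)[names(series) == by] <- "level"
    series$level <- as.character(series$level)
  }
  dplyr::arrange(series,
                 dplyr::across(dplyr::any_of(c("level", "wave_year"))))
}

#' Summary of weighted-minus-unweighted differences
#'
#' Mean and interquartile range of the per-wave (and per-level)
#' differences. Quartiles use linear interpolation between closest ranks
#' (`stats::quantile` type 7).
#'
#' @param series Output of [prevalence_contrast_series()].
#' @return One-row tibble: n, mean_diff_pts, iqr_low, iqr_high.
#' @export
contrast_summary <- function(series) {
  d <- series$diff_pts[!is.na(series$diff_pts)]
  q <- quantile(d, c(0.25, 0.75), type = 7, names = FALSE)
  tibble::tibble(n = length(d), mean_diff_pts = mean(d),
                 iqr_low = q[1], iqr_high = q[2])
}

#' Step 3: test for a trend in the weighted-unweighted difference
#'
#' Linear trend of `diff_pts` on the wave index, per level when split.
#' Flagged when the slope is significant at `significance_alpha` *and*
#' the fitted change from first to last wave exceeds
#' `prevalence_change_threshold_pts` percentage points.
#'
#' @param series Output of [prevalence_contrast_series()].
#' @param config An [analysis_config()].
#' @return Tibble: (level,) n_waves, slope, p_value, fitted_change_pts,
#'   flagged.
#' @export
test_difference_trend <- function(series, config = analysis_config()) {
  .trend_by_level(series, value_col = "diff_pts", config = config,
                  gate = function(fitted_first, fitted_last, fitted_change,
                                  p) {
                    list(fitted_change_pts = fitted_change,
                         flagged = p < config$significance_alpha &&
                           abs(fitted_change) >
                             config$prevalence_change_threshold_pts)
                  })
}
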