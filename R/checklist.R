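#' Summary verdict of the non-response checklist
#'
#' A cell's summary is `"Y"` (differential non-response likely biased the
#' estimated trend) exactly when step 1 flagged a differential change in
#' response *and* at least one of steps 2-4 flagged a concurrent change in
#' the outcome's variation, prevalence-difference, or associations. This
#' is the minimal rule consistent with the narrative logic of the
#' framework: association drift without differential response (step 4
#' alone) is attributed to other causes, not to non-response.
#'
#' Missing step results propagate: when the known flags cannot decide the
#' verdict, `NA` ("not assessable") is returned.
#'
#' @param step1,step2,step3,step4 Logical flags (vectorised).
#' @return Character vector of `"Y"`, `"N"` or `NA`.
#' @export
#' @examples
#' summary_verdict(TRUE, FALSE, FALSE, FALSE)  # "N"
#' summary_verdict(FALSE, FALSE, FALSE, TRUE)  # "N"
#' summary_verdict(TRUE, FALSE, TRUE, FALSE)   # "Y"
summary_verdict <- function(step1, step2, step3, step4) {
  any234 <- mapply(function(a, b, c) {
    v <- c(a, b, c)
    if (any(v %in% TRUE)) TRUE else if (anyNA(v)) NA else FALSE
  }, step2, step3, step4)
  verdict <- ifelse(step1 %in% FALSE, FALSE,
                    ifelse(is.na(step1) | is.na(any234), NA,
                           step1 & any234))
  ifelse(is.na(verdict), NA_character_, ifelse(verdict, "Y", "N"))
}

#' Assemble the non-response evaluation checklist
#'
#' Combines the four step flags into the checklist grid: one row per
#' outcome x subgroup dimension, with the step answers and the summary
#' verdict. The step-1 flag depends only on the dimension (it is computed
#' from the sampling frame, before outcomes enter); steps 2-4 are
#' outcome-specific. Combinations missing from a step's table become `NA`
#' ("not assessable"), never silently "N".
#'
#' @param step1_flags Tibble with columns `dimension`, `flagged` (and
#'   optionally provenance columns such as `p_value`).
#' @param step2_flags,step3_flags,step4_flags Tibbles with columns
#'   `outcome`, `dimension`, `flagged`.
#' @param outcomes,dimensions Grid to report on.
#' @return Tibble of class `nr_checklist`: outcome, dimension, step1-4
#'   (logical), summary (`"Y"`/`"N"`/`NA`).
#' @export
build_checklist <- function(step1_flags, step2_flags, step3_flags,
                            step4_flags,
                            outcomes = c("sport", "tv"),
                            dimensions = c("age", "sex", "ethnicity")) {
  grid <- tidyr::expand_grid(outcome = outcomes, dimension = dimensions)
  pick1 <- function(dim) {
    hit <- step1_flags$flagged[step1_flags$dimension == dim]
    if (length(hit) == 1) hit else NA
  }
  pick <- function(tbl, out, dim) {
    if (is.null(tbl) || nrow(tbl) == 0) return(NA)
    hit <- tbl$flagged[tbl$outcome == out & tbl$dimension == dim]
    if (length(hit) == 1) hit else NA
  }
  grid$step1 <- vapply(grid$dimension, pick1, logical(1))
  grid$step2 <- mapply(pick, list(step2_flags), grid$outcome,
                       grid$dimension)
  grid$step3 <- mapply(pick, list(step3_flags), grid$outcome,
                       grid$dimension)
  grid$step4 <- mapply(pick, list(step4_flags), grid$outcome,
                       grid$dimension)
  grid$summary <- summary_verdict(grid$step1, grid$step2, grid$step3,
                                  grid$step4)
  class(grid) <- c("nr_checklist", class(grid))
  grid
}

#' Run the full four-step diagnostic framework
#'
#' Executes steps 1-4 on a sampling frame, respondent outcome table and
#' population margins, and assembles the checklist:
#' 1. pooled and stratified response models plus time-interaction screens
#'    per dimension;
#' 2. per-wave SD series and variation-trend tests per dimension level;
#' 3. post-stratification weights, weighted/unweighted prevalence
#'    contrasts and difference-trend tests per dimension level;
#' 4. per-wave income-adjusted association models and OR-trend tests per
#'    term.
#'
#' A dimension collects several levels (step 2/3) or model terms (step 4),
#' so its checklist flag applies a Bonferroni-adjusted significance level
#' `significance_alpha / k` across its k trend tests together with the
#' magnitude gates, keeping the dimension-wise false-flag rate at the
#' nominal level; the per-level tables retain the unadjusted spec flags
#' for inspection. The step-4 gate additionally requires the fitted OR
#' change to exceed `config$or_change_threshold`.
#'
#' @param frame Validated sampling frame.
#' @param outcomes Outcome table.
#' @param margins Population margins table.
#' @param config An [analysis_config()].
#' @return List of class `nr_framework` with all step outputs and the
#'   `checklist`.
#' @export
run_framework <- function(frame, outcomes, margins,
                          config = analysis_config()) {
  dims <- c(age = "age_group", sex = "sex", ethnicity = "ethnicity")
  outcome_cols <- c(sport = "sport_weekly", tv = "tv_3h")
  raw_cols <- c(sport = "sport_times_per_year", tv = "tv_hours_per_day")

  # Step 1 -----------------------------------------------------------
  pooled <- fit_pooled_response_model(frame, config = config)
  interactions <- dplyr::bind_rows(lapply(unname(dims), function(v) {
    test_time_interactions(frame, v, config = config)
  }))
  step1_flags <- tibble::tibble(
    dimension = names(dims),
    flagged = interactions$flagged,
    statistic = interactions$statistic,
    p_value = interactions$p_value
  )
  stratified <- lapply(dims, function(v) {
    fit_stratified_time_trends(frame, v, config = config)
  })
  rates <- response_rate_table(frame)

  data <- join_respondents(frame, outcomes, config)
  weights <- poststrat_weights(frame, margins)

  available <- vapply(names(outcome_cols), function(o) {
    raw_cols[[o]] %in% names(data) && any(!is.na(data[[raw_cols[[o]]]]))
  }, logical(1))

  variation <- list(); variation_trends <- list()
  contrasts <- list(); contrast_trends <- list()
  association_fits <- list(); association_trends <- list()
  flags2 <- list(); flags3 <- list(); flags4 <- list()

  for (o in names(outcome_cols)[available]) {
    # Step 2 ---------------------------------------------------------
    for (d in names(dims)) {
      ser <- variation_by_wave(data, raw_cols[[o]], by = dims[[d]])
      tr <- test_variation_trend(ser, config)
      variation[[o]][[d]] <- ser
      variation_trends[[o]][[d]] <- tr
      flags2[[length(flags2) + 1]] <- tibble::tibble(
        outcome = o, dimension = d,
        flagged = any(
          tr$p_value < config$significance_alpha / nrow(tr) &
            abs(tr$rel_change_pct) > config$sd_change_threshold_pct
        )
      )
    }
    # Step 3 ---------------------------------------------------------
    for (d in names(dims)) {
      ser <- prevalence_contrast_series(frame, outcomes, margins,
                                        outcome = o, by = dims[[d]],
                                        weights = weights,
                                        config = config)
      tr <- test_difference_trend(ser, config)
      contrasts[[o]][[d]] <- ser
      contrast_trends[[o]][[d]] <- tr
      flags3[[length(flags3) + 1]] <- tibble::tibble(
        outcome = o, dimension = d,
        flagged = any(
          tr$p_value < config$significance_alpha / nrow(tr) &
            abs(tr$fitted_change_pts) >
              config$prevalence_change_threshold_pts
        )
      )
    }
    contrasts[[o]][["total"]] <- prevalence_contrast_series(
      frame, outcomes, margins, outcome = o, weights = weights,
      config = config
    )
    # Step 4 ---------------------------------------------------------
    fits <- fit_wave_association_models(data, outcome = o,
                                        config = config)
    association_fits[[o]] <- fits
    terms <- setdiff(unique(fits$term[fits$status == "ok"]),
                     "(Intercept)")
    trends <- dplyr::bind_rows(lapply(terms, function(tm) {
      or_time_trend(fits, tm, config = config)
    }))
    association_trends[[o]] <- trends
    for (d in names(dims)) {
      dim_terms <- trends[startsWith(trends$term, dims[[d]]), ,
                          drop = FALSE]
      hit <- nrow(dim_terms) > 0 &&
        any(dim_terms$p_value <
              config$significance_alpha / nrow(dim_terms) &
              abs(dim_terms$fitted_change_log_or) >
                log(config$or_change_threshold))
      flags4[[length(flags4) + 1]] <- tibble::tibble(
        outcome = o, dimension = d, flagged = hit
      )
    }
  }

  checklist <- build_checklist(
    step1_flags,
    dplyr::bind_rows(flags2), dplyr::bind_rows(flags3),
    dplyr::bind_rows(flags4),
    outcomes = names(outcome_cols), dimensions = names(dims)
  )

  structure(
    list(pooled_fit = pooled, interaction_tests = interactions,
         step1_flags = step1_flags, stratified_trends = stratified,
         response_rates = rates, weights = weights,
         variation = variation, variation_trends = variation_trends,
         contrasts = contrasts, contrast_trends = contrast_trends,
         association_fits = association_fits,
         association_trends = association_trends,
         checklist = checklist, config = config),
    class = "nr_framework"
  )
}

#' Render a deterministic plain-markdown report
#'
#' Produces a human-readable document containing the checklist grid, the
#' per-wave response rates, the step result tables and the thresholds in
#' force. Identical inputs produce byte-identical output.
#'
#' @param framework Output of [run_framework()].
#' @return Character vector of markdown lines.
#' @export
render_report <- function(framework) {
  cfg <- framework$config
  fmt_tbl <- function(df, digits = 4) {
    df <- as.data.frame(df)
    for (i in seq_along(df)) {
      if (is.numeric(df[[i]])) df[[i]] <- signif(df[[i]], digits)
    }
    body <- apply(df, 1, function(r) paste(r, collapse = " | "))
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      body, "")
  }
  yn <- function(x) ifelse(is.na(x), "not assessable",
                           ifelse(x %in% TRUE | x %in% "Y", "Y", "N"))
  chk <- framework$checklist
  chk_disp <- tibble::tibble(
    outcome = chk$outcome, dimension = chk$dimension,
    step1 = yn(chk$step1), step2 = yn(chk$step2), step3 = yn(chk$step3),
    step4 = yn(chk$step4), summary = yn(chk$summary)
  )
  lines <- c(
    "# Non-response over time: diagnostic report", "",
    "## Checklist", "",
    fmt_tbl(chk_disp),
    "## Thresholds in force", "",
    sprintf("- significance alpha: %g", cfg$significance_alpha),
    sprintf("- interaction alpha: %g", cfg$interaction_alpha),
    sprintf("- SD relative-change gate: %g%%", cfg$sd_change_threshold_pct),
    sprintf("- prevalence-difference change gate: %g points",
            cfg$prevalence_change_threshold_pts),
    sprintf("- OR change gate: factor %g", cfg$or_change_threshold), "",
    "## Response rates per wave", "",
    fmt_tbl(framework$response_rates),
    "## Step 1: pooled response model", "",
    fmt_tbl(framework$pooled_fit$coefficients),
    "## Step 1: time-interaction screens", "",
    fmt_tbl(framework$interaction_tests)
  )
  for (d in names(framework$stratified_trends)) {
    lines <- c(lines,
               sprintf("## Step 1: response trend stratified by %s", d),
               "", fmt_tbl(framework$stratified_trends[[d]]))
  }
  for (o in names(framework$variation_trends)) {
    for (d in names(framework$variation_trends[[o]])) {
      lines <- c(lines,
                 sprintf("## Step 2: variation trend, %s by %s", o, d),
                 "", fmt_tbl(framework$variation_trends[[o]][[d]]))
    }
  }
  for (o in names(framework$contrast_trends)) {
    for (d in names(framework$contrast_trends[[o]])) {
      lines <- c(lines,
                 sprintf(
                   "## Step 3: weighted-unweighted trend, %s by %s", o, d
                 ),
                 "", fmt_tbl(framework$contrast_trends[[o]][[d]]))
    }
  }
  for (o in names(framework$association_trends)) {
    lines <- c(lines,
               sprintf("## Step 4: OR trends, %s", o), "",
               fmt_tbl(framework$association_trends[[o]]))
  }
  lines
}
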