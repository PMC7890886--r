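#' Analysis configuration
#'
#' Bundles the tuning constants used by the four diagnostic steps and the
#' checklist. Defaults follow common practice for biennial health surveys:
#' two-sided tests at `significance_alpha = 0.05`, interaction screening at
#' the more liberal `interaction_alpha = 0.10`, sport participation
#' dichotomised at weekly (>= 46 times/year) and TV watching at >= 3 h/day.
#'
#' The trend flags of steps 2-4 combine statistical significance with a
#' practical-magnitude gate so that, on long series with large samples,
#' scientifically negligible drifts are not flagged:
#' * step 2 flags when the SD trend is significant *and* the first-to-last
#'   relative change exceeds `sd_change_threshold_pct` percent;
#' * step 3 flags when the weighted-minus-unweighted difference trend is
#'   significant *and* the fitted change exceeds
#'   `prevalence_change_threshold_pts` percentage points;
#' * the checklist's step-4 dimension flag requires a significant log-OR
#'   trend whose fitted change exceeds a factor `or_change_threshold`.
#'
#' @param time_unit_years Length in years of one wave-to-wave interval
#'   (default 2, biennial). Time enters all models as
#'   `(wave_year - first_wave_year) / time_unit_years`, so one unit is one
#'   interval and odds ratios are "per 2 years".
#' @param significance_alpha Two-sided significance level for main tests.
#' @param interaction_alpha Significance level for time-interaction screens.
#' @param sport_weekly_threshold Times/year at or above which sport
#'   participation counts as weekly.
#' @param tv_threshold Hours/day at or above which TV watching is flagged.
#' @param sd_change_threshold_pct Step-2 magnitude gate (percent relative
#'   change in SD, first to last observed wave).
#' @param prevalence_change_threshold_pts Step-3 magnitude gate
#'   (percentage points of fitted change in the weighted-minus-unweighted
#'   difference).
#' @param or_change_threshold Step-4 checklist magnitude gate
#'   (multiplicative change in OR over the fitted series). The default of
#'   1.5 asks for a substantively meaningful drift: at typical per-wave
#'   precisions the standard error of the fitted whole-series change in a
#'   log-OR is around 0.1, so a smaller gate would be regularly exceeded
#'   by chance whenever the slope also happens to reach significance.
#' @param age_breaks Lower bounds of the age bands (last band runs to
#'   `age_eligible[2]`).
#' @param age_eligible Inclusive eligibility range in years.
#' @param social_minimum,modal_income Reference household incomes used to
#'   band self-reported income (per survey year in real applications; single
#'   defaults here).
#' @return A list of class `nr_config`.
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$interaction_alpha
analysis_config <- function(time_unit_years = 2,
                            significance_alpha = 0.05,
                            interaction_alpha = 0.10,
                            sport_weekly_threshold = 46,
                            tv_threshold = 3,
                            sd_change_threshold_pct = 25,
                            prevalence_change_threshold_pts = 2,
                            or_change_threshold = 1.5,
                            age_breaks = c(16, 25, 45, 65),
                            age_eligible = c(15, 75),
                            social_minimum = 14000,
                            modal_income = 36500) {
  stopifnot(
    time_unit_years > 0,
    significance_alpha > 0, significance_alpha < 1,
    interaction_alpha > 0, interaction_alpha < 1,
    sport_weekly_threshold > 0, tv_threshold > 0,
    sd_change_threshold_pct > 0, prevalence_change_threshold_pts > 0,
    or_change_threshold > 1,
    length(age_eligible) == 2, age_eligible[1] < age_eligible[2],
    all(diff(age_breaks) > 0),
    social_minimum > 0, social_minimum < modal_income
  )
  structure(
    list(
      time_unit_years = time_unit_years,
      significance_alpha = significance_alpha,
      interaction_alpha = interaction_alpha,
      sport_weekly_threshold = sport_weekly_threshold,
      tv_threshold = tv_threshold,
      sd_change_threshold_pct = sd_change_threshold_pct,
      prevalence_change_threshold_pts = prevalence_change_threshold_pts,
      or_change_threshold = or_change_threshold,
      age_breaks = age_breaks,
      age_eligible = age_eligible,
      social_minimum = social_minimum,
      modal_income = modal_income
    ),
    class = "nr_config"
  )
}

#' Age-band labels implied by a set of breaks
#'
#' @param breaks Lower bounds of the bands.
#' @param eligible Inclusive eligibility range.
#' @return Character vector of band labels such as `"16-24"`.
#' @export
age_group_levels <- function(breaks = c(16, 25, 45, 65),
                             eligible = c(15, 75)) {
  upper <- c(breaks[-1] - 1, eligible[2])
  paste0(breaks, "-", upper)
}

#' Assign ages to age bands
#'
#' Bands are labelled by their printed ranges (default 16-24, 25-44, 45-64,
#' 65-75). Eligible ages below the first band's printed lower bound (age 15
#' under the defaults) are mapped into the first band; ages outside the
#' eligibility range return `NA` and are counted in the `"n_ineligible"`
#' attribute.
#'
#' @param age Integer ages in years.
#' @inheritParams age_group_levels
#' @return Factor of band labels with an `n_ineligible` attribute.
#' @export
#' @examples
#' derive_age_group(c(15, 24, 25, 64, 65, 75))
derive_age_group <- function(age, breaks = c(16, 25, 45, 65),
                             eligible = c(15, 75)) {
  labs <- age_group_levels(breaks, eligible)
  eligible_ok <- !is.na(age) & age >= eligible[1] & age <= eligible[2]
  idx <- findInterval(age, breaks)
  idx[idx == 0L] <- 1L # eligible ages below breaks[1] join the first band
  out <- factor(ifelse(eligible_ok, labs[idx], NA_character_), levels = labs)
  attr(out, "n_ineligible") <- sum(!eligible_ok & !is.na(age))
  out
}

#' Band household income against national reference incomes
#'
#' Bands: low = below the social minimum; mid-low = social minimum up to
#' (excluding) the modal income; mid-high = modal income up to and including
#' twice the modal income; high = strictly above twice the modal income.
#' The closure honours "high (> 2x modal)" literally while keeping the four
#' bands an exhaustive partition of the non-negative amounts.
#'
#' @param amount Household income amounts (same currency/period as the
#'   references). `NA` stays `NA`.
#' @param social_minimum,modal Reference incomes, `social_minimum < modal`.
#' @return Factor with levels `low`, `mid_low`, `mid_high`, `high`.
#' @export
#' @examples
#' classify_income(c(10000, 14000, 73000, 73001), 14000, 36500)
classify_income <- function(amount, social_minimum, modal) {
  stopifnot(social_minimum > 0, social_minimum < modal)
  if (any(amount < 0, na.rm = TRUE)) {
    stop("income amounts must be non-negative")
  }
  band <- dplyr::case_when(
    is.na(amount) ~ NA_character_,
    amount < social_minimum ~ "low",
    amount < modal ~ "mid_low",
    amount <= 2 * modal ~ "mid_high",
    TRUE ~ "high"
  )
  factor(band, levels = .income_levels)
}

#' Dichotomise sport-participation frequency
#'
#' Weekly participation means at least `threshold` (default 46) times/year.
#'
#' @param times_per_year Non-negative counts; `NA` stays `NA`.
#' @param threshold Times/year cut point.
#' @return Factor with levels `less_than_weekly`, `weekly`.
#' @export
dichotomize_sport <- function(times_per_year, threshold = 46) {
  if (any(times_per_year < 0, na.rm = TRUE)) {
    stop("sport frequency must be non-negative")
  }
  factor(ifelse(times_per_year >= threshold, "weekly", "less_than_weekly"),
         levels = c("less_than_weekly", "weekly"))
}

#' Dichotomise daily TV hours
#'
#' @param hours_per_day Non-negative hours; `NA` stays `NA`.
#' @param threshold Hours/day cut point (default 3).
#' @return Factor with levels `under_3h`, `3h_or_more`.
#' @export
dichotomize_tv <- function(hours_per_day, threshold = 3) {
  if (any(hours_per_day < 0, na.rm = TRUE)) {
    stop("TV hours must be non-negative")
  }
  factor(ifelse(hours_per_day >= threshold, "3h_or_more", "under_3h"),
         levels = c("under_3h", "3h_or_more"))
}

#' Derive modelling variables on a joined respondent table
#'
#' Adds logical indicators `sport_weekly` and `tv_3h` and the factor
#' `income_band` from the raw outcome columns, using the thresholds and
#' income references in `config`.
#'
#' @param data Tibble with columns `sport_times_per_year`,
#'   `tv_hours_per_day`, `household_income` (any may be absent).
#' @param config An [analysis_config()].
#' @return `data` with the derived columns appended.
#' @export
derive_analysis_vars <- function(data, config = analysis_config()) {
  if ("sport_times_per_year" %in% names(data)) {
    data$sport_weekly <-
      data$sport_times_per_year >= config$sport_weekly_threshold
  }
  if ("tv_hours_per_day" %in% names(data)) {
    data$tv_3h <- data$tv_hours_per_day >= config$tv_threshold
  }
  if ("household_income" %in% names(data)) {
    data$income_band <- classify_income(
      data$household_income, config$social_minimum, config$modal_income
    )
  }
  data
}

# Set canonical factor levels with the modelling reference level first
# (age 25-44, male, western, low income).
.with_refs <- function(df, config = analysis_config()) {
  labs <- age_group_levels(config$age_breaks, config$age_eligible)
  ref_age <- if ("25-44" %in% labs) "25-44" else labs[1]
  if ("age_group" %in% names(df)) {
    df$age_group <- stats::relevel(factor(df$age_group, levels = labs),
                                   ref = ref_age)
  }
  if ("sex" %in% names(df)) {
    df$sex <- factor(df$sex, levels = .sex_levels)
  }
  if ("ethnicity" %in% names(df)) {
    df$ethnicity <- factor(df$ethnicity, levels = .ethnicity_levels)
  }
  if ("district" %in% names(df)) {
    df$district <- factor(df$district)
  }
  if ("income_band" %in% names(df)) {
    df$income_band <- factor(df$income_band, levels = .income_levels)
  }
  df
}

# Wave index in intervals since the first wave.
.time_index <- function(wave_year, first_wave = min(wave_year),
                        time_unit_years = 2) {
  (wave_year - first_wave) / time_unit_years
}
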