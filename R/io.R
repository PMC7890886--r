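#' Load a sampling frame from CSV
#'
#' The sampling frame holds one record per invited person per wave, for
#' respondents and non-respondents alike (as obtained from, e.g., a
#' municipal registry). Required columns: `person_id`, `wave_year`, `age`,
#' `sex` (`male`/`female`), `ethnicity` (`western`/`non_western`),
#' `district`, `responded` (logical or 0/1).
#'
#' Rows with a missing demographic (age, sex, ethnicity, district) are
#' dropped (complete-case) and counted in the `drop_log` attribute, as are
#' rows whose age lies outside the eligibility range. The age band factor
#' `age_group` is derived on load.
#'
#' @param path CSV file path.
#' @param config An [analysis_config()].
#' @return Tibble of validated invitee records with attribute `drop_log`
#'   (named counts `missing_demographics`, `ineligible_age`).
#' @export
load_frame <- function(path, config = analysis_config()) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE)
  validate_frame(raw, config)
}

#' Validate an in-memory sampling frame
#'
#' @param raw Data frame with the columns documented in [load_frame()].
#' @inheritParams load_frame
#' @return See [load_frame()].
#' @export
validate_frame <- function(raw, config = analysis_config()) {
  required <- c("person_id", "wave_year", "age", "sex", "ethnicity",
                "district", "responded")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("sampling frame is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  .check_vocab(raw$sex, .sex_levels, "sex")
  .check_vocab(raw$ethnicity, .ethnicity_levels, "ethnicity")
  if (is.numeric(raw$responded)) {
    bad <- setdiff(unique(raw$responded[!is.na(raw$responded)]), c(0, 1))
    if (length(bad) > 0) {
      stop("responded must be logical or 0/1; found: ",
           paste(bad, collapse = ", "))
    }
    raw$responded <- raw$responded == 1
  }
  if (!is.logical(raw$responded)) {
    stop("responded must be logical or 0/1")
  }
  if (anyDuplicated(raw$person_id)) {
    stop("person_id must be unique across the frame")
  }

  demo <- c("age", "sex", "ethnicity", "district", "responded")
  complete <- complete.cases(raw[demo])
  n_missing <- sum(!complete)
  frame <- raw[complete, , drop = FALSE]

  ag <- derive_age_group(frame$age, config$age_breaks, config$age_eligible)
  n_inelig <- attr(ag, "n_ineligible")
  frame$age_group <- ag
  frame <- frame[!is.na(frame$age_group), , drop = FALSE]
  frame <- .with_refs(tibble::as_tibble(frame), config)
  attr(frame, "drop_log") <- c(missing_demographics = n_missing,
                               ineligible_age = n_inelig)
  frame
}

.check_vocab <- function(x, vocab, what) {
  bad <- setdiff(unique(x[!is.na(x)]), vocab)
  if (length(bad) > 0) {
    stop(sprintf("unknown %s value(s): %s (expected %s)",
                 what, paste(bad, collapse = ", "),
                 paste(vocab, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Load a respondent outcome table from CSV
#'
#' Required columns: `person_id` plus any of `sport_times_per_year`,
#' `tv_hours_per_day`, `household_income`. When a frame is supplied the
#' referential-integrity contract is checked: every outcome row must match
#' exactly one frame record with `responded = TRUE`.
#'
#' @param path CSV file path.
#' @param frame Optional validated sampling frame to check against.
#' @return Tibble of outcome records.
#' @export
load_outcomes <- function(path, frame = NULL) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"person_id" %in% names(out)) {
    stop("outcome table is missing required column: person_id")
  }
  known <- c("sport_times_per_year", "tv_hours_per_day", "household_income")
  if (!any(known %in% names(out))) {
    stop("outcome table has none of the outcome columns: ",
         paste(known, collapse = ", "))
  }
  if (anyDuplicated(out$person_id)) {
    stop("person_id must be unique in the outcome table")
  }
  if (!is.null(frame)) {
    responders <- frame$person_id[frame$responded]
    orphans <- setdiff(out$person_id, responders)
    if (length(orphans) > 0) {
      stop("outcome rows without a responding frame record, e.g.: ",
           paste(head(orphans, 5), collapse = ", "))
    }
  }
  tibble::as_tibble(out)
}

#' Load population margins from CSV
#'
#' One row per wave and weighting cell (`age_group`, `sex`, `ethnicity`,
#' `district`) with a non-negative `population_count`.
#'
#' @param path CSV file path.
#' @param config An [analysis_config()].
#' @return Tibble of population margins.
#' @export
load_margins <- function(path, config = analysis_config()) {
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("wave_year", "age_group", "sex", "ethnicity", "district",
                "population_count")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0) {
    stop("margins table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  .check_vocab(m$sex, .sex_levels, "sex")
  .check_vocab(m$ethnicity, .ethnicity_levels, "ethnicity")
  .check_vocab(m$age_group,
               age_group_levels(config$age_breaks, config$age_eligible),
               "age_group")
  if (any(m$population_count < 0, na.rm = TRUE)) {
    stop("population_count must be non-negative")
  }
  .with_refs(tibble::as_tibble(m), config)
}

#' Join respondents to their outcomes
#'
#' Inner-joins the responding frame records to the outcome table by
#' `person_id` and derives the modelling variables (see
#' [derive_analysis_vars()]).
#'
#' @param frame Validated sampling frame.
#' @param outcomes Outcome table.
#' @param config An [analysis_config()].
#' @return Tibble of respondent records with demographics and outcomes.
#' @export
join_respondents <- function(frame, outcomes, config = analysis_config()) {
  responders <- dplyr::filter(frame, .data$responded)
  orphans <- setdiff(outcomes$person_id, responders$person_id)
  if (length(orphans) > 0) {
    stop("outcome rows without a responding frame record, e.g.: ",
         paste(head(orphans, 5), collapse = ", "))
  }
  joined <- dplyr::inner_join(responders, outcomes, by = "person_id")
  derive_analysis_vars(joined, config)
}
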