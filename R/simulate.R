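#' Response-propensity model for the survey simulator
#'
#' Specifies, on the log-odds scale, how the probability of responding to
#' an invitation depends on demographics, calendar time, and (optionally)
#' the invitee's own outcome values. Defaults emulate a long-running
#' biennial municipal survey: response is higher among older people, women
#' and people with a western background; it declines every interval, and
#' the decline is faster for the young and for the non-western group.
#'
#' @param first_wave_response Overall response proportion targeted in the
#'   first wave; the reference-cell intercept is solved from it and the
#'   demographic mix at design construction (ignored when `intercept` is
#'   given).
#' @param intercept Optional reference-cell log-odds of responding in the
#'   first wave (reference: age 25-44, male, western, first district).
#' @param or Named list of odds ratios for the demographic main effects;
#'   each element is a named vector over non-reference levels of
#'   `age_group`, `sex`, `ethnicity` or `district`.
#' @param time_or Odds ratio per interval for the reference cell's response
#'   trend.
#' @param time_or_modifiers Named list of multiplicative modifiers of the
#'   trend OR for non-reference levels (a modifier of 0.97 for
#'   `non_western` means that group's per-interval trend OR is
#'   `time_or * 0.97`). These are the time-by-subgroup interactions.
#' @param mnar Named list (by outcome) of outcome-dependent selection
#'   schedules built with [mnar_schedule()]. Empty list = missing at
#'   random given the demographic cells.
#' @return List of class `nr_response_model`.
#' @export
response_model <- function(first_wave_response = 0.47,
                           intercept = NULL,
                           or = list(
                             age_group = c("16-24" = 1.01, "45-64" = 1.29,
                                           "65-75" = 1.54),
                             sex = c(female = 1.29),
                             ethnicity = c(non_western = 0.51)
                           ),
                           time_or = 0.91,
                           time_or_modifiers = list(
                             age_group = c("16-24" = 0.90 / 0.91,
                                           "45-64" = 0.93 / 0.91,
                                           "65-75" = 0.96 / 0.91),
                             ethnicity = c(non_western = 0.97)
                           ),
                           mnar = list()) {
  stopifnot(time_or > 0,
            is.null(intercept) || is.finite(intercept),
            first_wave_response > 0, first_wave_response < 1)
  structure(
    list(first_wave_response = first_wave_response,
         intercept = intercept,
         main = lapply(or, log),
         time = log(time_or),
         time_mod = lapply(time_or_modifiers, log),
         mnar = mnar),
    class = "nr_response_model"
  )
}

#' Outcome-dependent (MNAR) selection schedule
#'
#' The named outcome's dichotomised indicator enters the response log-odds
#' with a coefficient that moves linearly from `start` (first wave) to
#' `end` (last wave), optionally only within one demographic subgroup.
#' A nonzero schedule makes response depend on the outcome itself, the
#' selection mechanism that post-stratification weighting cannot repair.
#'
#' @param start,end Log-odds coefficients at the first and last wave.
#' @param on Optional named character, e.g. `c(ethnicity = "non_western")`,
#'   restricting the mechanism to one subgroup.
#' @return List of class `nr_mnar`.
#' @export
mnar_schedule <- function(start = 0, end = 0, on = NULL) {
  stopifnot(is.finite(start), is.finite(end))
  structure(list(start = start, end = end, on = on), class = "nr_mnar")
}

#' Outcome-generating model for the survey simulator
#'
#' @param family `"nbinom"` for over-dispersed counts (sport times/year),
#'   `"gamma"` for non-negative continuous values (TV hours/day), or
#'   `"bernoulli"` for a directly specified binary outcome.
#' @param ref_mean Mean for the reference cell (a probability for
#'   `"bernoulli"`).
#' @param effects Named list of additive log-mean effects (log-odds for
#'   `"bernoulli"`) per non-reference level of a demographic variable.
#' @param time_log Additive change in the log mean per interval (0 =
#'   wave-constant outcome model).
#' @param dispersion `size` for `"nbinom"`, `shape` for `"gamma"`
#'   (ignored for `"bernoulli"`).
#' @param threshold Dichotomisation cut: the binary indicator is
#'   `value >= threshold`.
#' @return List of class `nr_outcome_model`.
#' @export
outcome_model <- function(family = c("nbinom", "gamma", "bernoulli"),
                          ref_mean, effects = list(), time_log = 0,
                          dispersion = 1, threshold = 1) {
  family <- match.arg(family)
  stopifnot(ref_mean > 0, is.finite(time_log), dispersion > 0,
            threshold > 0)
  if (family == "bernoulli") stopifnot(ref_mean < 1)
  structure(
    list(family = family, ref_mean = ref_mean, effects = effects,
         time_log = time_log, dispersion = dispersion,
         threshold = threshold),
    class = "nr_outcome_model"
  )
}

.default_outcome_models <- function() {
  list(
    # Sport: mean well under the weekly cut with SD ~ 73 times/year.
    sport = outcome_model(
      family = "nbinom", ref_mean = 35,
      effects = list(
        age_group = c("16-24" = 0.25, "45-64" = -0.30, "65-75" = -0.55),
        sex = c(female = -0.15),
        ethnicity = c(non_western = -0.35)
      ),
      dispersion = 0.23, threshold = 46
    ),
    # TV: right-skewed hours/day around 2.5 with SD ~ 1.9. Subgroup
    # effects kept moderate so weighted-minus-unweighted prevalence
    # differences stay within the ~1-point band typical of surveys whose
    # weighting corrects little.
    tv = outcome_model(
      family = "gamma", ref_mean = 2.5,
      effects = list(
        age_group = c("16-24" = -0.05, "45-64" = 0.10, "65-75" = 0.16),
        ethnicity = c(non_western = 0.10)
      ),
      dispersion = 1.8, threshold = 3
    )
  )
}

#' Default demographic cell mix
#'
#' Cell probabilities over age group x sex x ethnicity x district for a
#' synthetic city of two districts in which the second district has a
#' smaller non-western population share.
#'
#' @param config An [analysis_config()].
#' @return Tibble with the four cell variables and a `prob` column
#'   summing to 1.
#' @export
default_demographic_mix <- function(config = analysis_config()) {
  labs <- age_group_levels(config$age_breaks, config$age_eligible)
  p_age <- setNames(c(0.16, 0.38, 0.30, 0.16), labs)
  nw_by_district <- c(d1 = 0.45, d2 = 0.25)
  cells <- tidyr::expand_grid(
    age_group = labs, sex = .sex_levels,
    ethnicity = .ethnicity_levels, district = names(nw_by_district)
  )
  p_eth <- ifelse(cells$ethnicity == "non_western",
                  nw_by_district[cells$district],
                  1 - nw_by_district[cells$district])
  cells$prob <- p_age[cells$age_group] * 0.5 * p_eth * 0.5
  cells
}

#' Define a synthetic multi-wave survey
#'
#' Bundles everything needed to generate a repeated cross-sectional survey
#' with known ground truth: the wave calendar, invitation volume, the
#' population's demographic cell mix, the response-propensity model, the
#' outcome-generating models, household-income generation, oversampling of
#' selected subgroups from a given wave onward, and the availability
#' windows of each outcome.
#'
#' Defaults emulate the study conditions of a 12-wave biennial survey
#' (1995-2017): first-wave response 47%, per-interval response trend ORs
#' 0.90-0.96 by age and 0.97 modifier for the non-western group, sport
#' asked from 1999, TV until 2015, and doubling of non-western invitation
#' rates from 2005.
#'
#' @param waves Wave calendar years (equally spaced).
#' @param invitations_per_wave Number of invitations sent each wave.
#' @param population_size Population behind the margins table.
#' @param demographic_mix Cell probability table
#'   ([default_demographic_mix()]).
#' @param response Model from [response_model()].
#' @param outcomes Named list of [outcome_model()]s.
#' @param oversampling List with `from_wave` and named multiplier vectors
#'   per demographic variable (all multipliers >= 1); invitation
#'   probabilities of matching cells are inflated from `from_wave` onward.
#'   `NULL` disables oversampling.
#' @param income List with `meanlog_ref`, per-variable `effects` on the
#'   log scale, `sdlog`, and `missing_rate`.
#' @param sport_waves,tv_waves Wave years in which each outcome was
#'   collected.
#' @param config An [analysis_config()].
#' @return List of class `nr_design` with a resolved intercept.
#' @export
simulation_design <- function(waves = seq(1995, 2017, by = 2),
                              invitations_per_wave = 11400,
                              population_size = 620000,
                              demographic_mix = default_demographic_mix(config),
                              response = response_model(),
                              outcomes = .default_outcome_models(),
                              oversampling = list(
                                from_wave = 2005,
                                ethnicity = c(non_western = 1.5)
                              ),
                              income = list(
                                meanlog_ref = log(38000),
                                effects = list(
                                  age_group = c("16-24" = -0.45,
                                                "65-75" = -0.15),
                                  ethnicity = c(non_western = -0.30)
                                ),
                                sdlog = 0.55,
                                missing_rate = 0
                              ),
                              sport_waves = waves[waves >= 1999],
                              tv_waves = waves[waves <= 2015],
                              config = analysis_config()) {
  stopifnot(length(waves) >= 1, !is.unsorted(waves),
            invitations_per_wave >= 1, population_size >= 1)
  tot <- sum(demographic_mix$prob)
  stopifnot(all(demographic_mix$prob >= 0), tot > 0)
  demographic_mix$prob <- demographic_mix$prob / tot
  if (!is.null(oversampling)) {
    mult <- unlist(oversampling[setdiff(names(oversampling), "from_wave")])
    if (length(mult) > 0 && any(mult < 1)) {
      stop("oversampling multipliers must be >= 1")
    }
  }
  zero_cells <- demographic_mix$prob == 0
  if (any(zero_cells) && length(response$time_mod) > 0) {
    warning("demographic mix contains empty cells; ",
            "time interactions on them are unidentifiable")
  }

  design <- structure(
    list(waves = waves, invitations_per_wave = invitations_per_wave,
         population_size = population_size,
         demographic_mix = demographic_mix,
         response = response, outcomes = outcomes,
         oversampling = oversampling, income = income,
         outcome_waves = list(sport = sport_waves, tv = tv_waves),
         config = config),
    class = "nr_design"
  )
  if (is.null(design$response$intercept)) {
    design$response$intercept <- .solve_intercept(design)
  }
  design
}

# Reference-cell intercept giving the targeted overall first-wave response.
.solve_intercept <- function(design) {
  offs <- .cell_effects(design$demographic_mix, design$response$main)
  target <- design$response$first_wave_response
  f <- function(b0) {
    sum(design$demographic_mix$prob * plogis(b0 + offs)) - target
  }
  uniroot(f, c(-20, 20), tol = 1e-12)$root
}

# Sum named per-level effects over the rows of a cell table.
.cell_effects <- function(cells, effects) {
  out <- rep(0, nrow(cells))
  for (var in names(effects)) {
    eff <- effects[[var]]
    hit <- match(as.character(cells[[var]]), names(eff))
    out <- out + ifelse(is.na(hit), 0, eff[hit])
  }
  out
}

# Per-cell response trend (log-OR per interval).
.cell_time_log <- function(cells, response) {
  response$time + .cell_effects(cells, response$time_mod)
}

# MNAR coefficient of an outcome at wave position i (1-based) of n waves.
.mnar_coef <- function(sched, i, n_waves) {
  if (n_waves == 1) return(sched$start)
  sched$start + (sched$end - sched$start) * (i - 1) / (n_waves - 1)
}

.mnar_applies <- function(sched, cells) {
  if (is.null(sched$on)) return(rep(TRUE, nrow(cells)))
  ok <- rep(TRUE, nrow(cells))
  for (var in names(sched$on)) {
    ok <- ok & as.character(cells[[var]]) == sched$on[[var]]
  }
  ok
}

# Cell mean of an outcome model at wave index t.
.outcome_mean <- function(model, cells, t) {
  if (model$family == "bernoulli") {
    plogis(qlogis(model$ref_mean) + .cell_effects(cells, model$effects) +
             model$time_log * t)
  } else {
    exp(log(model$ref_mean) + .cell_effects(cells, model$effects) +
          model$time_log * t)
  }
}

# P(value >= threshold) per cell, analytically.
.outcome_tail_prob <- function(model, cells, t) {
  mu <- .outcome_mean(model, cells, t)
  switch(model$family,
    nbinom = pnbinom(model$threshold - 1, size = model$dispersion, mu = mu,
                     lower.tail = FALSE),
    gamma = pgamma(model$threshold, shape = model$dispersion,
                   rate = model$dispersion / mu, lower.tail = FALSE),
    bernoulli = if (model$threshold <= 1) mu else rep(0, length(mu))
  )
}

.draw_outcome <- function(model, mu) {
  n <- length(mu)
  switch(model$family,
    nbinom = rnbinom(n, size = model$dispersion, mu = mu),
    gamma = rgamma(n, shape = model$dispersion,
                   rate = model$dispersion / mu),
    bernoulli = rbinom(n, 1, mu)
  )
}

#' Analytic population prevalence of the dichotomised outcomes
#'
#' The exact mixture prevalence over the demographic cells,
#' `sum_cells p(cell) * P(outcome >= threshold | cell, wave)`, independent
#' of the response model and of oversampling.
#'
#' @param design An [simulation_design()].
#' @param wave Wave year (must be in `design$waves`).
#' @return Named numeric of prevalences (proportions) per outcome.
#' @export
#' @examples
#' d <- simulation_design()
#' population_prevalence(d, 1999)
population_prevalence <- function(design, wave) {
  stopifnot(inherits(design, "nr_design"), wave %in% design$waves)
  t <- .time_index(wave, design$waves[1], .wave_unit(design))
  vapply(design$outcomes, function(m) {
    sum(design$demographic_mix$prob *
          .outcome_tail_prob(m, design$demographic_mix, t))
  }, numeric(1))
}

.wave_unit <- function(design) {
  if (length(design$waves) > 1) diff(design$waves)[1] else
    design$config$time_unit_years
}

#' Generate a synthetic multi-wave survey
#'
#' Draws invitees from the (possibly oversampled) invitation mix, generates
#' outcome values for *all* invitees from the outcome models so the ground
#' truth is known, draws response from the response-propensity model (which
#' may depend on those latent outcomes under MNAR schedules), and emits
#' outcomes only for responders. The margins table reflects the simulated
#' population, never the oversampled invitation mix. Identical
#' `(design, seed)` produce identical tables.
#'
#' @param design An [simulation_design()].
#' @param seed Integer seed; per-wave substreams are derived from it.
#' @return List of class `nr_survey` with elements `frame`, `outcomes`,
#'   `margins` and `truth` (generating coefficients, analytic population
#'   prevalence per wave, and a `bias_label` flag per outcome that is TRUE
#'   iff its MNAR schedule is nonzero).
#' @export
simulate_survey <- function(design, seed = 1L) {
  stopifnot(inherits(design, "nr_design"))
  cells <- design$demographic_mix
  n_waves <- length(design$waves)
  unit <- .wave_unit(design)
  resp <- design$response
  cell_main <- resp$intercept + .cell_effects(cells, resp$main)
  cell_tlog <- .cell_time_log(cells, resp)
  age_rng <- .age_band_ranges(design$config)

  set.seed(seed)
  wave_seeds <- sample.int(.Machine$integer.max - 1L, n_waves)

  frames <- vector("list", n_waves)
  outs <- vector("list", n_waves)
  for (i in seq_len(n_waves)) {
    set.seed(wave_seeds[i])
    wave <- design$waves[i]
    t <- .time_index(wave, design$waves[1], unit)

    inv_prob <- cells$prob * .invite_multiplier(cells, design$oversampling,
                                                wave)
    inv_prob <- inv_prob / sum(inv_prob)
    counts <- as.vector(rmultinom(1, design$invitations_per_wave, inv_prob))
    idx <- rep.int(seq_len(nrow(cells)), counts)
    n <- length(idx)

    band <- as.character(cells$age_group[idx])
    age <- .sample_ages(band, age_rng)

    # latent outcomes for every invitee
    values <- lapply(design$outcomes, function(m) {
      .draw_outcome(m, .outcome_mean(m, cells[idx, ], t))
    })
    indicators <- lapply(names(design$outcomes), function(o) {
      values[[o]] >= design$outcomes[[o]]$threshold
    })
    names(indicators) <- names(design$outcomes)

    lp <- cell_main[idx] + cell_tlog[idx] * t
    for (o in names(resp$mnar)) {
      sched <- resp$mnar[[o]]
      coef_t <- .mnar_coef(sched, i, n_waves)
      if (coef_t != 0) {
        lp <- lp + coef_t * indicators[[o]] * .mnar_applies(sched, cells)[idx]
      }
    }
    responded <- rbinom(n, 1, plogis(lp)) == 1

    inc <- design$income
    income <- rlnorm(n, meanlog = inc$meanlog_ref +
                       .cell_effects(cells[idx, ], inc$effects),
                     sdlog = inc$sdlog)
    if (inc$missing_rate > 0) {
      income[rbinom(n, 1, inc$missing_rate) == 1] <- NA_real_
    }

    frames[[i]] <- tibble::tibble(
      person_id = sprintf("w%d-%06d", wave, seq_len(n)),
      wave_year = wave,
      age = age,
      sex = as.character(cells$sex[idx]),
      ethnicity = as.character(cells$ethnicity[idx]),
      district = as.character(cells$district[idx]),
      responded = responded
    )
    emit <- function(o) {
      v <- values[[o]]
      ow <- design$outcome_waves[[o]]
      if (!is.null(ow) && !wave %in% ow) v[] <- NA
      v[responded]
    }
    outs[[i]] <- tibble::tibble(
      person_id = frames[[i]]$person_id[responded],
      sport_times_per_year = if ("sport" %in% names(values)) emit("sport"),
      tv_hours_per_day = if ("tv" %in% names(values)) emit("tv"),
      household_income = income[responded]
    )
  }

  frame <- validate_frame(dplyr::bind_rows(frames), design$config)
  outcomes <- dplyr::bind_rows(outs)

  margins <- tidyr::expand_grid(wave_year = design$waves,
                                dplyr::select(cells, -"prob"))
  margins$population_count <- rep(
    round(design$population_size * cells$prob), times = n_waves
  )
  margins <- .with_refs(margins, design$config)

  prev <- do.call(rbind, lapply(design$waves, function(w) {
    p <- population_prevalence(design, w)
    tibble::tibble(wave_year = w, outcome = names(p), prevalence = unname(p))
  }))
  bias_label <- vapply(names(design$outcomes), function(o) {
    sched <- resp$mnar[[o]]
    !is.null(sched) && (sched$start != 0 || sched$end != 0)
  }, logical(1))

  structure(
    list(frame = frame, outcomes = outcomes, margins = margins,
         truth = list(response = resp,
                      population_prevalence = tibble::as_tibble(prev),
                      bias_label = bias_label),
         design = design),
    class = "nr_survey"
  )
}

.invite_multiplier <- function(cells, oversampling, wave) {
  mult <- rep(1, nrow(cells))
  if (is.null(oversampling) || wave < oversampling$from_wave) return(mult)
  for (var in setdiff(names(oversampling), "from_wave")) {
    m <- oversampling[[var]]
    hit <- match(as.character(cells[[var]]), names(m))
    mult <- mult * ifelse(is.na(hit), 1, m[hit])
  }
  mult
}

.age_band_ranges <- function(config) {
  labs <- age_group_levels(config$age_breaks, config$age_eligible)
  lo <- c(config$age_eligible[1], config$age_breaks[-1])
  hi <- c(config$age_breaks[-1] - 1, config$age_eligible[2])
  setNames(Map(seq, lo, hi), labs)
}

.sample_ages <- function(band, ranges) {
  age <- integer(length(band))
  for (b in unique(band)) {
    sel <- band == b
    rng <- ranges[[b]]
    age[sel] <- rng[sample.int(length(rng), sum(sel), replace = TRUE)]
  }
  age
}

#' Null simulation design
#'
#' Flat response probability in every cell and wave (no time trend, no
#' subgroup effects, no MNAR, no oversampling); outcomes keep their
#' defaults. Used to check type-I behaviour of the diagnostics.
#'
#' @param response_rate Constant response probability.
#' @param ... Passed on to [simulation_design()].
#' @return An `nr_design`.
#' @export
design_null <- function(response_rate = 0.5, ...) {
  simulation_design(
    response = response_model(
      intercept = qlogis(response_rate),
      or = list(), time_or = 1, time_or_modifiers = list()
    ),
    oversampling = NULL, ...
  )
}

#' Escalating outcome-dependent selection design
#'
#' The default survey design plus a response mechanism that becomes
#' increasingly dependent on weekly sport participation within the
#' non-western group: the selection coefficient ramps linearly from 0 in
#' the first wave to `end` log-odds in the last. This is the recorded
#' scenario in which the framework should raise its summary flag.
#'
#' @param end Final-wave selection coefficient on the log-odds scale
#'   (negative = weekly-sport invitees increasingly under-respond).
#' @param ... Passed on to [simulation_design()].
#' @return An `nr_design`.
#' @export
design_mnar_escalating <- function(end = -2.5, ...) {
  simulation_design(
    response = response_model(
      mnar = list(sport = mnar_schedule(start = 0, end = end,
                                        on = c(ethnicity = "non_western")))
    ),
    ...
  )
}
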