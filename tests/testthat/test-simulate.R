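test_that("identical design and seed give identical tables", {
  d <- tiny_design()
  a <- simulate_survey(d, seed = 11)
  b <- simulate_survey(d, seed = 11)
  expect_identical(a$frame, b$frame)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$margins, b$margins)
  c <- simulate_survey(d, seed = 12)
  expect_false(identical(a$frame$responded, c$frame$responded))
})

test_that("null design keeps response flat at its intercept", {
  sim <- simulate_survey(design_null(0.5, invitations_per_wave = 4000),
                         seed = 5)
  rates <- response_rate_table(sim$frame)
  # binomial 99.9% band around 50% at n = 4000 per wave
  half_width <- 100 * qnorm(0.9995) * sqrt(0.25 / 4000)
  expect_true(all(abs(rates$rate_pct - 50) < half_width))
  fit <- fit_pooled_response_model(sim$frame, covariates = character(0))
  tr <- fit$coefficients[fit$coefficients$term == "time_index", ]
  expect_true(tr$ci_low < 1 && tr$ci_high > 1)
})

test_that("population prevalence is the exact cell mixture", {
  one_cell <- default_demographic_mix()[1, ]
  one_cell$prob <- 1
  d1 <- simulation_design(
    demographic_mix = one_cell,
    outcomes = list(sport = outcome_model("bernoulli", ref_mean = 0.3)),
    oversampling = NULL
  )
  expect_equal(unname(population_prevalence(d1, 1995)["sport"]), 0.3)

  two_cells <- tibble::tibble(
    age_group = "25-44", sex = c("male", "female"),
    ethnicity = "western", district = "d1", prob = c(0.5, 0.5)
  )
  d2 <- simulation_design(
    demographic_mix = two_cells,
    outcomes = list(sport = outcome_model(
      "bernoulli", ref_mean = 0.2,
      effects = list(sex = c(female = qlogis(0.4) - qlogis(0.2)))
    )),
    oversampling = NULL
  )
  expect_equal(unname(population_prevalence(d2, 1995)["sport"]), 0.3)
})

test_that("analytic prevalence matches brute-force simulation", {
  # everyone responds, one wave: respondents are the population
  d <- simulation_design(
    waves = 1999, invitations_per_wave = 2e5,
    response = response_model(intercept = 30, or = list(), time_or = 1,
                              time_or_modifiers = list()),
    oversampling = NULL, sport_waves = 1999, tv_waves = 1999
  )
  sim <- simulate_survey(d, seed = 21)
  data <- join_respondents(sim$frame, sim$outcomes)
  truth <- population_prevalence(d, 1999)
  for (o in c("sport", "tv")) {
    col <- c(sport = "sport_weekly", tv = "tv_3h")[[o]]
    obs <- mean(data[[col]])
    mc_se <- sqrt(truth[[o]] * (1 - truth[[o]]) / nrow(data))
    expect_lt(abs(obs - truth[[o]]), 3 * mc_se)
  }
})

test_that("under MAR, responder outcomes keep the generating law per cell", {
  d <- simulation_design(waves = c(1999, 2001),
                         invitations_per_wave = 6e4)
  sim <- simulate_survey(d, seed = 8)
  data <- join_respondents(sim$frame, sim$outcomes)
  cell <- data[data$age_group == "25-44" & data$sex == "male" &
                 data$ethnicity == "western" & data$wave_year == 1999, ]
  m <- d$outcomes$sport$ref_mean
  size <- d$outcomes$sport$dispersion
  sd_th <- sqrt(m + m^2 / size)
  expect_lt(abs(mean(cell$sport_times_per_year) - m),
            3 * sd_th / sqrt(nrow(cell)))
})

test_that("oversampling shifts invitations but not response propensity", {
  base <- tiny_design(oversampling = NULL, invitations_per_wave = 20000)
  over <- tiny_design(
    oversampling = list(from_wave = 2001, ethnicity = c(non_western = 3)),
    invitations_per_wave = 20000
  )
  sb <- simulate_survey(base, seed = 14)$frame
  so <- simulate_survey(over, seed = 15)$frame
  nw <- function(f, w) f[f$wave_year == w & f$ethnicity == "non_western", ]
  # invitation mix changes from the activation wave onward ...
  expect_gt(nrow(nw(so, 2005)) / sum(so$wave_year == 2005),
            nrow(nw(sb, 2005)) / sum(sb$wave_year == 2005) + 0.15)
  # ... but the response probability of a non-western invitee does not
  r_over <- mean(nw(so, 2005)$responded)
  r_base <- mean(nw(sb, 2005)$responded)
  se <- sqrt(r_base * (1 - r_base) *
               (1 / nrow(nw(so, 2005)) + 1 / nrow(nw(sb, 2005))))
  expect_lt(abs(r_over - r_base), 4 * se)
})

test_that("outcome tables contain responders only and respect availability", {
  sim <- simulate_survey(tiny_design(), seed = 2)
  responders <- sim$frame$person_id[sim$frame$responded]
  expect_true(all(sim$outcomes$person_id %in% responders))
  expect_equal(nrow(sim$outcomes), length(responders))
  joined <- join_respondents(sim$frame, sim$outcomes)
  # sport not asked in 1995/1997; TV asked throughout the tiny calendar
  expect_true(all(is.na(
    joined$sport_times_per_year[joined$wave_year < 1999]
  )))
  expect_false(anyNA(joined$tv_hours_per_day))
})

test_that("margins reflect the population mix, not the invitation mix", {
  over <- tiny_design(
    oversampling = list(from_wave = 1995, ethnicity = c(non_western = 4))
  )
  sim <- simulate_survey(over, seed = 9)
  m <- sim$margins[sim$margins$wave_year == 1995, ]
  nw_pop <- sum(m$population_count[m$ethnicity == "non_western"]) /
    sum(m$population_count)
  mix <- over$demographic_mix
  nw_true <- sum(mix$prob[mix$ethnicity == "non_western"])
  expect_lt(abs(nw_pop - nw_true), 1e-4)
  f <- sim$frame[sim$frame$wave_year == 1995, ]
  expect_gt(mean(f$ethnicity == "non_western"), nw_true + 0.15)
})
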