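test_that("saturated two-wave fit reproduces the closed-form odds ratio", {
  frame <- frame_two_waves(n_per_wave = 1000, responders = c(470, 320))
  fit <- fit_pooled_response_model(frame, covariates = character(0))
  or_hat <- fit$coefficients$or[fit$coefficients$term == "time_index"]
  oracle <- (320 / 680) / (470 / 530) # cross-product ratio
  expect_lt(abs(or_hat - oracle), 1e-6)
  expect_lt(abs(or_hat - 0.5306), 1e-4)
})

test_that("a frame with 50% response everywhere gives null odds ratios", {
  frame <- frame_two_waves(n_per_wave = 1000, responders = c(500, 500))
  frame$sex <- rep(c("male", "female"), length.out = nrow(frame))
  fit <- fit_pooled_response_model(frame, covariates = "sex")
  expect_true(all(abs(fit$coefficients$or[-1] - 1) < 1e-6))
})

test_that("single-wave covariate fit matches the cross-product oracle", {
  frame <- frame_one_wave_covariate(100, 30, 100, 20)
  fit <- fit_pooled_response_model(frame, covariates = "x",
                                   include_time = FALSE)
  or_hat <- fit$coefficients$or[fit$coefficients$term == "xunexposed"]
  expect_lt(abs(1 / or_hat - (30 * 80) / (70 * 20)), 1e-6)
  # requesting a time trend on one wave is an error
  expect_error(fit_pooled_response_model(frame, covariates = "x"),
               "single wave")
})

test_that("constant covariates are rejected as rank-deficient", {
  frame <- frame_two_waves()
  expect_error(fit_pooled_response_model(frame, covariates = "sex"),
               "constant")
  expect_error(test_time_interactions(frame, "sex"), "constant")
})

test_that("cumulative change reproduces the printed arithmetic", {
  expect_equal(round(cumulative_change(0.96, 11)), 36)
  expect_equal(round(cumulative_change(0.90, 11)), 69)
  expect_equal(cumulative_change(1, 11), 0)
  # per-interval declines are the n = 1 case
  expect_equal(cumulative_change(0.92, 1), 8)
  expect_equal(cumulative_change(0.96, 1), 4)
})

test_that("cumulative change composes multiplicatively over intervals", {
  for (or in c(0.85, 0.92, 1, 1.07)) {
    for (ab in list(c(3, 8), c(1, 10), c(0, 11))) {
      lhs <- 1 - (1 - cumulative_change(or, ab[1]) / 100) *
        (1 - cumulative_change(or, ab[2]) / 100)
      expect_equal(lhs, cumulative_change(or, sum(ab)) / 100,
                   tolerance = 1e-12)
    }
  }
  expect_error(cumulative_change(-0.5, 2))
})

test_that("response rates and subgroup gaps are simple arithmetic", {
  frame <- frame_two_waves(n_per_wave = 1000, responders = c(470, 320))
  rates <- response_rate_table(frame)
  expect_equal(rates$rate_pct[rates$wave_year == 1995], 47.0)
  frame$sex <- rep(c("male", "female"), length.out = nrow(frame))
  by_sex <- response_rate_table(frame, by = "sex")
  gap <- response_gap(by_sex)
  expect_equal(nrow(gap), 2)
  manual <- tapply(by_sex$rate_pct, by_sex$wave_year,
                   function(r) max(r) - min(r))
  expect_equal(gap$gap_pts,
               as.numeric(manual[as.character(gap$wave_year)]))
  expect_error(response_gap(rates), "subgroup")
})

test_that("stratified trends recover generating per-level odds ratios", {
  d <- simulation_design(
    invitations_per_wave = 6000,
    response = response_model(
      time_or = 0.92,
      time_or_modifiers = list(
        age_group = c("16-24" = 0.90 / 0.92, "45-64" = 0.93 / 0.92,
                      "65-75" = 0.96 / 0.92)
      )
    ),
    oversampling = NULL
  )
  sim <- simulate_survey(d, seed = 31)
  strat <- fit_stratified_time_trends(sim$frame, "age_group")
  truth <- c("25-44" = 0.92, "16-24" = 0.90, "45-64" = 0.93,
             "65-75" = 0.96)
  for (lev in names(truth)) {
    row <- strat[strat$level == lev, ]
    expect_true(row$ci_low <= truth[[lev]] && truth[[lev]] <= row$ci_high)
  }
})

test_that("strata spanning a single wave are rejected", {
  frame <- frame_two_waves()
  frame$sex <- ifelse(frame$wave_year == 1995, "male", "female")
  frame$sex[1] <- "female" # avoid constant covariate, keep male 1-wave
  expect_error(fit_stratified_time_trends(frame, "sex", adjust = NULL),
               "male")
})

test_that("interaction screen equals a brute-force likelihood-ratio test", {
  set.seed(77)
  n <- 200
  frame <- tibble::tibble(
    person_id = sprintf("p%03d", 1:n),
    wave_year = sample(c(1995, 1997, 1999, 2001), n, replace = TRUE),
    age = 30L, sex = "male", ethnicity = "western", district = "d1",
    x1 = sample(c("a", "b"), n, replace = TRUE),
    x2 = sample(c("a", "b"), n, replace = TRUE),
    x3 = sample(c("a", "b"), n, replace = TRUE)
  )
  lp <- -0.3 + 0.4 * (x1 <- frame$x1 == "b") -
    0.5 * (frame$x2 == "b") + 0.1 * (frame$wave_year - 1995) / 2
  frame$responded <- rbinom(n, 1, plogis(lp)) == 1

  res <- test_time_interactions(frame, "x1",
                                covariates = c("x1", "x2", "x3"))
  expect_equal(res$df, 1)

  ti <- (frame$wave_year - 1995) / 2
  X0 <- stats::model.matrix(~ ti + x1 + x2 + x3, data = frame)
  X1 <- stats::model.matrix(~ ti + x1 + x2 + x3 + ti:x1, data = frame)
  y <- as.numeric(frame$responded)
  lrt_oracle <- 2 * (logistic_max_loglik(X1, y) -
                       logistic_max_loglik(X0, y))
  expect_lt(abs(res$statistic - lrt_oracle), 1e-4)
})
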