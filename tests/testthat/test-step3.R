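test_that("cell weights equal population-to-sample share ratios", {
  resp <- tibble::tibble(person_id = as.character(1:20),
                         g = rep(c("A", "B"), each = 10))
  marg <- tibble::tibble(g = c("A", "B"),
                         population_count = c(900, 100))
  w <- compute_poststrat_weights(resp, marg, cell_vars = "g")
  expect_equal(attr(w, "method"), "cell")
  # (N_c/N)/(n_c/n): A = 0.9/0.5 = 1.8, B = 0.1/0.5 = 0.2; mean already 1
  expect_equal(unique(w$weight[resp$g == "A"]), 1.8)
  expect_equal(unique(w$weight[resp$g == "B"]), 0.2)
  expect_equal(mean(w$weight), 1)
})

test_that("weighted prevalence is the weighted mean in percent", {
  # cells A (prev 50%, pop share 0.9) and B (prev 80%, pop share 0.1)
  y <- c(rep(c(TRUE, FALSE), 5), rep(TRUE, 8), FALSE, FALSE)
  w <- c(rep(1.8, 10), rep(0.2, 10))
  expect_equal(weighted_prevalence(y), 65)
  expect_equal(weighted_prevalence(y, w), 53)
  expect_equal(weighted_prevalence(rep(TRUE, 4), c(9, 1, 1, 2)), 100)
  expect_true(is.na(weighted_prevalence(logical(0))))
  expect_error(weighted_prevalence(y, -w), "positive")
})

test_that("uniform response gives unit weights and identical prevalence", {
  # every cell responds at exactly 50%
  cells <- tidyr::expand_grid(age_group = c("16-24", "25-44"),
                              sex = c("male", "female"),
                              ethnicity = c("western", "non_western"),
                              district = "d1")
  frame <- tidyr::uncount(cells, 40)
  frame$person_id <- sprintf("p%04d", seq_len(nrow(frame)))
  frame$wave_year <- 1995
  frame$responded <- rep(c(TRUE, FALSE), nrow(frame) / 2)
  margins <- cells
  margins$population_count <- rep(c(3000, 1000), 4)
  # equal response rates with margins proportional to invitees: weights 1
  margins$population_count <- 4000
  w <- compute_poststrat_weights(frame[frame$responded, ], margins)
  expect_equal(attr(w, "method"), "cell")
  expect_true(all(abs(w$weight - 1) < 1e-12))
  set.seed(3)
  y <- rbinom(nrow(w), 1, 0.5)
  expect_equal(weighted_prevalence(y, w$weight), weighted_prevalence(y),
               tolerance = 1e-9)
})

test_that("weighted cell shares reproduce population shares exactly", {
  sim <- simulate_survey(tiny_design(), seed = 6)
  w <- poststrat_weights(sim$frame, sim$margins)
  resp <- dplyr::inner_join(dplyr::filter(sim$frame, responded), w,
                            by = c("person_id", "wave_year"))
  for (wave in unique(resp$wave_year)) {
    rw <- resp[resp$wave_year == wave, ]
    m <- sim$margins[sim$margins$wave_year == wave, ]
    cell_of <- function(df) interaction(df$age_group, df$sex,
                                        df$ethnicity, df$district,
                                        drop = FALSE)
    got <- tapply(rw$weight, cell_of(rw), sum)
    got[is.na(got)] <- 0
    got <- got / sum(rw$weight)
    want <- tapply(m$population_count, cell_of(m), sum)
    want <- want / sum(want)
    present <- names(got)[got > 0]
    expect_lt(max(abs(got[present] - want[present])), 1e-6)
  }
})

test_that("empty respondent cells fall back to raking over the margins", {
  set.seed(42)
  cells <- tidyr::expand_grid(age_group = c("16-24", "25-44"),
                              sex = c("male", "female"),
                              ethnicity = c("western", "non_western"),
                              district = c("d1", "d2"))
  resp <- cells[rep(1:16, times = c(0, rep(3, 15))), ] # one empty cell
  resp$person_id <- sprintf("p%03d", seq_len(nrow(resp)))
  margins <- cells
  margins$population_count <- sample(100:500, 16)
  expect_warning(
    w <- compute_poststrat_weights(resp, margins),
    NA
  )
  expect_equal(attr(w, "method"), "raking")
  # each one-way margin is matched to 1e-6
  for (v in c("age_group", "sex", "ethnicity", "district")) {
    got <- tapply(w$weight, resp[[v]], sum) / sum(w$weight)
    want <- tapply(margins$population_count, margins[[v]], sum)
    want <- want / sum(want)
    expect_lt(max(abs(got - want[names(got)])), 1e-6)
  }
  # and the weights agree with an independently coded IPF oracle
  targets <- lapply(c(age_group = "age_group", sex = "sex",
                      ethnicity = "ethnicity", district = "district"),
                    function(v) {
                      tg <- tapply(margins$population_count, margins[[v]],
                                   sum)
                      tg / sum(tg)
                    })
  expect_equal(w$weight, ipf_oracle(resp, targets), tolerance = 1e-8)
})

test_that("impossible weighting inputs raise errors", {
  resp <- tibble::tibble(person_id = "a", g = "A")
  expect_error(
    compute_poststrat_weights(
      resp, tibble::tibble(g = "A", population_count = 0),
      cell_vars = "g"
    ),
    "zero or missing population"
  )
  expect_error(
    compute_poststrat_weights(resp[0, ],
                              tibble::tibble(g = "A",
                                             population_count = 5),
                              cell_vars = "g"),
    "no respondents"
  )
})

test_that("difference summaries use interpolated quartiles", {
  ser <- tibble::tibble(wave_year = c(1999, 2001, 2003),
                        diff_pts = c(-1, 0, 1))
  s <- contrast_summary(ser)
  expect_equal(s$mean_diff_pts, 0)
  expect_equal(c(s$iqr_low, s$iqr_high), c(-0.5, 0.5))
})

test_that("difference trends are gated on significance and magnitude", {
  waves <- seq(1999, 2017, 2)
  flat <- tibble::tibble(wave_year = waves, diff_pts = 0)
  expect_false(test_difference_trend(flat)$flagged)
  set.seed(1)
  drift <- tibble::tibble(wave_year = waves,
                          diff_pts = seq(0, 5, length.out = 10) +
                            rnorm(10, 0, 0.2))
  tr <- test_difference_trend(drift)
  expect_true(tr$flagged)
  expect_equal(tr$fitted_change_pts, 5, tolerance = 0.8)
  expect_error(test_difference_trend(flat[1:2, ]), "at least 3 waves")
})

test_that("weighting repairs cell-level selection in a known mixture", {
  # two-cell design, selection on the cell variable only: weighted
  # prevalence recovers the population mixture
  frame <- tibble::tibble(
    person_id = sprintf("p%04d", 1:4000),
    wave_year = 1995, age = 30L,
    sex = "male", ethnicity = rep(c("western", "non_western"),
                                  c(2000, 2000)),
    district = "d1",
    responded = rep(c(TRUE, FALSE), c(3000, 1000)) # nw responds 50%
  )
  # outcome depends on the cell: western 20%, non-western 60%
  set.seed(5)
  resp <- frame[frame$responded, ]
  y <- rbinom(nrow(resp), 1,
              ifelse(resp$ethnicity == "western", 0.2, 0.6))
  margins <- tibble::tibble(
    age_group = "25-44", sex = "male",
    ethnicity = c("western", "non_western"), district = "d1",
    population_count = c(500, 500)
  )
  resp$age_group <- derive_age_group(resp$age)
  w <- compute_poststrat_weights(resp, margins)
  pop_truth <- 100 * (0.5 * 0.2 + 0.5 * 0.6)
  wt <- weighted_prevalence(y, w$weight)
  uw <- weighted_prevalence(y)
  expect_lt(abs(wt - pop_truth), abs(uw - pop_truth))
  expect_lt(abs(wt - pop_truth), 3) # sampling noise only
})
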