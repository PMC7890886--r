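# Fixture builders shared across the test files. Everything is generated
# in code; no data files.

# A hand-built two-wave frame with fixed responder counts per wave.
frame_two_waves <- function(n_per_wave = 1000, responders = c(470, 320),
                            waves = c(1995, 1997)) {
  dplyr::bind_rows(lapply(seq_along(waves), function(i) {
    tibble::tibble(
      person_id = sprintf("w%d-%04d", waves[i], seq_len(n_per_wave)),
      wave_year = waves[i],
      age = 30L,
      sex = "male",
      ethnicity = "western",
      district = "d1",
      responded = seq_len(n_per_wave) <= responders[i]
    )
  }))
}

# Single-wave frame with a binary covariate x and fixed responder counts.
frame_one_wave_covariate <- function(n_exposed = 100, resp_exposed = 30,
                                     n_unexposed = 100,
                                     resp_unexposed = 20) {
  tibble::tibble(
    person_id = sprintf("p%04d", seq_len(n_exposed + n_unexposed)),
    wave_year = 2001,
    age = 30L, sex = "male", ethnicity = "western", district = "d1",
    x = rep(c("exposed", "unexposed"), c(n_exposed, n_unexposed)),
    responded = c(seq_len(n_exposed) <= resp_exposed,
                  seq_len(n_unexposed) <= resp_unexposed)
  )
}

# A small, fast simulation design for structural tests.
tiny_design <- function(invitations_per_wave = 1200, ...) {
  simulation_design(
    waves = seq(1995, 2005, by = 2),
    invitations_per_wave = invitations_per_wave,
    ...
  )
}

# Independent two-pass standard deviation (oracle for step 2).
sd_two_pass <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Independent brute-force logistic log-likelihood maximiser (oracle for
# the step-1 LRT): BFGS with analytic gradient on the Bernoulli NLL.
logistic_max_loglik <- function(X, y) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  grad <- function(beta) {
    p <- plogis(drop(X %*% beta))
    -drop(crossprod(X, y - p))
  }
  fit <- optim(rep(0, ncol(X)), nll, grad, method = "BFGS",
               control = list(maxit = 10000, reltol = 1e-15))
  -fit$value
}

# Independent iterative-proportional-fitting oracle (step 3 raking).
ipf_oracle <- function(resp, targets, max_iter = 5000, tol = 1e-12) {
  w <- rep(1, nrow(resp))
  for (iter in seq_len(max_iter)) {
    for (v in names(targets)) {
      cur <- tapply(w, resp[[v]], sum) / sum(w)
      w <- w * (targets[[v]][names(cur)] / cur)[resp[[v]]]
    }
    dev <- max(vapply(names(targets), function(v) {
      cur <- tapply(w, resp[[v]], sum) / sum(w)
      max(abs(cur - targets[[v]][names(cur)]))
    }, numeric(1)))
    if (dev < tol) break
  }
  unname(w / mean(w))
}
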