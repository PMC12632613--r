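# Cox partial-likelihood machinery: likelihood, IRLS updates, fitter.

test_that("log partial likelihood collapses to -sum log|R_i| at beta = 0", {
  d <- survival_data(time = c(1, 2), status = c(1, 1), x = matrix(0, 2, 1))
  expect_equal(log_partial_likelihood(d, 0), -log(2) - log(1))
  # general exact identity at beta = 0
  rnd <- random_survival(n = 12, p = 3, seed = 4)
  ut <- sort(unique(rnd$data$time[rnd$data$status == 1]))
  expected <- -sum(vapply(ut, function(t_k) {
    sum(rnd$data$status == 1 & rnd$data$time == t_k) *
      log(sum(rnd$data$time >= t_k))
  }, numeric(1)))
  expect_equal(log_partial_likelihood(rnd$data, rep(0, 3)), expected)
})

test_that("datasets without events are rejected", {
  expect_error(survival_data(1:3, c(0, 0, 0), matrix(1, 3, 1)) |>
                 log_partial_likelihood(0), "no events")
  expect_error(log_partial_likelihood(
    survival_data(1:2, c(1, 1), matrix(0, 2, 1)), NaN), "finite")
})

test_that("log partial likelihood matches a direct double-loop evaluation", {
  rnd <- random_survival(n = 6, p = 2, seed = 1)
  expect_equal(log_partial_likelihood(rnd$data, rnd$beta),
               loglik_loop(rnd$data, rnd$beta), tolerance = 1e-12)
  # and with ties in the event times (Breslow convention)
  d <- survival_data(time = c(1, 1, 2, 2, 3, 4), status = c(1, 1, 1, 0, 1, 0),
                     x = matrix(seq(-0.5, 0.5, length.out = 12), 6, 2))
  b <- c(0.7, -0.3)
  expect_equal(log_partial_likelihood(d, b), loglik_loop(d, b),
               tolerance = 1e-12)
})

test_that("irls_update matches the explicit nested-loop formulas", {
  rnd <- random_survival(n = 8, p = 2, seed = 2)
  ws <- irls_update(rnd$data, rep(0, 8))
  ref <- irls_loop(rnd$data, rep(0, 8))
  expect_equal(ws$weights, ref$weights, tolerance = 1e-12)
  expect_equal(ws$responses, ref$responses, tolerance = 1e-12)
  # nonzero eta
  eta <- drop(rnd$data$x %*% rnd$beta)
  ws <- irls_update(rnd$data, eta)
  ref <- irls_loop(rnd$data, eta)
  expect_equal(ws$weights, ref$weights, tolerance = 1e-10)
  expect_equal(ws$responses, ref$responses, tolerance = 1e-10)
})

test_that("a subject at risk for no event time has w = 0 and z = eta", {
  # subject 1 censored before the earliest event
  d <- survival_data(time = c(0.5, 1, 2, 3), status = c(0, 1, 1, 0),
                     x = matrix(rnorm(8), 4, 2))
  ws <- irls_update(d, c(0.3, -0.1, 0.2, 0))
  expect_identical(ws$weights[1], 0)
  expect_identical(ws$responses[1], 0.3)
})

test_that("IRLS weights and responses reproduce the eta-gradient and
           diagonal curvature of the negative log likelihood", {
  rnd <- random_survival(n = 9, p = 2, seed = 3)
  eta0 <- drop(rnd$data$x %*% rnd$beta) / 2
  ws <- irls_update(rnd$data, eta0)
  f <- function(eta) {
    # log partial likelihood as a function of eta via an identity design
    d <- survival_data(rnd$data$time, rnd$data$status, diag(length(eta)))
    log_partial_likelihood(d, eta)
  }
  h <- 1e-5
  for (i in seq_along(eta0)) {
    ei <- replace(numeric(length(eta0)), i, h)
    grad_fd <- (f(eta0 + ei) - f(eta0 - ei)) / (2 * h)
    curv_fd <- -(f(eta0 + ei) - 2 * f(eta0) + f(eta0 - ei)) / h^2
    expect_equal(ws$weights[i] * (ws$responses[i] - eta0[i]), grad_fd,
                 tolerance = 1e-4)
    expect_equal(ws$weights[i], curv_fd, tolerance = 1e-4)
  }
})

test_that("analytic beta-gradient matches central finite differences", {
  for (seed in 1:5) {
    rnd <- random_survival(n = 10, p = 3, seed = seed)
    beta <- rnd$beta / 2
    g <- tlscp:::cox_gradient(rnd$data, beta)
    h <- 1e-6
    for (j in 1:3) {
      ej <- replace(numeric(3), j, h)
      fd <- (log_partial_likelihood(rnd$data, beta + ej) -
             log_partial_likelihood(rnd$data, beta - ej)) / (2 * h)
      expect_equal(unname(g[j]), fd, tolerance = 1e-5 * max(1, abs(fd)))
    }
  }
})

test_that("fit_cox is stationary and agrees with an established Cox
           implementation", {
  skip_if_not_installed("survival")
  rnd <- random_survival(n = 200, p = 5, seed = 11)
  beta_hat <- fit_cox(rnd$data)
  expect_lt(max(abs(tlscp:::cox_gradient(rnd$data, beta_hat))), 1e-6)
  ref <- survival::coxph(
    survival::Surv(rnd$data$time, rnd$data$status) ~ rnd$data$x,
    ties = "breslow")
  se <- sqrt(diag(ref$var))
  expect_true(all(abs(beta_hat - coef(ref)) < 2 * se))
  expect_equal(unname(beta_hat), unname(coef(ref)), tolerance = 1e-5)
})

test_that("a constant covariate gets coefficient 0 under ridge", {
  d <- survival_data(time = c(1, 2, 3, 4), status = c(1, 1, 1, 0),
                     x = matrix(1, 4, 1))
  expect_equal(unname(fit_cox(d, ridge = 1e-4)), 0, tolerance = 1e-4)
})
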