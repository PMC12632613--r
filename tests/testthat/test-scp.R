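# End-to-end fusion-penalized Cox fitting, cluster extraction, and BIC
# selection of the sparsity level.

test_that("vacuous sparsity level reproduces the unpenalized Cox fit", {
  rnd <- random_survival(n = 150, p = 5, seed = 21)
  ref <- fit_cox(rnd$data)
  fit <- scp(rnd$data, k = 4)   # k = p - 1 admits any difference pattern
  expect_equal(unname(fit$beta), unname(ref), tolerance = 1e-4)
})

test_that("three well-separated clusters are recovered exactly at large n", {
  cfg <- scenario_config(n_target = 2000, p = 9, seed = 2)
  tgt <- generate_target(cfg)
  fit <- scp(tgt$data, k = 2)
  expect_equal(nmi(fit$labels, tgt$partition), 1)
  expect_equal(length(fit$centers), 3L)
  # every penalized coefficient equals its cluster center exactly
  expect_equal(unname(fit$beta[fit$penalized]),
               fit$centers[fit$labels], tolerance = 1e-12)
  # the fitted break positions are the true ones along the rank order
  D <- build_fusion_matrix(fit$tau)
  expect_equal(sum(drop(D %*% fit$beta[fit$penalized]) != 0), 2)
})

test_that("extract_clusters opens a cluster at every gap above tol", {
  cl <- extract_clusters(c(1, 1, 3), 1:3, tol = 1e-8)
  expect_equal(cl$labels, c(1L, 1L, 2L))
  expect_equal(cl$centers, c(1, 3))
  cl <- extract_clusters(rep(2.5, 4), 1:4, tol = 1e-8)
  expect_equal(length(cl$centers), 1L)
  set.seed(12)
  for (i in 1:100) {
    p <- sample(3:10, 1)
    b <- round(rnorm(p), 1)
    tau <- build_rank_map(b)
    tol <- 1e-8
    cl <- extract_clusters(b, tau, tol = tol)
    expect_equal(length(unique(cl$labels)),
                 1L + sum(abs(diff(b[tau])) > tol))
  }
})

test_that("BIC selection recomputes, prefers small k on ties, and handles a
           single-candidate grid", {
  rnd <- random_survival(n = 120, p = 6, seed = 31,
                         beta = c(1, 1, 1, -0.5, -0.5, -0.5))
  single <- scp(rnd$data, k = 2)
  expect_equal(single$k_used, 2L)
  fit <- scp(rnd$data, k = 1:5)
  tab <- fit$bic_table
  # BIC values agree with -2*loglik + df*log(#events) recomputed directly
  expect_equal(tab$bic,
               -2 * tab$loglik + tab$df * log(sum(rnd$data$status == 1)),
               tolerance = 1e-8)
  expect_equal(fit$bic, min(tab$bic))
  expect_equal(fit$df, length(fit$centers))
})

test_that("BIC keeps the model small when the truth is one cluster", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    n <- 250; p <- 6
    X <- matrix(runif(n * p, -0.5, 0.5), n, p)
    d <- tlscp:::simulate_survival(X, rep(0.5, p), noise_sd = 0.5,
                                   censor_rate = 0.3)
    fit <- scp(d, k = 1:5)
    if (length(fit$centers) <= 2) hits <- hits + 1L
  }
  expect_gte(hits, 16L)
})

test_that("results are invariant to the ordering of the k grid", {
  rnd <- random_survival(n = 150, p = 6, seed = 41)
  f1 <- scp(rnd$data, k = 1:5)
  f2 <- scp(rnd$data, k = c(3, 5, 1, 4, 2))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
  expect_equal(f1$k_used, f2$k_used)
})

test_that("refitting with the returned rank map and k reproduces the fit", {
  cfg <- scenario_config(n_target = 300, p = 9, seed = 8)
  tgt <- generate_target(cfg)
  fit <- scp(tgt$data, k = 1:4)
  refit <- scp(tgt$data, k = fit$k_used, tau = fit$tau)
  expect_equal(fit$beta, refit$beta, tolerance = 1e-6)
})

test_that("the outer loop's objective trace is nonincreasing", {
  cfg <- scenario_config(n_target = 500, p = 9, seed = 5)
  tgt <- generate_target(cfg)
  fit <- scp(tgt$data, k = 2)
  expect_true(all(diff(fit$trace) < 1e-6))
})

test_that("unpenalized covariates are excluded from fusion and clustering", {
  cfg <- scenario_config(n_target = 400, p = 6, seed = 13)
  tgt <- generate_target(cfg)
  # add a binary adjustment covariate with its own effect
  sex <- rbinom(400, 1, 0.5)
  X <- cbind(tgt$data$x, sex = sex)
  d <- survival_data(tgt$data$time, tgt$data$status, X, unpenalized = "sex")
  fit <- scp(d, k = 2)
  expect_equal(length(fit$labels), 6L)
  expect_false("sex" %in% names(fit$labels))
  expect_true("sex" %in% names(fit$beta))
  expect_equal(fit$df, length(fit$centers) + 1L)
})

test_that("print, summary, coef, logLik, predict and residuals methods work", {
  cfg <- scenario_config(n_target = 200, p = 6, seed = 3)
  tgt <- generate_target(cfg)
  fit <- scp(tgt$data, k = 2)
  expect_output(print(fit), "clusters found")
  expect_output(print(summary(fit)), "Tuning path")
  expect_equal(coef(fit), fit$beta)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  lp <- predict(fit, tgt$data)
  expect_equal(lp, drop(tgt$data$x %*% fit$beta))
  expect_equal(predict(fit, tgt$data, type = "risk"), exp(lp))
  r <- residuals(fit, tgt$data)
  # martingale residuals sum to zero at the fitted values
  expect_lt(abs(sum(r)), 1e-6)
})
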