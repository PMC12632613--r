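# Weighted rank averaging and the transfer-learning fit.

test_that("weighted rank averaging follows the averaging rule", {
  # hand evaluation: opposite rankings with equal weights tie everywhere,
  # resolved by feature index
  expect_identical(weighted_rank_average(1:3, 3:1, 0.5, 0.5), 1:3)
  # agreement: merged equals either ranking
  r <- c(2L, 4L, 1L, 3L)
  expect_identical(weighted_rank_average(r, r, 0.7, 0.3), order(r))
  # zero target weight: pure transfer of the source ordering
  rs <- c(3L, 1L, 4L, 2L)
  rt <- c(1L, 2L, 3L, 4L)
  expect_identical(weighted_rank_average(rs, rt, 1, 0),
                   order(rs))
  # direct score check on a non-trivial case
  tau <- weighted_rank_average(rs, rt, 2, 1)
  expect_identical(tau, order(2 * rs + 1 * rt))
})

test_that("merged ranking is invariant to common rescaling of the weights", {
  set.seed(17)
  for (i in 1:20) {
    p <- sample(4:12, 1)
    rs <- sample.int(p); rt <- sample.int(p)
    ws <- runif(p); wt <- runif(p)
    a <- weighted_rank_average(rs, rt, ws, wt)
    b <- weighted_rank_average(rs, rt, 13.7 * ws, 13.7 * wt)
    expect_identical(a, b)
  }
})

test_that("invalid rank vectors and weights are rejected", {
  expect_error(weighted_rank_average(c(1L, 1L, 2L), 1:3, 1, 1),
               "not a permutation")
  expect_error(weighted_rank_average(1:3, 1:4, 1, 1), "length")
  expect_error(weighted_rank_average(1:3, 1:3, 0, 0), "weights")
})

test_that("transfer from an identical source reproduces the plain fit", {
  cfg <- scenario_config(n_target = 250, p = 9, seed = 19)
  tgt <- generate_target(cfg)
  plain <- scp(tgt$data, k = 1:3)
  tl <- tlscp(tgt$data, source = tgt$data, k = 1:3)
  # source and target rankings coincide, so any weights give the same tau
  expect_identical(tl$tau, plain$tau)
  expect_equal(tl$beta, plain$beta, tolerance = 1e-8)
})

test_that("summary-level source input matches individual-level input", {
  cfg <- scenario_config(n_target = 200, n_source = 500, p = 9, seed = 23)
  tgt <- generate_target(cfg)
  src <- generate_source(cfg, tgt$beta)
  full <- tlscp(tgt$data, source = src$data, k = 2)
  beta_s <- fit_cox(src$data)
  by_coef <- tlscp(tgt$data, source = beta_s, n_source = 500, k = 2)
  by_rank <- tlscp(tgt$data,
                   source_ranks = rank(beta_s, ties.method = "first"),
                   n_source = 500, k = 2)
  expect_identical(full$tau, by_coef$tau)
  expect_identical(full$tau, by_rank$tau)
  expect_equal(full$beta, by_coef$beta)
})

test_that("target covariates may be a named subset of the source's", {
  cfg <- scenario_config(n_target = 200, n_source = 500, p = 9, seed = 29)
  tgt <- generate_target(cfg)
  src <- generate_source(cfg, tgt$beta)
  # source with extra covariates; overlap is matched by name and re-ranked
  extra <- matrix(runif(500 * 2, -0.5, 0.5), 500, 2,
                  dimnames = list(NULL, c("e1", "e2")))
  src_wide <- survival_data(src$data$time, src$data$status,
                            cbind(src$data$x, extra))
  fit <- tlscp(tgt$data, source = src_wide, k = 2)
  expect_s3_class(fit, "tlscp")
  expect_identical(sort(unname(fit$rank_source)), 1:9)
  expect_error(tlscp(tgt$data, source = fit_cox(src$data)[1:5], k = 2),
               "do not cover|missing")
})

test_that("per-feature weights steer individual features toward a cohort", {
  rs <- c(1L, 2L, 3L, 4L)
  rt <- c(4L, 3L, 2L, 1L)
  # features 1-2 trust the source, features 3-4 the target
  tau <- weighted_rank_average(rs, rt, w_source = c(1, 1, 0, 0),
                               w_target = c(0, 0, 1, 1))
  expect_identical(tau, order(c(1, 2, 2, 1)))
})

test_that("ranking transfer helps a small target cohort", {
  # paired replicates at reduced size; the source ranking is consistent
  wins <- 0L; n_rep <- 8L
  for (r in seq_len(n_rep)) {
    cfg <- scenario_config(n_target = 150, n_source = 1500, p = 30,
                           seed = 100 + r)
    tgt <- generate_target(cfg)
    src <- generate_source(cfg, tgt$beta)
    f_scp <- scp(tgt$data, k = 1:4)
    f_tl <- tlscp(tgt$data, src$data, k = 1:4)
    if (nmi(f_tl$labels, tgt$partition) >= nmi(f_scp$labels, tgt$partition))
      wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.7 * n_rep))
})
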