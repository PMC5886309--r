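test_that("a design with no rejection region commits no familywise error", {
  st <- small_store(R = 1000, n_max = 5)
  d <- mams_design(K = 3, J = 2, n = 5, e = c(1000, 1000), f = c(999, 1000),
                   statistic = "t", degenerate = TRUE)
  oc <- mams_oc(d, st, delta1 = 0.545, delta0 = 0.178)
  expect_identical(oc$fwer, 0)
  expect_true(all(oc$pwer == 0))
})

test_that("single-stage z rejection rate matches the closed form", {
  st <- mams_store(R = 20000, K = 1, J = 1, n_max = 10, seed = 9)
  d <- mams_design(K = 1, J = 1, n = 10, e = 1.645, f = 1.645,
                   statistic = "z")
  oc <- mams_oc(d, st, delta1 = 0.5)
  p <- 1 - pnorm(1.645)
  expect_lt(abs(oc$fwer - p), 3.5 * sqrt(p * (1 - p) / 20000))
  expect_equal(oc$se_fwer, sqrt(oc$fwer * (1 - oc$fwer) / 20000))
})

test_that("expected sample size identities hold exactly", {
  st <- small_store(R = 3000, n_max = 8)
  d <- mams_design(K = 3, J = 2, n = 8, e = c(1.1, 1.6), f = c(0.4, 1.6),
                   statistic = "t")
  sim <- simulate_trials(d, st, null_scenario(3))
  # aggregate formula n(max omega + sum omega) vs per-trial accumulation
  agg <- expected_sample_size(sim)
  expect_equal(agg, mean(sim$recruited_n), tolerance = 1e-12)
  expect_equal(agg, expected_sample_size(sim$omega, n = 8), tolerance = 1e-12)
  expect_error(expected_sample_size(matrix(integer(0), 3, 0), n = 8),
               "no trial outcomes")

  # degenerate designs pin the ESS at its extremes
  all_stop <- mams_design(K = 3, J = 2, n = 8, e = c(-5, 1.6), f = c(-6, 1.6),
                          statistic = "t")
  expect_equal(expected_sample_size(simulate_trials(all_stop, st,
                                                    null_scenario(3))),
               4 * 8)
  expect_equal(expected_sample_size(simulate_trials(
    forced_continuation_design(K = 3, n = 8), st, null_scenario(3))),
    8 * 8)
})

test_that("separate stopping never ends a trial before simultaneous stopping", {
  st <- small_store(R = 4000, n_max = 10)
  base <- list(K = 3, J = 2, n = 10, e = c(1.2, 1.7), f = c(0.3, 1.7))
  dsim <- do.call(mams_design, c(base, list(rule = "simultaneous",
                                            statistic = "t")))
  dsep <- do.call(mams_design, c(base, list(rule = "separate",
                                            statistic = "t")))
  ss <- simulate_trials(dsim, st, null_scenario(3))
  se <- simulate_trials(dsep, st, null_scenario(3))
  expect_true(all(se$total_n >= ss$total_n))
  expect_gte(expected_sample_size(se), expected_sample_size(ss))
})

test_that("power approaches one for a very large interesting effect", {
  st <- mams_store(R = 10000, K = 3, J = 2, n_max = 10, seed = 15)
  d <- mams_design(K = 3, J = 2, n = 10, e = c(2.3, 2.2), f = c(0.7, 2.2),
                   statistic = "t")
  oc <- mams_oc(d, st, delta1 = 5, delta0 = 0)
  expect_gte(oc$power, 0.999)
})

test_that("the penalised objective combines ESS terms and feasibility penalties", {
  st <- small_store(R = 2000, n_max = 10)
  d <- mams_design(K = 3, J = 2, n = 10, e = c(1.4, 1.8), f = c(0.3, 1.8),
                   statistic = "t")
  spec <- mams_objective(alpha = 0.05, beta = 0.1, delta1 = 0.545,
                         delta0 = 0.178, w = c(1, 1, 1) / 3, penalty = 300)
  oc <- mams_oc(d, st, spec$delta1, spec$delta0)

  # zero-penalty regime: plain weighted average (force feasibility fields)
  oc_feas <- oc; oc_feas$fwer <- 0.04; oc_feas$power <- 0.95
  expect_equal(objective_value(oc_feas, d, spec),
               (oc$ess_null + oc$ess_lfc + max_sample_size(d)) / 3)

  # alpha excess of 0.01 with P = 300 adds exactly 300 * 0.01/0.05 = 60
  oc_inf <- oc_feas; oc_inf$fwer <- 0.06
  expect_equal(objective_value(oc_inf, d, spec) -
                 objective_value(oc_feas, d, spec), 60)

  # all weight on the null ESS, feasible: objective is the null ESS
  spec1 <- mams_objective(alpha = 0.05, beta = 0.1, delta1 = 0.545,
                          delta0 = 0.178, w = c(1, 0, 0), penalty = 300)
  expect_equal(objective_value(oc_feas, d, spec1), oc$ess_null)
})

test_that("single-stage sample size reduces to the two-arm formula for K = 1", {
  for (al in c(0.05, 0.025)) for (be in c(0.1, 0.2)) {
    d1 <- 0.545
    n <- ceiling(2 * (qnorm(1 - al) + qnorm(1 - be))^2 / d1^2)
    expect_equal(single_stage_sample_size(1, al, be, d1), 2 * n)
  }
})

test_that("many-to-one critical value agrees with independent oracles", {
  cc <- single_stage_critical(K = 3, alpha = 0.05)
  # multivariate-normal oracle
  corr <- matrix(0.5, 3, 3); diag(corr) <- 1
  p <- mvtnorm::pmvnorm(upper = rep(cc, 3), corr = corr,
                        algorithm = mvtnorm::GenzBretz(abseps = 1e-7))
  expect_equal(as.numeric(p), 0.95, tolerance = 1e-5)
  # simulation oracle: one shared control draw plus arm-wise draws
  set.seed(77)
  M <- 1e6
  w0 <- rnorm(M)
  mx <- pmax(rnorm(M), rnorm(M), rnorm(M))
  phat <- mean((mx + w0) / sqrt(2) > cc)
  expect_lt(abs(phat - 0.05), 3 * sqrt(0.05 * 0.95 / M))
})

test_that("the single-stage size is minimal for the required pairwise power", {
  K <- 3; al <- 0.05; be <- 0.1; d1 <- 0.545
  tot <- single_stage_sample_size(K, al, be, d1)
  n <- tot / (K + 1)
  cc <- single_stage_critical(K, al)
  pw <- function(n) 1 - pnorm(cc - d1 * sqrt(n / 2))
  expect_gte(pw(n), 1 - be)
  expect_lt(pw(n - 1), 1 - be)
})
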