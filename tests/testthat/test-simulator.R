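test_that("replicate store is reproducible and extension-stable", {
  a <- mams_store(R = 50, K = 2, J = 2, n_max = 6, seed = 42)
  b <- mams_store(R = 50, K = 2, J = 2, n_max = 6, seed = 42)
  expect_identical(a$Z, b$Z)
  # replicate-major generation: growing R appends without disturbing earlier
  # replicates
  big <- mams_store(R = 80, K = 2, J = 2, n_max = 6, seed = 42)
  expect_identical(big$Z[, , , 1:50], a$Z)
  # mean-shift/scale realisation leaves the store standard normal
  z <- a$Z
  expect_lt(abs(mean(z)), 4 / sqrt(length(z)))
})

test_that("store memory guard names the budget", {
  expect_error(mams_store(R = 1e6, K = 3, J = 2, n_max = 100, seed = 1,
                          max_bytes = 1e6),
               "budget")
})

test_that("common random numbers: smaller group sizes reuse leading deviates", {
  st <- small_store(R = 100, K = 2, n_max = 40)
  s20 <- mamsmc:::store_block_sums(st, 20)
  s40 <- mamsmc:::store_block_sums(st, 40)
  manual <- colSums(st$Z[1:20, , , , drop = FALSE])
  expect_equal(s20$S1, manual, tolerance = 1e-12)
  # responses for n = 20 are exactly the first 20 of those for n = 40
  sc <- mams_scenario(c(0.3, 0.1), sigma_true = 1.7)
  x20 <- mamsmc:::store_responses(st, 3, 20, sc)
  x40 <- mamsmc:::store_responses(st, 3, 40, sc)
  expect_identical(x20, x40[1:20, , ])
  expect_false(isTRUE(all.equal(s20$S1, s40$S1)))
})

test_that("pooled variance matches hand computation and a brute-force oracle", {
  # two arms of two patients: means 1 and 2, SS = 2 + 2, df = 2
  pv <- pooled_variance(list(c(0, 2), c(1, 3)))
  expect_equal(pv$sigma2, 2)
  expect_identical(pv$df, 2L)

  expect_equal(pooled_variance(list(rep(3, 4), rep(3, 2), rep(3, 5)))$sigma2, 0)

  expect_error(pooled_variance(list(1, 2)), "degrees of freedom")

  # oracle: accumulate squared deviations patient by patient about each arm's
  # frozen cumulative mean, computed with explicit loops
  brute <- function(arms) {
    ss <- 0; ntot <- 0
    for (x in arms) {
      m <- 0
      for (v in x) m <- m + v
      m <- m / length(x)
      for (v in x) ss <- ss + (v - m)^2
      ntot <- ntot + length(x)
    }
    ss / (ntot - length(arms))
  }
  set.seed(5)
  for (i in 1:100) {
    arms <- lapply(seq_len(sample(2:5, 1)),
                   function(k) rnorm(sample(1:6, 1), sd = runif(1, 0.5, 3)))
    if (sum(lengths(arms)) - length(arms) < 1) next
    expect_equal(pooled_variance(arms)$sigma2, brute(arms),
                 tolerance = 1e-12)
  }
})

test_that("interim statistics follow the two-sample form with a shared control", {
  expect_equal(test_statistics(c(0, 0.5), c(25, 25), 1),
               0.5 / sqrt(2 / 25), tolerance = 1e-12)
  expect_equal(test_statistics(c(0.7, 0.7, 0.7), c(10, 12, 9), 2.3),
               c(0, 0))
  expect_error(test_statistics(c(0, 1), c(5, 5), 0), "degenerate variance")
})

test_that("z statistics under the null are standard normal across replicates", {
  R <- 100000; n <- 16
  st <- mams_store(R = R, K = 1, J = 1, n_max = n, seed = 3)
  s <- mamsmc:::store_block_sums(st, n)
  tstat <- (s$S1[1, 2, ] - s$S1[1, 1, ]) / (n * sqrt(2 / n))
  expect_lt(abs(mean(tstat)), 4 / sqrt(R))
  expect_lt(abs(var(tstat) - 1), 4 * sqrt(2 / R))
})

test_that("single-trial conduct follows the stage-wise decision algorithm", {
  # K = 2, J = 2: arm 1 futile at stage 1, arm 2 continues => 5n patients
  n <- 4
  d <- mams_design(K = 2, J = 2, n = n, e = c(2, 2.2), f = c(0, 2.2),
                   rule = "simultaneous", statistic = "z")
  X <- array(0, dim = c(n, 2, 3))
  X[, 1, 1] <- c(-0.2, 0.1, 0.05, 0.05)   # control stage 1, mean 0
  X[, 1, 2] <- c(-1.2, -0.8, -1.1, -0.9)  # arm 1: T11 = -1/sqrt(2/4) < 0
  X[, 1, 3] <- c(0.6, 0.9, 0.7, 0.6)      # arm 2: T21 = 0.7/sqrt(.5) ~ 0.99
  X[, 2, ] <- 0.1                          # stage 2 (arm 2 accepts)
  out <- conduct_trial(d, X)
  expect_identical(out$omega, c(1L, 2L))
  expect_identical(out$psi, c(0L, 0L))
  expect_equal(out$total_n, 5 * n)

  # all statistics past efficacy at stage 1: trial ends with n(K+1) patients
  d2 <- mams_design(K = 2, J = 2, n = n, e = c(-5, 2.2), f = c(-6, 2.2),
                    rule = "simultaneous", statistic = "z")
  out2 <- conduct_trial(d2, X)
  expect_identical(out2$psi, c(1L, 1L))
  expect_equal(out2$total_n, 3 * n)
})

test_that("forced continuation recruits every arm in every stage", {
  st <- small_store(R = 200, n_max = 5)
  d <- forced_continuation_design(K = 3, n = 5)
  sim <- simulate_trials(d, st, null_scenario(3))
  expect_true(all(sim$total_n == 2 * 5 * 4))
})

test_that("batched simulation equals the single-replicate loop element-wise", {
  R <- 1000
  st <- mams_store(R = R, K = 3, J = 2, n_max = 9, seed = 21)
  sc <- lfc_scenario(3, 0.5, 0.15, sigma_true = 1.3)
  for (rule in c("simultaneous", "separate"))
    for (statistic in c("z", "t")) {
      d <- mams_design(K = 3, J = 2, n = 9, e = c(1.3, 1.7), f = c(0.2, 1.7),
                       rule = rule, statistic = statistic)
      sim <- simulate_trials(d, st, sc)
      for (r in seq_len(R)) {
        X <- mamsmc:::store_responses(st, r, d$n, sc)
        ref <- conduct_trial(d, X)
        expect_identical(sim$omega[, r], ref$omega)
        expect_identical(sim$psi[, r], ref$psi)
        expect_identical(sim$total_n[r], as.numeric(ref$total_n))
      }
    }
})

test_that("raising efficacy boundaries never adds familywise errors", {
  st <- small_store(R = 5000, n_max = 10)
  sc <- null_scenario(3)
  for (rule in c("simultaneous", "separate")) {
    base <- mams_design(K = 3, J = 2, n = 10, e = c(1.5, 1.8),
                        f = c(0.4, 1.8), rule = rule, statistic = "t")
    up <- mams_design(K = 3, J = 2, n = 10, e = c(1.8, 2.1),
                      f = c(0.4, 2.1), rule = rule, statistic = "t")
    s0 <- simulate_trials(base, st, sc)
    s1 <- simulate_trials(up, st, sc)
    fwe0 <- colSums(s0$psi) > 0L
    fwe1 <- colSums(s1$psi) > 0L
    expect_true(all(fwe1 <= fwe0))
    if (rule == "separate")  # arm-level rejections are monotone too
      expect_true(all(s1$psi <= s0$psi))
  }
})

test_that("quantile substitution maps normal boundaries to heavier-tailed t values", {
  e <- c(-2.5, -1, 0, 0.777, 1.645, 2.330, 3)
  # equal-tail map leaves the sign and widens the magnitude
  adj <- quantile_substitute(e, df = 20)
  expect_true(all(abs(adj) >= abs(e)))
  expect_equal(adj[e == 0], 0)
  expect_true(all(diff(adj) > 0))  # strictly increasing in the input
  # degrees of freedom -> Inf recovers the normal boundaries
  expect_equal(quantile_substitute(e, df = 1e6), e, tolerance = 1e-4)
  # infinite boundaries pass through
  expect_identical(quantile_substitute(c(-Inf, Inf), df = 5), c(-Inf, Inf))
  expect_error(quantile_substitute(1.96, df = 0), "degree")

  # independent oracle: invert a numerically integrated t CDF at the normal
  # tail probability for the stage-1 worked-example boundary
  nu <- quantile_substitution_df(K = 3, J = 2, n = 45)
  expect_identical(nu, c(176L, 356L))
  target <- 1 - pnorm(2.330)
  tail_prob <- function(x) integrate(function(u) dt(u, df = 176), x, Inf,
                                     rel.tol = 1e-12)$value
  oracle <- uniroot(function(x) tail_prob(x) - target, c(2, 3),
                    tol = 1e-10)$root
  expect_equal(quantile_substitute(2.330, df = 176), oracle,
               tolerance = 1e-8)
})

test_that("quantile substitution of a design preserves the shared terminal boundary", {
  d <- mams_reference_designs(1, "simultaneous", "triangular")
  adj <- quantile_substitute_design(d)
  expect_identical(adj$statistic, "t")
  expect_equal(adj$e[2], adj$f[2])
  expect_gt(adj$e[1], d$e[1])
  expect_gt(adj$f[1], d$f[1])
})
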