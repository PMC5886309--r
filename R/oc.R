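#' Monte Carlo operating characteristics of a design
#'
#' Simulates the design on a common-random-numbers store under the global
#' null (for the familywise error-rate, the per-hypothesis rejection rates
#' and the null expected sample size) and under the least favourable
#' configuration \code{theta = (delta1, delta0, ..., delta0)} (for the
#' pairwise power of the first hypothesis and the LFC expected sample size).
#'
#' @param design a validated \code{"mams_design"}.
#' @param store a \code{"mams_store"} supporting the design's \code{n}.
#' @param delta1 interesting treatment effect defining the LFC.
#' @param delta0 uninteresting effect for arms 2..K under the LFC.
#' @param sigma_true true response standard deviation generating the data
#'   (defaults to the design's presumed value).
#' @param reps optional replicate subset passed to [simulate_trials()].
#' @return An object of class \code{"mams_oc"}: familywise error-rate
#'   \code{fwer}, pairwise \code{power}, per-hypothesis rejection
#'   probabilities \code{pwer} (under the null), expected sample sizes
#'   \code{ess_null} and \code{ess_lfc}, the maximum sample size
#'   \code{max_n}, Monte Carlo standard errors (\code{se_fwer},
#'   \code{se_power}, \code{se_ess_null}, \code{se_ess_lfc}) and the
#'   replicate count \code{R}. \code{method = "monte-carlo"}.
#' @examples
#' d <- mams_reference_designs(1, "simultaneous", "triangular")
#' st <- mams_store(R = 2000, K = 3, J = 2, n_max = d$n, seed = 1)
#' mams_oc(d, st, delta1 = 0.545, delta0 = 0.178)
#' @export
mams_oc <- function(design, store, delta1, delta0 = 0,
                    sigma_true = design$sigma, reps = NULL) {
  K <- design$K
  sim0 <- simulate_trials(design, store,
                          null_scenario(K, sigma_true = sigma_true), reps)
  sim1 <- simulate_trials(design, store,
                          lfc_scenario(K, delta1, delta0,
                                       sigma_true = sigma_true), reps)
  R <- sim0$R
  fwer <- mean(colSums(sim0$psi) > 0L)
  power <- mean(sim1$psi[1L, ] == 1L)
  pwer <- rowMeans(sim0$psi == 1L)
  structure(list(
    fwer = fwer, power = power, pwer = pwer,
    ess_null = mean(sim0$total_n), ess_lfc = mean(sim1$total_n),
    max_n = max_sample_size(design),
    se_fwer = sqrt(fwer * (1 - fwer) / R),
    se_power = sqrt(power * (1 - power) / R),
    se_ess_null = stats::sd(sim0$total_n) / sqrt(R),
    se_ess_lfc = stats::sd(sim1$total_n) / sqrt(R),
    R = R, delta1 = delta1, delta0 = delta0, sigma_true = sigma_true,
    design = design, method = "monte-carlo"),
    class = "mams_oc")
}

#' @export
print.mams_oc <- function(x, digits = 4, ...) {
  cat(sprintf("MAMS operating characteristics (%s%s)\n", x$method,
              if (x$method == "monte-carlo") sprintf(", R = %d", x$R) else ""))
  cat(sprintf("  FWER (theta = 0):      %.*f  (SE %.*f)\n", digits, x$fwer,
              digits, x$se_fwer))
  cat(sprintf("  power (LFC, H01):      %.*f  (SE %.*f)\n", digits, x$power,
              digits, x$se_power))
  cat("  per-hypothesis rejection at the null:",
      paste(formatC(x$pwer, digits = digits, format = "f"), collapse = ", "),
      "\n")
  cat(sprintf("  ESS at the null: %.1f   ESS at the LFC: %.1f   max N: %d\n",
              x$ess_null, x$ess_lfc, x$max_n))
  invisible(x)
}

#' Expected sample size from simulated outcomes
#'
#' The realised sample size of a trial with concluding stages \code{omega} is
#' \code{n * (max(omega) + sum(omega))}; the expected sample size is its mean
#' over trials. Identical (exactly, not just in expectation) to the mean of
#' the per-trial totals accumulated during simulation.
#'
#' @param sim a \code{"mams_sim"} object, or a \code{K x R} matrix of
#'   concluding stages.
#' @param n group size (taken from the simulation object if omitted).
#' @return numeric expected sample size.
#' @export
expected_sample_size <- function(sim, n = NULL) {
  if (inherits(sim, "mams_sim")) {
    omega <- sim$omega
    n <- sim$design$n
  } else {
    omega <- sim
    if (is.null(n)) stop("'n' is required with a bare omega matrix", call. = FALSE)
  }
  if (length(omega) == 0L) stop("no trial outcomes supplied", call. = FALSE)
  mean(total_sample_size(omega, n))
}

#' Specify the design optimality criterion
#'
#' The objective for a candidate design is the weighted combination
#' \deqn{w_1 \, ESS(0) + w_2 \, ESS(\delta) + w_3 \, n J (K+1)
#'   + P\left[ I(\hat\alpha > \alpha)\frac{\hat\alpha-\alpha}{\alpha}
#'   + I(\hat\beta > \beta)\frac{\hat\beta-\beta}{\beta} \right],}
#' where \eqn{\hat\alpha} is the (estimated) familywise error-rate,
#' \eqn{\hat\beta} the estimated type-II error rate (one minus the pairwise
#' power), and \eqn{P > 0} a penalty for infeasible designs, by default the
#' total sample size of the corresponding single-stage design
#' ([single_stage_sample_size()]).
#'
#' @param alpha nominal familywise error-rate.
#' @param beta nominal type-II error rate (1 - power).
#' @param delta1,delta0 effects defining the LFC.
#' @param w weights \code{c(w1, w2, w3)} on ESS at the null, ESS at the LFC,
#'   and the maximum sample size; non-negative, not all zero.
#' @param sigma presumed response standard deviation.
#' @param penalty penalty \code{P}; \code{NULL} defers to the single-stage
#'   sample size, computed when first needed (it depends on K).
#' @return An object of class \code{"mams_objective"}.
#' @export
mams_objective <- function(alpha = 0.05, beta = 0.1, delta1, delta0 = 0,
                           w = c(1, 1, 1) / 3, sigma = 1, penalty = NULL) {
  stopifnot(length(w) == 3L, all(w >= 0), sum(w) > 0,
            alpha > 0, alpha < 1, beta > 0, beta < 1, delta1 > 0)
  if (!is.null(penalty) && penalty <= 0)
    stop("'penalty' must be positive", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, delta1 = delta1, delta0 = delta0,
                 w = as.numeric(w), sigma = sigma, penalty = penalty),
            class = "mams_objective")
}

# Resolve the penalty P for a given K (single-stage total sample size unless
# the user supplied one).
objective_penalty <- function(spec, K) {
  if (!is.null(spec$penalty)) return(spec$penalty)
  single_stage_sample_size(K, spec$alpha, spec$beta, spec$delta1,
                           sigma = spec$sigma)
}

#' Evaluate the penalised design objective
#'
#' @param oc a \code{"mams_oc"} computed for \code{design} under the
#'   objective's scenarios.
#' @param design the evaluated \code{"mams_design"}.
#' @param spec a \code{"mams_objective"}.
#' @return numeric objective value (lower is better).
#' @export
objective_value <- function(oc, design, spec) {
  P <- objective_penalty(spec, design$K)
  beta_hat <- 1 - oc$power
  spec$w[1] * oc$ess_null + spec$w[2] * oc$ess_lfc +
    spec$w[3] * max_sample_size(design) +
    P * ((oc$fwer > spec$alpha) * (oc$fwer - spec$alpha) / spec$alpha +
         (beta_hat > spec$beta) * (beta_hat - spec$beta) / spec$beta)
}

# P(max of K equicorrelated-1/2 standard normals <= c), by 1-D integration:
# with Z_k = (W_k + W_0)/sqrt(2), the event factorises given W_0.
dunnett_cdf <- function(c, K) {
  if (!is.finite(c)) return(if (c > 0) 1 else 0)
  f <- function(u) stats::dnorm(u) * stats::pnorm(sqrt(2) * c - u)^K
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
}

#' Single-stage critical value for many-to-one comparisons
#'
#' The critical value \code{c} at which a single-stage trial with K
#' experimental arms and a shared control, using known-variance z-statistics,
#' has familywise error-rate exactly \code{alpha} under the global null:
#' \code{P(max_k T_k > c) = alpha} for the equicorrelated (correlation 1/2)
#' multivariate normal. Computed deterministically by one-dimensional
#' Gaussian integration of the conditional factorisation given the shared
#' control.
#'
#' @param K number of experimental arms.
#' @param alpha nominal familywise error-rate.
#' @return numeric critical value.
#' @export
single_stage_critical <- function(K, alpha = 0.05) {
  stopifnot(K >= 1, alpha > 0, alpha < 1)
  if (K == 1L) return(stats::qnorm(1 - alpha))
  stats::uniroot(function(c) dunnett_cdf(c, K) - (1 - alpha),
                 lower = stats::qnorm(1 - alpha),
                 upper = stats::qnorm(1 - alpha / (2 * K)) + 1,
                 tol = 1e-9, extendInt = "upX")$root
}

#' Sample size of the corresponding single-stage design
#'
#' The smallest per-arm group size \code{n} such that a single-stage K-arm
#' trial with critical value from [single_stage_critical()] attains pairwise
#' power at least \code{1 - beta} for the first hypothesis at the LFC
#' (\code{theta1 = delta1}); the pairwise power is the marginal probability
#' \code{P(T_1 >= c)} with \code{T_1 ~ N(delta1 sqrt(n/2)/sigma, 1)}. Returns
#' the total sample size \code{(K + 1) n}. This is the default infeasibility
#' penalty of [mams_objective()].
#'
#' @param K number of experimental arms.
#' @param alpha nominal familywise error-rate.
#' @param beta nominal type-II error rate.
#' @param delta1 interesting treatment effect.
#' @param delta0 uninteresting effect (not needed for the pairwise power;
#'   accepted for interface symmetry).
#' @param sigma response standard deviation.
#' @return integer total sample size \code{(K + 1) n}.
#' @export
single_stage_sample_size <- function(K, alpha = 0.05, beta = 0.1, delta1,
                                     delta0 = 0, sigma = 1) {
  stopifnot(delta1 > 0, sigma > 0)
  cc <- single_stage_critical(K, alpha)
  n <- ceiling(2 * sigma^2 * (cc + stats::qnorm(1 - beta))^2 / delta1^2)
  # guard against ceiling landing one short/long through rounding
  pw <- function(n) 1 - stats::pnorm(cc - delta1 * sqrt(n / 2) / sigma)
  while (pw(n) < 1 - beta) n <- n + 1
  while (n > 1 && pw(n - 1) >= 1 - beta) n <- n - 1
  as.integer((K + 1) * n)
}
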