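#' Joint correlation structure of the z-test statistics
#'
#' With known variance and equal allocation, the interim statistics
#' \code{T[k, j]} over arms k and analyses j are jointly multivariate normal
#' with unit variances and correlations
#' \code{Corr(T[k,j], T[k,j']) = sqrt(j/j')} (same arm, j <= j'),
#' \code{Corr(T[k,j], T[k',j]) = 1/2} (shared control) and
#' \code{Corr(T[k,j], T[k',j']) = sqrt(j/j')/2} for k != k', j <= j'.
#'
#' @param J number of stages.
#' @param K number of experimental arms.
#' @param n group size (immaterial under equal stage sizes; kept for
#'   interface clarity).
#' @return correlation matrix of dimension \code{K*J}, with coordinate
#'   \code{(k, j)} at row \code{(k-1)*J + j}.
#' @export
z_covariance <- function(J, K, n = 1) {
  d <- K * J
  C <- matrix(0, d, d)
  idx <- function(k, j) (k - 1L) * J + j
  for (k1 in seq_len(K)) for (j1 in seq_len(J))
    for (k2 in seq_len(K)) for (j2 in seq_len(J)) {
      r <- sqrt(min(j1, j2) / max(j1, j2))
      if (k1 != k2) r <- r / 2
      C[idx(k1, j1), idx(k2, j2)] <- r
    }
  C
}

#' Enumerate the outcome set of a design
#'
#' Walks the trial-conduct algorithm symbolically, stage by stage: at each
#' analysis every active arm either rejects (statistic at least \code{e[j]}),
#' accepts (below \code{f[j]}; below the shared terminal boundary at stage J)
#' or continues (between the boundaries). Under the simultaneous rule a
#' rejection terminates the whole trial, with continuing arms concluding
#' undecided. Each terminal outcome carries its \code{(omega, psi)} labels
#' and the rectangular region of statistic space that produces it.
#'
#' @param design a validated \code{"mams_design"}.
#' @return list of outcomes, each a list with \code{omega}, \code{psi}
#'   (integer vectors of length K) and \code{lower}, \code{upper}
#'   (\code{K x J} matrices of interval constraints on the statistics,
#'   \code{-Inf}/\code{Inf} where unconstrained).
#' @export
enumerate_outcomes <- function(design) {
  K <- design$K; J <- design$J
  if (K * J > 12L)
    stop(sprintf(
      "outcome enumeration over K*J = %d statistic coordinates is intractable; use Monte Carlo evaluation",
      K * J), call. = FALSE)
  e <- design$e; f <- design$f
  out <- vector("list", 0L)
  recurse <- function(j, active, omega, psi, lower, upper) {
    m <- length(active)
    nch <- if (j < J) 3L else 2L  # R, A (, C)
    grid <- as.matrix(expand.grid(rep(list(seq_len(nch)), m)))
    for (row in seq_len(nrow(grid))) {
      lo <- lower; up <- upper; om <- omega; ps <- psi
      cont <- integer(0); anyrej <- FALSE
      for (i in seq_len(m)) {
        k <- active[i]
        ch <- grid[row, i]
        if (ch == 1L) {            # reject
          lo[k, j] <- e[j]; ps[k] <- 1L; om[k] <- j; anyrej <- TRUE
        } else if (ch == 2L) {     # accept
          up[k, j] <- if (j == J) e[J] else f[j]; om[k] <- j
        } else {                   # continue
          lo[k, j] <- f[j]; up[k, j] <- e[j]; cont <- c(cont, k)
        }
      }
      if (design$rule == "simultaneous" && anyrej) {
        om[cont] <- j
        out[[length(out) + 1L]] <<- list(omega = om, psi = ps,
                                         lower = lo, upper = up)
      } else if (length(cont) == 0L) {
        out[[length(out) + 1L]] <<- list(omega = om, psi = ps,
                                         lower = lo, upper = up)
      } else {
        recurse(j + 1L, cont, om, ps, lo, up)
      }
    }
  }
  recurse(1L, seq_len(K), integer(K), integer(K),
          matrix(-Inf, K, J), matrix(Inf, K, J))
  out
}

# Deterministic multivariate-normal rectangle probability. Miwa quadrature is
# deterministic and accurate to ~1e-11 at the dimensions the enumeration
# guard admits; it warns (benignly) that infinite limits are truncated.
pmvnorm_det <- function(lower, upper, mean, sigma) {
  suppressWarnings(as.numeric(mvtnorm::pmvnorm(
    lower = lower, upper = upper, mean = mean, sigma = sigma,
    algorithm = mvtnorm::Miwa(steps = 512L))))
}

#' Exact outcome probabilities for a z-statistic design
#'
#' For known-variance z-test statistics the interim statistics are jointly
#' multivariate normal, so the probability of each enumerated outcome is a
#' multivariate-normal rectangle probability. Under a true standard deviation
#' \code{sigma_true} different from the presumed \code{sigma}, the statistics
#' have means \code{theta_k sqrt(j n / 2) / sigma} and covariance
#' \code{(sigma_true/sigma)^2} times the standard correlation structure; both
#' effects are applied analytically.
#'
#' @param design a \code{"mams_design"} with \code{statistic = "z"}.
#' @param theta true treatment effect vector (length K).
#' @param sigma_true true response standard deviation.
#' @param outcomes optionally, a pre-computed [enumerate_outcomes()] result.
#' @return list with \code{outcomes} and numeric \code{prob} (one entry per
#'   outcome; their sum is 1 up to the integration tolerance of about 1e-6).
#' @export
exact_outcome_probabilities <- function(design, theta,
                                        sigma_true = design$sigma,
                                        outcomes = NULL) {
  if (design$statistic != "z")
    stop("exact evaluation requires a z-statistic design: the joint law of the t-statistics has no simple form",
         call. = FALSE)
  K <- design$K; J <- design$J; n <- design$n
  stopifnot(length(theta) == K)
  if (is.null(outcomes)) outcomes <- enumerate_outcomes(design)
  C <- z_covariance(J, K, n) * (sigma_true / design$sigma)^2
  mn <- as.vector(t(outer(theta, seq_len(J),
                          function(th, j) th * sqrt(j * n / 2) / design$sigma)))
  # coordinate (k, j) sits at (k-1)*J + j; lower/upper matrices are K x J,
  # so transpose before flattening
  prob <- vapply(outcomes, function(o) {
    lo <- as.vector(t(o$lower)); up <- as.vector(t(o$upper))
    sel <- which(is.finite(lo) | is.finite(up))
    if (!length(sel)) return(1)
    pmvnorm_det(lo[sel], up[sel], mn[sel], C[sel, sel, drop = FALSE])
  }, numeric(1))
  list(outcomes = outcomes, prob = prob)
}

#' Exact operating characteristics of a z-statistic design
#'
#' Non-Monte-Carlo operating characteristics by outcome enumeration and
#' multivariate-normal integration: the familywise error-rate, the
#' per-hypothesis rejection probabilities and the expected sample size under
#' the global null, and the pairwise power and expected sample size under the
#' LFC. Serves as the oracle against which the simulator's z-mode is checked,
#' and as the known-variance design pathway.
#'
#' @inheritParams mams_oc
#' @return a \code{"mams_oc"} with \code{method = "exact"} and zero standard
#'   errors; fields \code{prob_total_null} and \code{prob_total_lfc} hold the
#'   total enumerated probability mass (1 up to integration tolerance).
#' @examples
#' d <- mams_design(K = 1, J = 1, n = 10, e = 1.645, f = 1.645,
#'                  statistic = "z")
#' mams_exact_oc(d, delta1 = 0.5)$fwer  # 1 - pnorm(1.645)
#' @export
mams_exact_oc <- function(design, delta1, delta0 = 0,
                          sigma_true = design$sigma) {
  K <- design$K
  outcomes <- enumerate_outcomes(design)
  p0 <- exact_outcome_probabilities(design, rep(0, K), sigma_true, outcomes)
  p1 <- exact_outcome_probabilities(design, c(delta1, rep(delta0, K - 1L)),
                                    sigma_true, outcomes)
  anyrej <- vapply(outcomes, function(o) sum(o$psi) > 0L, logical(1))
  rej1 <- vapply(outcomes, function(o) o$psi[1L] == 1L, logical(1))
  tn <- vapply(outcomes, function(o) total_sample_size(o$omega, design$n),
               numeric(1))
  pwer <- vapply(seq_len(K), function(k)
    sum(p0$prob[vapply(outcomes, function(o) o$psi[k] == 1L, logical(1))]),
    numeric(1))
  structure(list(
    fwer = sum(p0$prob[anyrej]), power = sum(p1$prob[rej1]), pwer = pwer,
    ess_null = sum(tn * p0$prob), ess_lfc = sum(tn * p1$prob),
    max_n = max_sample_size(design),
    se_fwer = 0, se_power = 0, se_ess_null = 0, se_ess_lfc = 0,
    R = NA_integer_, delta1 = delta1, delta0 = delta0,
    sigma_true = sigma_true, design = design, method = "exact",
    prob_total_null = sum(p0$prob), prob_total_lfc = sum(p1$prob)),
    class = "mams_oc")
}
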