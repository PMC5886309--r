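#' Conduct a single MAMS trial on one replicate of responses
#'
#' Reference (loop-form) implementation of the stage-by-stage trial conduct
#' algorithm: at each analysis j the statistics of all still-active arms are
#' computed; an arm rejects its null if the statistic is at least \code{e[j]},
#' accepts if below \code{f[j]}, and otherwise continues. Under simultaneous
#' stopping the whole trial ends at the first analysis with any rejection
#' (undecided arms conclude without a decision); under separate stopping the
#' trial runs until every hypothesis is decided. The control recruits in every
#' stage the trial runs. At the final analysis the shared terminal boundary
#' forces a decision on every remaining arm.
#'
#' The vectorised [simulate_trials()] is the production path; this function is
#' its element-wise-identical single-replicate counterpart and the natural
#' entry point for inspecting one trial.
#'
#' @param design a validated \code{"mams_design"}.
#' @param X response array \code{n x J x (K+1)} (control is slice 1 of the
#'   third dimension), e.g. from a replicate store or observed data.
#' @return list with \code{omega} (stage at which each arm concluded),
#'   \code{psi} (rejection indicators), \code{total_n} (realised sample
#'   size) and \code{stages_run}.
#' @export
conduct_trial <- function(design, X) {
  K <- design$K; J <- design$J; n <- design$n
  stopifnot(length(dim(X)) == 3L, dim(X)[1L] >= n, dim(X)[2L] >= J,
            dim(X)[3L] == K + 1L)
  omega <- integer(K); psi <- integer(K)
  recruited <- vector("list", K + 1L)  # accumulated responses per arm
  for (a in seq_len(K + 1L)) recruited[[a]] <- numeric(0)
  j <- 0L
  repeat {
    j <- j + 1L
    recruited[[1L]] <- c(recruited[[1L]], X[seq_len(n), j, 1L])
    for (k in seq_len(K))
      if (omega[k] == 0L)
        recruited[[k + 1L]] <- c(recruited[[k + 1L]], X[seq_len(n), j, k + 1L])
    means <- vapply(recruited, mean, numeric(1))
    counts <- lengths(recruited)
    scale <- if (design$statistic == "z") {
      design$sigma
    } else {
      sqrt(pooled_variance(recruited)$sigma2)
    }
    for (k in seq_len(K)) {
      if (omega[k] != 0L) next
      Tkj <- test_statistics(means, counts, scale, arms = k)
      if (Tkj >= design$e[j]) {
        psi[k] <- 1L; omega[k] <- j
      } else if (j == J || Tkj < design$f[j]) {
        omega[k] <- j
      }
    }
    if (design$rule == "simultaneous") {
      if (sum(psi) > 0L || all(omega != 0L)) {
        omega[omega == 0L] <- j
        break
      }
    } else {
      if (all(omega != 0L)) break
    }
  }
  list(omega = omega, psi = psi,
       total_n = total_sample_size(omega, n), stages_run = j)
}

#' Simulate many MAMS trials under a scenario
#'
#' Vectorised trial conduct over the replicates of a common-random-numbers
#' store: all replicates advance stage by stage together, with per-replicate
#' bookkeeping of active arms, frozen cumulative sums for dropped arms, the
#' pooled variance estimate, and the stopping rule. Results are element-wise
#' identical to running [conduct_trial()] replicate by replicate on the
#' realised responses.
#'
#' @param design a validated \code{"mams_design"} with \code{n <= n_max} of
#'   the store.
#' @param store a \code{"mams_store"}.
#' @param scenario a \code{"mams_scenario"} with \code{K} treatment effects.
#' @param reps optional integer vector of replicate indices to simulate
#'   (default: all).
#' @return An object of class \code{"mams_sim"}: list with \code{omega},
#'   \code{psi} (both \code{K x R} integer matrices), \code{total_n}
#'   (length-R realised sample sizes), \code{recruited_n} (the same quantity
#'   accumulated incrementally during conduct), and the design and scenario.
#' @export
simulate_trials <- function(design, store, scenario, reps = NULL) {
  K <- design$K; J <- design$J; n <- design$n
  if (K != store$K || J > store$J)
    stop("design dimensions do not match the replicate store", call. = FALSE)
  if (length(scenario$theta) != K)
    stop("scenario must supply one treatment effect per experimental arm",
         call. = FALSE)
  bs <- store_block_sums(store, n)
  all_reps <- is.null(reps)
  if (all_reps) reps <- seq_len(store$R)
  R <- length(reps)
  mu <- c(scenario$mu0, scenario$mu0 + scenario$theta)
  sT <- scenario$sigma_true

  omega <- matrix(0L, K, R); psi <- matrix(0L, K, R)
  active <- matrix(TRUE, K, R)
  alive <- rep(TRUE, R)
  cums1 <- matrix(0, K + 1L, R)   # frozen at dropout for dropped arms
  cums2 <- matrix(0, K + 1L, R)
  Ncum <- matrix(0L, K + 1L, R)
  recruited_n <- rep(0L, R)

  for (j in seq_len(J)) {
    if (!any(alive)) break
    for (a in seq_len(K + 1L)) {
      rec <- if (a == 1L) alive else alive & active[a - 1L, ]
      if (!any(rec)) next
      s1 <- if (all_reps) bs$S1[j, a, ][rec] else bs$S1[j, a, reps][rec]
      s2 <- if (all_reps) bs$S2[j, a, ][rec] else bs$S2[j, a, reps][rec]
      cums1[a, rec] <- cums1[a, rec] + n * mu[a] + sT * s1
      cums2[a, rec] <- cums2[a, rec] + n * mu[a]^2 + 2 * mu[a] * sT * s1 + sT^2 * s2
      Ncum[a, rec] <- Ncum[a, rec] + n
      recruited_n[rec] <- recruited_n[rec] + n
    }
    if (design$statistic == "t") {
      df <- colSums(Ncum) - (K + 1L)
      if (any(df[alive] < 1L))
        stop("cannot form a t-statistic: pooled degrees of freedom below 1 at an analysis",
             call. = FALSE)
      ss <- colSums(cums2 - cums1^2 / Ncum)
      scale <- sqrt(ss / df)
      if (any(!is.finite(scale[alive]) | scale[alive] <= 0))
        stop("degenerate variance: pooled variance estimate is zero at an analysis",
             call. = FALSE)
    } else {
      scale <- rep(design$sigma, R)
    }
    M <- cums1 / Ncum
    for (k in seq_len(K)) {
      w <- which(alive & active[k, ])
      if (!length(w)) next
      Tk <- (M[k + 1L, w] - M[1L, w]) /
        (scale[w] * sqrt(1 / Ncum[1L, w] + 1 / Ncum[k + 1L, w]))
      rej <- Tk >= design$e[j]
      acc <- !rej & if (j == J) TRUE else Tk < design$f[j]
      psi[k, w[rej]] <- 1L
      omega[k, w[rej | acc]] <- j
      active[k, w[rej | acc]] <- FALSE
    }
    if (design$rule == "simultaneous") {
      stopnow <- alive & (colSums(psi) > 0L | colSums(active) == 0L)
      if (any(stopnow)) {
        undecided <- active & rep(stopnow, each = K)
        omega[undecided] <- j
        active[undecided] <- FALSE
        alive[stopnow] <- FALSE
      }
    } else {
      alive <- alive & colSums(active) > 0L
    }
  }
  structure(list(omega = omega, psi = psi,
                 total_n = total_sample_size(omega, n),
                 recruited_n = recruited_n,
                 design = design, scenario = scenario, R = R),
            class = "mams_sim")
}

#' @export
print.mams_sim <- function(x, ...) {
  cat(sprintf("MAMS simulation: %d trials, K = %d, J = %d, %s rule, %s statistics\n",
              x$R, x$design$K, x$design$J, x$design$rule, x$design$statistic))
  cat(sprintf("  any rejection: %.4f   H01 rejected: %.4f   mean sample size: %.1f\n",
              mean(colSums(x$psi) > 0L), mean(x$psi[1L, ]), mean(x$total_n)))
  invisible(x)
}

#' Simulate trial outcomes from a design
#'
#' \code{simulate} method for \code{"mams_design"}: builds a replicate store
#' of \code{nsim} blocks and runs the design under a scenario (default the
#' global null with the design's presumed standard deviation).
#'
#' @param object a \code{"mams_design"}.
#' @param nsim number of simulated trials.
#' @param seed integer seed for the replicate store.
#' @param scenario a \code{"mams_scenario"}; defaults to the global null.
#' @param ... unused.
#' @return a \code{"mams_sim"} object.
#' @export
simulate.mams_design <- function(object, nsim = 1000, seed = 1,
                                 scenario = NULL, ...) {
  if (is.null(scenario))
    scenario <- null_scenario(object$K, sigma_true = object$sigma)
  store <- mams_store(R = nsim, K = object$K, J = object$J,
                      n_max = object$n, seed = seed)
  simulate_trials(object, store, scenario)
}
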