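#' Evaluate a design's objective on a replicate store
#'
#' Convenience wrapper: Monte Carlo operating characteristics under the
#' objective's scenarios, plus the penalised objective value. Evaluating
#' competing designs on the same store gives common-random-numbers
#' comparisons.
#'
#' @param design a validated \code{"mams_design"}.
#' @param store a \code{"mams_store"}.
#' @param spec a \code{"mams_objective"}.
#' @param reps optional replicate subset.
#' @return list with elements \code{oc} and \code{objective}.
#' @export
evaluate_objective <- function(design, store, spec, reps = NULL) {
  oc <- mams_oc(design, store, spec$delta1, spec$delta0,
                sigma_true = spec$sigma, reps = reps)
  list(oc = oc, objective = objective_value(oc, design, spec))
}

# Sample a CE population: integer n from a rounded clipped normal, continuous
# boundary parameters from clipped normals, with f_j < e_j (j < J) enforced by
# resampling violating rows (pairwise sort as a last resort).
ce_sample <- function(pop, J, mu_n, sd_n, n_range, mu, sd, box_lo, box_up) {
  n <- as.integer(round(pmin(pmax(stats::rnorm(pop, mu_n, sd_n),
                                  n_range[1]), n_range[2])))
  d <- length(mu)
  th <- matrix(stats::rnorm(pop * d, rep(mu, each = pop),
                            rep(sd, each = pop)), pop, d)
  th <- pmin(pmax(th, rep(box_lo, each = pop)), rep(box_up, each = pop))
  if (J > 1L) {
    ei <- seq_len(J - 1L); fi <- (J - 1L) + seq_len(J - 1L)
    for (tries in seq_len(50L)) {
      bad <- which(apply(th, 1L, function(x) any(x[fi] >= x[ei])))
      if (!length(bad)) break
      rep_th <- matrix(stats::rnorm(length(bad) * d, rep(mu, each = length(bad)),
                                    rep(sd, each = length(bad))),
                       length(bad), d)
      th[bad, ] <- pmin(pmax(rep_th, rep(box_lo, each = length(bad))),
                        rep(box_up, each = length(bad)))
    }
    for (r in seq_len(nrow(th)))   # last resort: order the offending pair
      for (jj in seq_len(J - 1L))
        if (th[r, fi[jj]] >= th[r, ei[jj]]) {
          pr <- sort(c(th[r, fi[jj]], th[r, ei[jj]]))
          th[r, fi[jj]] <- pr[1] - 1e-6; th[r, ei[jj]] <- pr[2] + 1e-6
        }
  }
  list(n = n, theta = th)
}

ce_design <- function(K, J, n, th, rule, statistic, sigma) {
  cJ <- th[length(th)]
  if (J > 1L) {
    e <- c(th[seq_len(J - 1L)], cJ)
    f <- c(th[(J - 1L) + seq_len(J - 1L)], cJ)
  } else {
    e <- cJ; f <- cJ
  }
  mams_design(K = K, J = J, n = n, e = e, f = f, rule = rule,
              statistic = statistic, sigma = sigma)
}

#' Optimise a MAMS design by the cross-entropy method
#'
#' Searches jointly over the integer group size \code{n} and the continuous
#' stopping boundaries (stage-wise efficacy and futility boundaries plus one
#' shared terminal boundary, so \code{e[J] = f[J]} by construction) to
#' minimise the penalised objective of [mams_objective()], estimated by
#' Monte Carlo on a fixed replicate store. Every candidate is evaluated on
#' the same store, so comparisons between candidates use common random
#' numbers and are not swamped by simulation noise.
#'
#' The cross-entropy method samples a population of candidates from
#' independent (clipped) normal sampling distributions, ranks them by
#' objective, refits the sampling distribution to the elite fraction with
#' exponential smoothing, and repeats. The incumbent best candidate is
#' retained across iterations, so the best objective in the trace is
#' non-increasing. The search stops when the elite objective spread falls
#' below \code{tol} or after \code{maxit} iterations.
#'
#' @param spec a \code{"mams_objective"}.
#' @param store a \code{"mams_store"} built with \code{n_max >= max(n_range)}.
#' @param K,J trial dimensions (default: the store's).
#' @param rule stopping rule for candidate designs.
#' @param statistic \code{"t"} (default) or \code{"z"}.
#' @param n_range integer interval \code{c(n_lo, n_hi)} for the group size.
#' @param boundary_box list with numeric \code{lower} and \code{upper} bounds
#'   for the continuous parameters, ordered \code{(e_1..e_{J-1},
#'   f_1..f_{J-1}, terminal)}; a sensible default box is used when omitted.
#' @param pop population size per iteration.
#' @param elite_frac elite fraction refit each iteration.
#' @param smooth exponential smoothing factor on the sampling parameters.
#' @param maxit maximum iterations.
#' @param tol elite objective spread at which to declare convergence.
#' @param seed optional integer seed making the search reproducible.
#' @param reps optional replicate subset for candidate evaluation (the
#'   returned design can afterwards be re-evaluated at full R on a fresh
#'   store with [evaluate_objective()]).
#' @return An object of class \code{"mams_optim"}: the best \code{design},
#'   its \code{objective} and \code{oc}, a per-iteration \code{trace}
#'   data frame (best/mean objective, elite spread, sampling parameters),
#'   flags \code{converged} and \code{infeasible}, and the call settings.
#' @export
mams_optimise <- function(spec, store, K = store$K, J = store$J,
                          rule = c("simultaneous", "separate"),
                          statistic = c("t", "z"),
                          n_range = c(2L, store$n_max),
                          boundary_box = NULL,
                          pop = 1000L, elite_frac = 0.1, smooth = 0.7,
                          maxit = 50L, tol = 1e-3, seed = NULL, reps = NULL) {
  rule <- match.arg(rule)
  statistic <- match.arg(statistic)
  stopifnot(inherits(spec, "mams_objective"),
            n_range[1] >= 1, n_range[2] <= store$n_max,
            n_range[1] <= n_range[2])
  if (!is.null(seed)) set.seed(seed)
  d <- 2L * (J - 1L) + 1L
  if (is.null(boundary_box))
    boundary_box <- list(lower = c(rep(0, J - 1L), rep(-3, J - 1L), 0),
                         upper = rep(6, d))
  stopifnot(length(boundary_box$lower) == d, length(boundary_box$upper) == d)
  P <- objective_penalty(spec, K)
  spec$penalty <- P

  mu_n <- mean(n_range); sd_n <- max(1, diff(n_range) / 2)
  mu <- (boundary_box$lower + boundary_box$upper) / 2
  sd <- (boundary_box$upper - boundary_box$lower) / 2
  n_elite <- max(2L, ceiling(pop * elite_frac))

  best <- NULL
  trace <- vector("list", maxit)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    cand <- ce_sample(pop, J, mu_n, sd_n, n_range, mu, sd,
                      boundary_box$lower, boundary_box$upper)
    obj <- numeric(pop)
    ocs <- vector("list", pop)
    for (i in seq_len(pop)) {
      des <- ce_design(K, J, cand$n[i], cand$theta[i, ], rule, statistic,
                       spec$sigma)
      ev <- evaluate_objective(des, store, spec, reps)
      obj[i] <- ev$objective
      ocs[[i]] <- ev$oc
    }
    # inject the incumbent so elite retention makes the best trace monotone
    all_n <- cand$n; all_th <- cand$theta; all_obj <- obj
    if (!is.null(best)) {
      all_n <- c(all_n, best$n); all_th <- rbind(all_th, best$theta)
      all_obj <- c(all_obj, best$objective)
    }
    ord <- order(all_obj)
    el <- ord[seq_len(n_elite)]
    if (is.null(best) || all_obj[ord[1L]] < best$objective) {
      i1 <- ord[1L]
      best <- list(n = all_n[i1], theta = all_th[i1, ],
                   objective = all_obj[i1],
                   oc = if (i1 <= pop) ocs[[i1]] else best$oc)
    }
    spread <- all_obj[el[n_elite]] - all_obj[el[1L]]
    mu_n <- smooth * mean(all_n[el]) + (1 - smooth) * mu_n
    sd_n <- max(smooth * stats::sd(all_n[el]) + (1 - smooth) * sd_n, 0.1)
    mu <- smooth * colMeans(all_th[el, , drop = FALSE]) + (1 - smooth) * mu
    sd <- pmax(smooth * apply(all_th[el, , drop = FALSE], 2L, stats::sd) +
                 (1 - smooth) * sd, 1e-3)
    trace[[it]] <- data.frame(iteration = it, best = best$objective,
                              mean = mean(obj), elite_spread = spread,
                              mu_n = mu_n, sd_n = sd_n)
    if (spread < tol) { converged <- TRUE; break }
  }
  trace <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  design <- ce_design(K, J, best$n, best$theta, rule, statistic, spec$sigma)
  oc <- best$oc
  infeasible <- oc$fwer > spec$alpha || (1 - oc$power) > spec$beta
  structure(list(design = design, objective = best$objective, oc = oc,
                 trace = trace, converged = converged,
                 infeasible = infeasible, spec = spec, rule = rule,
                 statistic = statistic, penalty = P, seed = seed),
            class = "mams_optim")
}

#' @export
print.mams_optim <- function(x, ...) {
  cat(sprintf("Cross-entropy MAMS design search (%d iterations, %s)\n",
              max(x$trace$iteration),
              if (x$converged) "converged" else "iteration limit"))
  cat(sprintf("  best objective: %.4f%s\n", x$objective,
              if (x$infeasible) "  [flagged infeasible]" else ""))
  print(x$design)
  invisible(x)
}

#' @export
summary.mams_optim <- function(object, ...) {
  cat(sprintf("Best objective %.4f after %d iterations (%s)\n",
              object$objective, max(object$trace$iteration),
              if (object$converged) "converged" else "iteration limit"))
  print(object$design)
  print(object$oc)
  cat("Search trace (last rows):\n")
  print(utils::tail(object$trace, 5L), row.names = FALSE)
  invisible(object)
}

#' @export
plot.mams_optim <- function(x, ...) {
  graphics::plot(x$trace$iteration, x$trace$mean, type = "l", lty = 2,
                 xlab = "iteration", ylab = "objective",
                 ylim = range(x$trace$best, x$trace$mean), ...)
  graphics::lines(x$trace$iteration, x$trace$best, lwd = 2)
  graphics::legend("topright", legend = c("population mean", "incumbent best"),
                   lty = c(2, 1), lwd = c(1, 2), bty = "n")
  invisible(x)
}
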