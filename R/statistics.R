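#' Pooled variance estimate at an interim analysis
#'
#' The variance estimate at analysis j pools the squared deviations of every
#' patient recruited up to that analysis — including patients in arms dropped
#' before stage j — each measured about their own arm's cumulative mean
#' (frozen at dropout for dropped arms):
#' \deqn{\hat\sigma_j^2 = \frac{\sum_k \sum_i (X_{ki} - \bar X_{k})^2}
#'                             {\sum_k N_{k} - (K+1)}.}
#' Arms recruit nothing after dropout, so absent patients simply contribute no
#' terms.
#'
#' @param responses list with one numeric vector per arm (control first):
#'   all responses recruited in that arm up to the analysis.
#' @return list with \code{sigma2} (the pooled variance), \code{df}
#'   (\code{sum(N_k) - (K+1)}), and \code{N} (per-arm counts).
#' @examples
#' pooled_variance(list(c(0, 2), c(1, 3)))  # sigma2 = 2, df = 2
#' @export
pooled_variance <- function(responses) {
  stopifnot(is.list(responses), length(responses) >= 2L)
  N <- lengths(responses)
  if (any(N < 1L))
    stop("every arm must have recruited at least one patient", call. = FALSE)
  df <- sum(N) - length(responses)
  if (df < 1L)
    stop(sprintf(
      "cannot form a t-statistic: pooled degrees of freedom %d < 1", df),
      call. = FALSE)
  ss <- sum(vapply(responses, function(x) sum((x - mean(x))^2), numeric(1)))
  list(sigma2 = ss / df, df = as.integer(df), N = as.integer(N))
}

#' Interim test statistics
#'
#' For each experimental arm k, the statistic comparing it to the shared
#' control at an analysis is
#' \deqn{T_k = \frac{\bar X_k - \bar X_0}{s \sqrt{1/N_0 + 1/N_k}},}
#' where \code{s} is either the presumed standard deviation (z-test) or the
#' pooled estimate from [pooled_variance()] (t-test).
#'
#' @param means numeric vector of cumulative arm means, control first.
#' @param counts integer vector of cumulative arm sample sizes, control first.
#' @param scale positive scale \code{s}.
#' @param arms indices (into 1..K) of the experimental arms to report;
#'   defaults to all.
#' @return numeric vector of statistics, one per requested arm.
#' @export
test_statistics <- function(means, counts, scale, arms = NULL) {
  stopifnot(length(means) == length(counts), length(means) >= 2L)
  if (!is.finite(scale) || scale <= 0)
    stop("degenerate variance: statistic scale must be positive (all responses identical?)",
         call. = FALSE)
  if (any(counts < 1L))
    stop("all arms must have at least one observation", call. = FALSE)
  K <- length(means) - 1L
  if (is.null(arms)) arms <- seq_len(K)
  (means[arms + 1L] - means[1L]) /
    (scale * sqrt(1 / counts[1L] + 1 / counts[arms + 1L]))
}

#' Quantile substitution of stopping boundaries
#'
#' Maps known-variance (normal) boundaries to t-distribution boundaries with
#' equal upper-tail probability: \code{b' = qt(pnorm(b), df)}. Because t tails
#' are heavier than normal tails, \code{|b'| >= |b|} for finite \code{b} and
#' \code{df}, and \code{b' -> b} as \code{df -> Inf}. Infinite boundaries pass
#' through unchanged.
#'
#' @param b numeric vector of boundaries.
#' @param df degrees of freedom, recycled against \code{b}; each must be
#'   >= 1.
#' @return adjusted boundaries, same length as \code{b}.
#' @seealso [quantile_substitute_design()]
#' @export
quantile_substitute <- function(b, df) {
  stopifnot(length(df) >= 1L)
  df <- rep_len(df, length(b))
  if (any(df < 1))
    stop("quantile substitution needs at least 1 degree of freedom per stage",
         call. = FALSE)
  out <- b
  fin <- is.finite(b)
  out[fin] <- stats::qt(stats::pnorm(b[fin]), df = df[fin])
  out
}

#' Design-time degrees of freedom for quantile substitution
#'
#' At analysis j, assuming no arm has been dropped, every one of the
#' \code{K + 1} arms has recruited \code{j * n} patients, so the pooled
#' variance has \code{(K + 1) * (j * n - 1)} degrees of freedom.
#'
#' @param K,J,n design dimensions.
#' @return integer vector of length J.
#' @export
quantile_substitution_df <- function(K, J, n) {
  K <- as.integer(K)
  (K + 1L) * (seq_len(J) * as.integer(n)) - (K + 1L)
}

#' Apply quantile substitution to a whole design
#'
#' Returns a copy of the design whose efficacy and futility boundaries have
#' been replaced by their t-distribution equivalents at the design-time
#' degrees of freedom (no dropout assumed), and whose statistic is set to
#' \code{"t"}. This is the boundary-adjustment route for running a
#' known-variance design with t-test statistics.
#'
#' @param design a \code{"mams_design"} (typically with normal-theory
#'   boundaries).
#' @param df optional per-stage degrees of freedom overriding the design-time
#'   default from [quantile_substitution_df()].
#' @return an adjusted \code{"mams_design"} with \code{statistic = "t"}.
#' @export
quantile_substitute_design <- function(design, df = NULL) {
  if (is.null(df)) df <- quantile_substitution_df(design$K, design$J, design$n)
  stopifnot(length(df) == design$J)
  design$e <- quantile_substitute(design$e, df)
  design$f <- quantile_substitute(design$f, df)
  design$statistic <- "t"
  validate_design(design)
}
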