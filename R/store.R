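#' Build a common-random-numbers replicate store
#'
#' Generates \code{R} independent replicate blocks of standard-normal deviates
#' for \code{K + 1} arms over \code{J} stages with up to \code{n_max} patients
#' per arm per stage, from a single integer seed. Responses for a scenario
#' with mean \code{mu} and true standard deviation \code{sigma_true} are
#' realised lazily as \code{mu + sigma_true * Z}, so one store serves the
#' global null, the LFC and any true variance. For a group size
#' \code{n <= n_max} the first \code{n} deviates of each arm-stage block are
#' used, so operating characteristics of candidate designs with different
#' \code{n} share common random numbers — the variance-reduction device that
#' makes objective comparisons between candidate designs meaningful at
#' moderate \code{R}.
#'
#' The store is generated in replicate-major order with R's default
#' Mersenne-Twister generator, so rebuilding with a larger \code{R} and the
#' same seed reproduces the original replicates bit-for-bit and appends new
#' ones.
#'
#' @param R number of replicate blocks.
#' @param K number of experimental arms.
#' @param J maximum number of stages.
#' @param n_max largest per-arm per-stage group size the store supports.
#' @param seed integer seed.
#' @param max_bytes memory budget for the deviate array (default 4 GiB).
#' @return An object of class \code{"mams_store"} with fields \code{Z} (array
#'   \code{n_max x J x (K+1) x R}), \code{R}, \code{K}, \code{J},
#'   \code{n_max}, \code{seed}, and an internal cache of block sums.
#' @examples
#' st <- mams_store(R = 100, K = 2, J = 2, n_max = 10, seed = 1)
#' @export
mams_store <- function(R, K, J, n_max, seed, max_bytes = 4e9) {
  stopifnot(R >= 1, K >= 1, J >= 1, n_max >= 1)
  bytes <- 8 * R * (K + 1) * J * n_max
  if (bytes > max_bytes)
    stop(sprintf(
      "store of %d replicates x %d arms x %d stages x %d patients needs %.1f GiB, over the %.1f GiB budget; reduce R or n_max, or evaluate in chunks",
      R, K + 1, J, n_max, bytes / 2^30, max_bytes / 2^30), call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  # replicate index last + filling column-major => replicate-major draw order
  Z <- array(stats::rnorm(n_max * J * (K + 1) * R),
             dim = c(n_max, J, K + 1L, R))
  structure(list(Z = Z, R = as.integer(R), K = as.integer(K),
                 J = as.integer(J), n_max = as.integer(n_max),
                 seed = as.integer(seed), cache = new.env(parent = emptyenv())),
            class = "mams_store")
}

#' @export
print.mams_store <- function(x, ...) {
  cat(sprintf(
    "MAMS replicate store: R = %d replicates, %d arms x %d stages x up to %d patients (seed %d)\n",
    x$R, x$K + 1L, x$J, x$n_max, x$seed))
  invisible(x)
}

# Per-block sums of the first n standard-normal deviates and their squares.
# Returns list(S1, S2), each an array J x (K+1) x R. Cached by n: the trial
# simulator only needs per-arm-stage block sums and sums of squares, never the
# individual responses.
store_block_sums <- function(store, n) {
  stopifnot(n >= 1, n == round(n))
  if (n > store$n_max)
    stop(sprintf("group size n = %d exceeds the store's n_max = %d",
                 n, store$n_max), call. = FALSE)
  key <- as.character(n)
  hit <- store$cache[[key]]
  if (!is.null(hit)) return(hit)
  Zn <- store$Z[seq_len(n), , , , drop = FALSE]
  S1 <- colSums(Zn)          # J x (K+1) x R
  S2 <- colSums(Zn * Zn)
  out <- list(S1 = S1, S2 = S2)
  store$cache[[key]] <- out
  out
}

# Raw responses for one replicate under a scenario: array n x J x (K+1),
# X = mu_arm + sigma_true * Z. Arm 1 of the array is the control.
store_responses <- function(store, r, n, scenario) {
  stopifnot(r >= 1, r <= store$R)
  if (length(scenario$theta) != store$K)
    stop("scenario has wrong number of treatment effects for this store",
         call. = FALSE)
  mu <- c(scenario$mu0, scenario$mu0 + scenario$theta)
  Z <- store$Z[seq_len(n), , , r, drop = FALSE]
  dim(Z) <- c(n, store$J, store$K + 1L)
  X <- Z * scenario$sigma_true
  for (k in seq_len(store$K + 1L)) X[, , k] <- X[, , k] + mu[k]
  X
}
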