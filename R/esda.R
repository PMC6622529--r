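#' Global Moran's I with permutation inference
#'
#' \deqn{I = \frac{n}{S_0} \frac{\sum_i \sum_j w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with z the mean-deviated values and S_0 the sum of all weights.  The
#' expectation under the randomization null is -1/(n-1); the pseudo p-value
#' comes from random total permutations of the value vector under the given
#' seed, \code{p = (greater_or_equal + 1) / (permutations + 1)} on the side
#' of the observed statistic (one-sided, toward the alternative indicated
#' by the sign of I - E[I]).
#'
#' @param values numeric vector of length n (non-constant).
#' @param w a [weights_matrix].
#' @param permutations number of random permutations (default 999).
#' @param seed RNG seed for the permutations (required for reproducible
#'   pipeline runs).
#' @return A list of class \code{"moran_result"}: I, expected, p_perm,
#'   permutations, seed, and the permutation replicates in \code{sim}.
#' @export
morans_i <- function(values, w, permutations = 999, seed = 1L) {
  stopifnot(inherits(w, "weights_matrix"), length(values) == w$n, w$n >= 3)
  if (stats::sd(values) == 0)
    stop("degenerate variance: values are constant")
  I_obs <- moran_stat(values, w)
  expected <- -1 / (w$n - 1)
  sim <- numeric(permutations)
  if (permutations > 0) {
    rng <- local_rng(seed)
    for (b in seq_len(permutations))
      sim[b] <- moran_stat(values[rng$sample(w$n)], w)
  }
  extreme <- if (I_obs >= expected) sum(sim >= I_obs) else sum(sim <= I_obs)
  structure(list(I = I_obs, expected = expected,
                 p_perm = (extreme + 1) / (permutations + 1),
                 permutations = permutations, seed = seed, sim = sim),
            class = "moran_result")
}

moran_stat <- function(values, w) {
  z <- values - mean(values)
  lag <- spatial_lag(w, z)
  s0 <- sum(unlist(w$weights))
  (w$n / s0) * sum(z * lag) / sum(z^2)
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("<Moran's I = %.4f (E[I] = %.4f), pseudo p = %.4g, %d permutations>\n",
              x$I, x$expected, x$p_perm, x$permutations))
  invisible(x)
}

#' Local indicators of spatial autocorrelation (LISA)
#'
#' Per-unit local Moran statistics
#' \deqn{I_i = \frac{z_i}{m_2} \sum_j w_{ij} z_j, \qquad m_2 = \sum_i z_i^2 / n,}
#' whose mean over units equals the global I under row-standardized
#' weights.  Cluster quadrants come from the signs of the standardized
#' value and its spatial lag: HH (high surrounded by high), LL, HL
#' (high surrounded by low), LH.  Significance is assessed by conditional
#' permutation: unit i's value is held fixed while the remaining n-1 values
#' are randomly reassigned to its neighbors.  No multiplicity correction is
#' applied by default (standard LISA-map practice); set
#' \code{fdr = TRUE} for Benjamini-Hochberg adjusted significance.
#'
#' @param values numeric vector of length n (non-constant).
#' @param w a [weights_matrix], typically row-standardized.
#' @param permutations conditional permutations per unit (default 999).
#' @param seed RNG seed.
#' @param alpha significance level for the \code{significant} flag
#'   (default 0.05).
#' @param fdr apply Benjamini-Hochberg correction before flagging
#'   significance (default FALSE).
#' @return A data.frame of class \code{"lisa_result"} with columns
#'   unit_id, local_I, quadrant, p_perm, significant.
#' @export
lisa <- function(values, w, permutations = 999, seed = 1L, alpha = 0.05,
                 fdr = FALSE) {
  stopifnot(inherits(w, "weights_matrix"), length(values) == w$n, w$n >= 3)
  if (stats::sd(values) == 0)
    stop("degenerate variance: values are constant")
  n <- w$n
  z <- values - mean(values)
  m2 <- sum(z^2) / n
  lag <- spatial_lag(w, z)
  local_I <- z * lag / m2
  quadrant <- ifelse(z >= 0,
                     ifelse(lag >= 0, "HH", "HL"),
                     ifelse(lag >= 0, "LH", "LL"))
  p_perm <- rep(NA_real_, n)
  rng <- local_rng(seed)
  for (i in seq_len(n)) {
    nb <- w$neighbours[[i]]
    if (length(nb) == 0) next
    wt <- w$weights[[i]]
    others <- z[-i]
    k <- length(nb)
    sim <- numeric(permutations)
    for (b in seq_len(permutations)) {
      picked <- others[rng$sample(n - 1L, k)]
      sim[b] <- z[i] * sum(wt * picked) / m2
    }
    extreme <- if (local_I[i] >= 0) sum(sim >= local_I[i])
               else sum(sim <= local_I[i])
    p_perm[i] <- (extreme + 1) / (permutations + 1)
  }
  p_used <- if (fdr) stats::p.adjust(p_perm, method = "BH") else p_perm
  out <- data.frame(unit_id = w$ids, local_I = local_I, quadrant = quadrant,
                    p_perm = p_perm,
                    significant = !is.na(p_used) & p_used <= alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("lisa_result", "data.frame")
  out
}

# Isolated RNG sub-stream so permutation draws never disturb (or depend on)
# the caller's global RNG state.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  env$sample <- function(n, k = n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- sample.int(n, k)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  env
}
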