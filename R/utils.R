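## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the global RNG state, seeds it, evaluates `code`, and restores the
#' previous state on exit, so seeded operations never perturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic integer hash (Lehmer-style congruential mix) so that every
#' randomized sub-task (e.g. one k-means trial) gets its own stream derived
#' from a single user-supplied seed. Always in `[1, 2^31 - 2]`.
#'
#' @param seed master integer seed.
#' @param ... further integers distinguishing the sub-task.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(17, 8, 3) == derive_seed(17, 8, 3)
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (v in c(...)) {
    h <- (h * 48271 + as.numeric(v) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Used to compare demarcated bins with planted population labels.
#'
#' @param a,b vectors of equal length; labels may be of any atomic type.
#' @return A number in `[-1, 1]`; 1 means identical partitions.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1) # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}
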