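#' Derive a child seed from a run seed
#'
#' All top-level stochastic entry points accept a single integer `seed`.
#' Sub-tasks (cohorts, conditions, replicate simulations) derive their own
#' seeds deterministically from it with this helper, so that one run seed
#' reproduces every stream while keeping streams for different stages
#' decoupled.  The result always fits in a 32-bit signed integer.
#'
#' @param seed Integer run seed (or `NULL` for no seeding).
#' @param tag Character or integer label of the sub-stream.
#' @return An integer seed, or `NULL` if `seed` is `NULL`.
#' @export
#' @examples
#' derive_seed(1L, "cohort-FC50")
derive_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  tag <- as.character(tag)
  # small string hash (djb2), folded into [0, 2^31 - 2]
  h <- 5381
  for (code in utf8ToInt(tag)) h <- (h * 33 + code) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483646 + 1)
}

# Seed the global RNG if a seed is given; restore is not attempted --
# callers own the ambient stream, as is idiomatic in R simulation code.
.seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
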