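# Seed-stream management.
#
# A single top-level seed spawns independent per-purpose sub-seeds so that,
# e.g., changing p perturbs genotype draws but not noise draws. Streams are
# derived with a multiplicative-congruential step on the 2^31 - 1 field,
# keeping every derived seed a valid 32-bit integer.

.STREAM_IDS <- c(
  frequencies = 1L, genotypes = 2L, effects = 3L, noise = 4L,
  causal = 5L, covariates = 6L, shuffle = 7L, test_genotypes = 8L,
  test_noise = 9L, std_genotypes = 10L, std_noise = 11L, replicate = 12L
)

#' Derive a per-purpose sub-seed from a top-level seed
#'
#' @param seed integer top-level seed.
#' @param purpose stream name, one of the entries of `names(.STREAM_IDS)`
#'   (frequencies, genotypes, effects, noise, causal, covariates, shuffle,
#'   test_genotypes, test_noise, std_genotypes, std_noise, replicate).
#' @param index optional nonnegative integer offsetting the stream (e.g.
#'   replicate number or subset size), default 0.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
stream_seed <- function(seed, purpose, index = 0L) {
  id <- .STREAM_IDS[[match.arg(purpose, names(.STREAM_IDS))]]
  m <- 2147483647  # 2^31 - 1, prime
  s <- (as.double(seed) %% m + 1) * 48271 %% m
  s <- (s * 69621 + id * 2654435761 %% m) %% m
  s <- (s * 48271 + (as.double(index) %% m) * 40692) %% m
  as.integer(s %% (m - 1) + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so library code never
#' clobbers the user's random stream. With `seed = NULL` the expression
#' uses (and advances) the session RNG.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
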