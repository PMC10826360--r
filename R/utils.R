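# Internal helpers: seeded evaluation and deterministic seed derivation.

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# state; a NULL seed uses (and advances) the current stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

# Spawn `n` independent stage seeds from one master seed.
spawnSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Derive a reproducible seed from a master seed and a label
#'
#' Folds the master seed and an arbitrary set of key components (condition
#' fields, replicate index, stage name, ...) into an integer seed below
#' 2^31 via a polynomial rolling hash. Because the hash depends only on the
#' key values, adding conditions to a grid never perturbs the seeds of
#' existing cells.
#'
#' @param masterSeed integer master seed.
#' @param ... key components; coerced to character and concatenated.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' deriveSeed(1, "empirical_resample", 1000, "randomized", 1.15, 3)
deriveSeed <- function(masterSeed, ...) {
  key <- paste(c(format(masterSeed), vapply(list(...), function(x)
    paste(format(x, digits = 15, scientific = FALSE, trim = TRUE),
          collapse = "\1"), character(1))), collapse = "\1")
  m <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% m
  as.integer(h %% (m - 2) + 1)
}

# Stable two-key descending order: prevalence first, then total abundance,
# then original position.
.orderDesc2 <- function(key1, key2) {
  order(-key1, -key2, seq_along(key1))
}
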