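## Counter-based seed splitting: every stochastic operation in the package
## derives its own child seed from one user-facing integer seed plus a string
## key, so modules can be re-run independently yet reproduce a full pipeline
## run bit for bit.

#' Derive a child seed from a master seed and a key
#'
#' Implements a small counter-based splitting scheme: the key is hashed
#' (FNV-1a, folded to 31 bits) and combined with the master seed by a
#' Lehmer-style multiplicative step. All randomness in the package flows
#' through this function, so a single integer seed determines every
#' synthetic image, EM initialization and permutation draw.
#'
#' @param seed integer master seed.
#' @param key character scalar naming the consumer (e.g. `"gen_ion_map/Li"`).
#' @return An integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
split_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(key), length(key) == 1)
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  m <- 2147483647
  x <- (abs(seed) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + h) %% m
  as.integer(x + 1L)
}

## Evaluate expr under a local RNG state seeded from (seed, key); the caller's
## RNG stream is untouched.
with_split_seed <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(split_seed(seed, key))
  expr
}
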