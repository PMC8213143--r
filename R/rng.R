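# Deterministic seed derivation. Subject-level seeds are derived from the
# master seed by an LCG-style 32-bit integer mix so that inserting or removing
# one subject never perturbs the random stream of another. All arithmetic is
# done in doubles mod 2^32 (exact: intermediates stay below 2^53).

MOD32 <- 2^32

mix32 <- function(x) {
  x <- x %% MOD32
  # two rounds of a full-period LCG (Numerical Recipes constants), then a
  # multiplicative scramble; enough to decorrelate consecutive inputs before
  # the value is handed to R's Mersenne-Twister as a seed
  for (k in 1:2) x <- (mulmod32(x, 1664525) + 1013904223) %% MOD32
  mulmod32(x, 2654435761)
}

# (a*b) mod 2^32 without exceeding 2^53: split a into 16-bit halves
mulmod32 <- function(a, b) {
  a <- a %% MOD32; b <- b %% MOD32
  hi <- floor(a / 65536)
  lo <- a - hi * 65536
  (((hi * b) %% 65536) * 65536 + lo * b) %% MOD32
}

#' Derive a child seed from a master seed and an index
#'
#' Stable integer mix used for per-subject (and per-contrast) seeding:
#' the stream of subject \code{i} depends only on \code{(master, i)}, so
#' adding or removing subjects leaves all other subjects' data unchanged.
#'
#' @param master integer master seed.
#' @param index non-negative integer (subject index, contrast index, ...).
#'   May be a vector.
#' @return integer seed(s) in \code{[0, 2^31)}.
#' @export
deriveSeed <- function(master, index) {
  vapply(index, function(i) {
    s <- mix32(mix32(master %% MOD32) + i + 1)
    as.integer(floor(s / 2))  # < 2^31, valid R seed
  }, integer(1))
}

# Run `expr` under a given seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
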