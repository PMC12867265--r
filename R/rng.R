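# Seeded-RNG scaffolding. Every stochastic routine takes an explicit seed and
# runs under a locally scoped RNG state, so library calls never disturb (or
# depend on) the caller's random stream.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# Deterministic child seed derived from a master seed and a context string;
# keeps all derived seeds inside 32-bit integer range.
derive_seed <- function(seed, what) {
  h <- sum(utf8ToInt(as.character(what)) * seq_along(utf8ToInt(as.character(what))))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 13) %% 2147483629)
}
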