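# Small shared helpers.

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-stage sub-seed, kept below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 100003) %% 2147483647)
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# sample() without the length-1 surprise
sample_safe <- function(x, k) x[sample.int(length(x), k)]

hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

`%||%` <- rlang::`%||%`
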