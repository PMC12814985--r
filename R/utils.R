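# Internal helpers shared across modules.

# Derive a child RNG seed from a parent seed and a stream index.
# Linear-congruential step keeps everything inside 32-bit integer range and
# all intermediate products below 2^53, so the arithmetic is exact in doubles.
child_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647)
  as.integer((s * 16807 + as.double(stream)) %% 2147483647)
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
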