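# Internal helpers: seeded substreams and RNG hygiene.

# Derive a reproducible 31-bit substream seed from a master seed and a set of
# integer/string codes (stage, participant, round ...). Plain modular
# arithmetic, stable across platforms and package versions.
substream_seed <- function(master, ...) {
  codes <- list(...)
  h <- as.double(master %% 2147483647L)
  for (code in codes) {
    if (is.character(code)) {
      code <- sum(utf8ToInt(code) * seq_along(utf8ToInt(code)))
    }
    h <- (h * 48271 + as.double(code) * 9973 + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a local RNG state; global .Random.seed is restored.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
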