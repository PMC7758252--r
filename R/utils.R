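# Internal helpers: deterministic seed derivation and scoped RNG use.

# Mix a master seed with a named stream and an index into a 31-bit seed.
# Plain modular hash; stable across platforms (all arithmetic < 2^53).
derive_seed <- function(master, stream, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(master) %% m
  for (ch in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + ch) %% m
  }
  h <- (h * 131071 + as.numeric(index) * 2654435) %% m
  as.integer(h)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared argument check
assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %s", name, min))
  }
  invisible(x)
}
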