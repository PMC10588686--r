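# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never clobber the
# user's random stream. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a stream index, kept within the
# 32-bit integer range R requires.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + 7919 * stream) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dominet <- function(...) stop(..., call. = FALSE)

is_count_matrix <- function(A, tol = 1e-8) {
  is.numeric(A) && all(is.finite(A)) && all(A >= 0) &&
    all(abs(A - round(A)) < tol)
}
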