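# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# With seed = NULL the ambient RNG stream is used unchanged.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  code
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Number of sampling steps spanned by a period `T` at interval `dt`;
# errors unless T is a positive integer multiple of dt (tolerance 1e-9).
period_steps <- function(T, dt) {
  if (!is_scalar_number(T) || !is_scalar_number(dt) || T <= 0 || dt <= 0) {
    err_invalid("period and dt must be positive finite scalars")
  }
  k <- round(T / dt)
  if (k < 1 || abs(T - k * dt) > 1e-9 * max(1, abs(T))) {
    err_invalid(sprintf("period %g s is not a positive multiple of dt = %g s", T, dt))
  }
  as.integer(k)
}
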