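# internal helpers shared across modules

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

clamp01 <- function(x) clamp(x, 0, 1)

# round halves away from zero (base round() rounds halves to even)
round_half_up <- function(x) floor(x + 0.5)

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# derive a reproducible sub-seed below 2^31 from a user seed and a stream index
derive_seed <- function(seed, stream) {
  (as.double(seed) * 2654435761 + as.double(stream) * 40503) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
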