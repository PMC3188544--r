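# Internal helpers: seeded RNG scoping and sub-seed derivation.

# Required for data.table's non-standard evaluation inside package code.
.datatable.aware <- TRUE

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# A NULL seed means "use the ambient stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
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

# Deterministic sub-seed for consumer `i` of a run-level seed.  Arithmetic in
# doubles (exact below 2^53), reduced into the 32-bit integer range.
derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) %% 2147483647 * 1009 + as.double(i) * 7919) %% 2147483629)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
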