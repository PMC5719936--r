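#' @keywords internal
"_PACKAGE"

# Internal validation helpers. All user-facing errors name the offending
# field or gene so failures in pipeline runs are actionable.

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != as.integer(x) || x < min)
    abort_field(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_scale <- function(x, field) {
  if (length(x) != 1L || !is.finite(x) || x < 0)
    abort_field(field, "must be a single nonnegative number")
  as.numeric(x)
}

check_prob <- function(x, field) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    abort_field(field, "must be a probability in [0, 1]")
  as.numeric(x)
}

check_stage_grid <- function(x, field) {
  if (length(x) < 3L || anyNA(x) || any(!is.finite(x)))
    abort_field(field, "needs at least 3 finite time points")
  if (any(diff(x) <= 0))
    abort_field(field, "hours must be strictly increasing")
  as.numeric(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; seeds are kept below 2^31 - 1 for portability.
with_seed <- function(seed, expr) {
  seed <- as.integer(seed %% .Machine$integer.max)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation: distinct streams per generator stage.
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 48271 + offset) %% 2147483629
}
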