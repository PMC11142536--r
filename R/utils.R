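# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of per-item sub-seeds from one master seed.  Drawn inside
# the master stream so regeneration is bit-identical.
derive_seeds <- function(n) {
  if (n == 0L) return(integer(0))
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

assert_count <- function(x, field, min = 1) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
      x != round(x)) {
    stop_field(field, sprintf("must be a single integer >= %s", min))
  }
  as.integer(x)
}

assert_number <- function(x, field, min = -Inf, max = Inf,
                          open_min = FALSE, open_max = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) && is.finite(x) &&
    (if (open_min) x > min else x >= min) &&
    (if (open_max) x < max else x <= max)
  if (!ok) {
    stop_field(field, sprintf("must be a single number in %s%s, %s%s",
                              if (open_min) "(" else "[", min, max,
                              if (open_max) ")" else "]"))
  }
  as.numeric(x)
}

assert_fraction <- function(x, field, open = FALSE) {
  assert_number(x, field, min = 0, max = 1, open_min = open, open_max = open)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
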