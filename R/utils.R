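# internal helpers: argument checks and deterministic seed derivation

# session cache for deterministic noiseless curve simulations
.simCache <- new.env(parent = emptyenv())

.assertScalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  if (positive && x <= 0)
    stop("'", name, "' must be > 0", call. = FALSE)
  if (nonneg && x < 0)
    stop("'", name, "' must be >= 0", call. = FALSE)
  invisible(x)
}

# per-item seed for batches: deterministic, independent of batch size, and
# kept inside the 32-bit integer range R requires of set.seed()
.deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}
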