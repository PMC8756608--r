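# Internal helpers shared across modules.

# Classed errors so callers can distinguish invalid designs, invalid
# comparison contexts, and data problems programmatically.
lr_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("lossrange_", class), "lossrange_error")))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. `seed = NULL` leaves the global stream
# untouched (and advances it).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Keys for matching gambles across conditions; rounding guards against
# floating-point jitter in equally spaced grids.
gamble_key <- function(gain, loss) {
  paste(round(gain, 9), round(loss, 9), sep = "_")
}
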