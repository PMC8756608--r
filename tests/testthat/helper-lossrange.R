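# Shared fixtures, built in code.

# Small 5-level 2x2 design whose grids share every second level.
small_design <- function() range_design(20, 40, n_levels = 5)

# Fast fit specification for unit tests (fewer starts than the default 10).
quick_spec <- function(seed = 42) fit_spec(n_starts = 3, seed = seed)

# A tiny choice-record frame built by hand.
toy_records <- function() {
  data.frame(
    agent_id = rep(c("a01", "a02"), each = 4),
    condition = "X",
    gain = rep(c(8, 8, 16, 16), 2),
    loss = rep(c(8, 16, 8, 16), 2),
    accepted = c(1L, 0L, 1L, 1L, 1L, 0L, 1L, 0L)
  )
}
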