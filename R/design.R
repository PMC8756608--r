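#' Construct a choice-set condition from a gain/loss range pair
#'
#' A condition is the full factorial of `n_levels` equally spaced gain
#' amounts ending at `max_gain` with `n_levels` equally spaced loss
#' magnitudes ending at `max_loss`. Every gamble is a 50-50 prospect: the
#' gain and the loss each occur with probability one half, which is implicit
#' throughout the package. Losses are stored as positive magnitudes; the
#' sign is applied only inside value functions.
#'
#' @param max_gain Largest gain on offer (currency units, > 0).
#' @param max_loss Largest loss magnitude on offer (currency units, > 0).
#' @param n_levels Number of equally spaced levels per attribute (>= 2).
#'   Levels are `max * k / n_levels` for `k = 1..n_levels`, so they are
#'   strictly positive and end exactly at the maximum.
#' @param label Short tag for the condition, e.g. `"LL"` or `"HL"`. Defaults
#'   to a tag built from the two maxima.
#' @return An object of class `gamble_condition`: a list with elements
#'   `label`, `max_gain`, `max_loss`, `gain_levels`, `loss_levels`, and
#'   `gambles` (a data frame with columns `gain` and `loss`, ordered by gain
#'   then loss).
#' @examples
#' ll <- build_condition(20, 20, n_levels = 5, label = "LL")
#' ll$gain_levels     # 4 8 12 16 20
#' nrow(ll$gambles)   # 25
#' @export
build_condition <- function(max_gain, max_loss, n_levels = 20, label = NULL) {
  if (!is_scalar_number(max_gain) || max_gain <= 0 ||
      !is_scalar_number(max_loss) || max_loss <= 0) {
    lr_error("max_gain and max_loss must be strictly positive numbers", "invalid_design")
  }
  if (!is_scalar_number(n_levels) || n_levels < 2 || n_levels != round(n_levels)) {
    lr_error("n_levels must be an integer >= 2", "invalid_design")
  }
  n_levels <- as.integer(n_levels)
  gain_levels <- max_gain * seq_len(n_levels) / n_levels
  loss_levels <- max_loss * seq_len(n_levels) / n_levels
  if (is.null(label)) {
    label <- sprintf("G%g_L%g", max_gain, max_loss)
  }
  gambles <- data.frame(
    gain = rep(gain_levels, each = n_levels),
    loss = rep(loss_levels, times = n_levels)
  )
  structure(
    list(
      label = as.character(label),
      max_gain = max_gain,
      max_loss = max_loss,
      gain_levels = gain_levels,
      loss_levels = loss_levels,
      gambles = gambles
    ),
    class = "gamble_condition"
  )
}

#' @export
print.gamble_condition <- function(x, ...) {
  cat(sprintf(
    "<gamble_condition '%s'> %d gambles; gains %g..%g, losses %g..%g (%d levels each)\n",
    x$label, nrow(x$gambles),
    min(x$gain_levels), x$max_gain,
    min(x$loss_levels), x$max_loss,
    length(x$gain_levels)
  ))
  invisible(x)
}

#' @export
as.data.frame.gamble_condition <- function(x, ...) {
  data.frame(label = x$label, x$gambles)
}

#' The 2x2 range-manipulation design
#'
#' Builds the four conditions of the classic range manipulation: maximum
#' gain in {low, high} crossed with maximum loss in {low, high}. Labels give
#' the gain letter first, so `"HL"` is high maximum gain with low maximum
#' loss. With the defaults (20 vs 40, 20 levels) the low- and high-range
#' grids share every second level, so the set of gambles common to all four
#' conditions is non-trivial (10 x 10 = 100 gambles).
#'
#' @param low,high Low and high range maxima (applied to both attributes).
#' @param n_levels Levels per attribute in every condition.
#' @return Named list of four `gamble_condition` objects: `LL`, `LH`, `HL`,
#'   `HH`.
#' @export
range_design <- function(low = 20, high = 40, n_levels = 20) {
  if (!is_scalar_number(low) || !is_scalar_number(high) || !(0 < low && low < high)) {
    lr_error("need 0 < low < high", "invalid_design")
  }
  list(
    LL = build_condition(low, low, n_levels, "LL"),
    LH = build_condition(low, high, n_levels, "LH"),
    HL = build_condition(high, low, n_levels, "HL"),
    HH = build_condition(high, high, n_levels, "HH")
  )
}

#' Gambles common to every condition
#'
#' Intersects the gamble sets of two or more conditions. Cross-condition
#' comparisons (model-free accept proportions, lambda fits restricted to a
#' shared instrument) must be computed on these common gambles to respect
#' measurement invariance.
#'
#' @param conditions A list of at least two `gamble_condition` objects.
#' @return Data frame with columns `gain` and `loss`, sorted by gain then
#'   loss. Empty (zero rows) with a warning when the intersection is empty.
#' @examples
#' des <- range_design(20, 40, n_levels = 5)
#' common_gambles(des)  # the 2x2 grid of levels shared by all four
#' @export
common_gambles <- function(conditions) {
  if (inherits(conditions, "gamble_condition")) {
    lr_error("common_gambles() needs a list of at least two conditions", "invalid_design")
  }
  if (!is.list(conditions) || length(conditions) < 2 ||
      !all(vapply(conditions, inherits, logical(1), "gamble_condition"))) {
    lr_error("common_gambles() needs a list of at least two conditions", "invalid_design")
  }
  keys <- lapply(conditions, function(cn) gamble_key(cn$gambles$gain, cn$gambles$loss))
  shared <- Reduce(intersect, keys)
  first <- conditions[[1]]$gambles
  out <- first[gamble_key(first$gain, first$loss) %in% shared, , drop = FALSE]
  out <- out[order(out$gain, out$loss), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("conditions share no gambles; returning an empty set")
  }
  out
}
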