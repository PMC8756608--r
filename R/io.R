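# Plain-text readers/writers for the package's tabular formats. All are
# comma-delimited with a header row and round-trip their own output exactly.

#' Read and write choice-record tables
#'
#' Choice records are stored as delimited text with header
#' `agent_id,condition,gain,loss,accepted`, one row per response, `accepted`
#' encoded 0/1.
#'
#' @param records Data frame of choice records.
#' @param path File path.
#' @return `read_choices()` returns the records data frame (`accepted` as
#'   integer 0/1); `write_choices()` returns `path` invisibly.
#' @export
write_choices <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("agent_id", "condition", "gain", "loss", "accepted") %in% names(records)))
  out <- records[, c("agent_id", "condition", "gain", "loss", "accepted")]
  out$accepted <- as.integer(out$accepted)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_choices
#' @export
read_choices <- function(path) {
  recs <- utils::read.csv(path, colClasses = c(
    agent_id = "character", condition = "character",
    gain = "numeric", loss = "numeric", accepted = "integer"
  ))
  if (!all(recs$accepted %in% c(0L, 1L))) {
    lr_error("accepted column must be 0/1", "invalid_input")
  }
  recs
}

#' Read and write condition tables
#'
#' Conditions serialize as delimited text with columns `label,gain,loss`,
#' one row per gamble.
#'
#' @param conditions A `gamble_condition` or list of them.
#' @param path File path.
#' @return `read_condition_table()` returns a data frame with columns
#'   `label`, `gain`, `loss`; `write_condition_table()` returns `path`
#'   invisibly.
#' @export
write_condition_table <- function(conditions, path) {
  if (inherits(conditions, "gamble_condition")) conditions <- list(conditions)
  tab <- do.call(rbind, lapply(conditions, as.data.frame))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_condition_table
#' @export
read_condition_table <- function(path) {
  utils::read.csv(path, colClasses = c(label = "character", gain = "numeric", loss = "numeric"))
}

#' Export a table of per-agent fit results
#'
#' Writes the data frame produced by [fit_population()] as delimited text
#' with columns `agent_id, alpha, beta, lam, mu, bias, loglik, converged,
#' at_bound, n_trials`.
#'
#' @param fits Data frame from [fit_population()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_results <- function(fits, path) {
  cols <- c("agent_id", "alpha", "beta", "lam", "mu", "bias",
            "loglik", "converged", "at_bound", "n_trials")
  stopifnot(is.data.frame(fits), all(cols %in% names(fits)))
  utils::write.csv(fits[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
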