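#' Model-free accept proportions on the common gambles
#'
#' The model-free measure of the range effect: per condition, the
#' proportion of accept responses restricted to the gambles present in
#' every condition, so that cross-condition comparisons use the same
#' measurement instrument. `by_agent` (default) averages per-agent
#' proportions, treating agents as the sampling unit; `pooled` counts
#' accepts over all trials.
#'
#' @param records Choice-record data frame.
#' @param common Data frame of common gambles (columns `gain`, `loss`),
#'   e.g. from [common_gambles()].
#' @param aggregation `"by_agent"` or `"pooled"`.
#' @return Data frame with columns `condition`, `aggregation`,
#'   `proportion`, `n_trials`, `n_agents`. Conditions with no
#'   common-gamble trials are omitted with a warning.
#' @export
accept_proportions_by_condition <- function(records, common,
                                            aggregation = c("by_agent", "pooled")) {
  aggregation <- match.arg(aggregation)
  stopifnot(is.data.frame(records),
            all(c("condition", "gain", "loss", "accepted") %in% names(records)))
  if (!is.data.frame(common) || nrow(common) == 0L) {
    lr_error("the common gamble set is empty", "invalid_input")
  }
  keep <- gamble_key(records$gain, records$loss) %in% gamble_key(common$gain, common$loss)
  sub <- records[keep, , drop = FALSE]
  all_conditions <- unique(records$condition)
  dropped <- setdiff(all_conditions, unique(sub$condition))
  if (length(dropped)) {
    warning(sprintf("no common-gamble trials in condition(s): %s; omitted",
                    paste(dropped, collapse = ", ")))
  }
  rows <- lapply(sort(unique(sub$condition)), function(cond) {
    rc <- sub[sub$condition == cond, , drop = FALSE]
    acc <- as.numeric(rc$accepted)
    prop <- if (aggregation == "pooled") {
      mean(acc)
    } else {
      mean(tapply(acc, rc$agent_id, mean))
    }
    data.frame(condition = cond, aggregation = aggregation, proportion = prop,
               n_trials = nrow(rc),
               n_agents = length(unique(rc$agent_id)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export an accept-proportion table
#'
#' @param table Data frame from [accept_proportions_by_condition()] or
#'   [predicted_proportion_table()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_proportion_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
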