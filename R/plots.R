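# Optional figures (ggplot2 in Suggests).

#' Bar panel of accept proportions by condition
#'
#' @param table Data frame with columns `condition` and either
#'   `mean_accept` (predictions) or `proportion` (observed).
#' @return A ggplot object.
#' @export
plot_proportion_table <- function(table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    lr_error("ggplot2 is required for plotting", "missing_suggests")
  }
  df <- data.frame(
    condition = table$condition,
    proportion = if ("mean_accept" %in% names(table)) table$mean_accept else table$proportion
  )
  lev <- intersect(c("LH", "LL", "HH", "HL"), df$condition)
  if (length(lev)) df$condition <- factor(df$condition, levels = lev)
  ggplot2::ggplot(df, ggplot2::aes(x = condition, y = proportion)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Condition (max gain / max loss)",
                  y = "Proportion accepted (common gambles)")
}

#' Histograms of second-half lambda ranks by first-half percentile
#'
#' One panel per target percentile; second-half rank distributions in red
#' with the stochasticity-only null, when present, overlaid in green.
#'
#' @param report A `recovery_report`.
#' @return A ggplot object.
#' @export
plot_rank_distributions <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    lr_error("ggplot2 is required for plotting", "missing_suggests")
  }
  stopifnot(inherits(report, "recovery_report"))
  stack <- function(dists, which) {
    do.call(rbind, lapply(seq_along(report$percentiles), function(j) {
      data.frame(percentile = sprintf("%dth percentile", report$percentiles[j]),
                 lambda_rank = dists[[j]], source = which)
    }))
  }
  df <- stack(report$rank_distributions, "Stochasticity and generalization")
  if (!is.null(report$null_distributions)) {
    df <- rbind(df, stack(report$null_distributions, "Stochasticity alone"))
  }
  df$percentile <- factor(df$percentile,
                          levels = sprintf("%dth percentile", report$percentiles))
  ggplot2::ggplot(df, ggplot2::aes(x = lambda_rank, fill = source)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.55, bins = 20) +
    ggplot2::facet_wrap(~percentile, nrow = 1) +
    ggplot2::scale_fill_manual(values = c(
      "Stochasticity and generalization" = "firebrick",
      "Stochasticity alone" = "forestgreen"
    )) +
    ggplot2::labs(x = "Second-half rank of lambda", y = "Count", fill = NULL) +
    ggplot2::theme(legend.position = "bottom")
}
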