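#' Cost-effectiveness plane for a strategy comparison
#'
#' Plots the incremental point (effect gain on x, cost difference on y)
#' with the willingness-to-pay line through the origin; points below the
#' line have positive net monetary benefit, and the lower-right quadrant
#' is the dominance region.
#'
#' @param object An `fp_cea` from [compare_strategies()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fp_cea <- function(object, ...) {
  pt <- tibble::tibble(
    delta_effect = object$delta_effect,
    delta_cost = object$delta_cost
  )
  lim_e <- max(abs(pt$delta_effect), 1e-6) * 1.4
  lim_c <- max(abs(pt$delta_cost), object$wtp * lim_e * 0.1, 1e-6) * 1.4
  ggplot2::ggplot(pt, ggplot2::aes(x = .data$delta_effect, y = .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_abline(
      slope = object$wtp, intercept = 0,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_point(size = 3, colour = "#2166ac") +
    ggplot2::coord_cartesian(
      xlim = c(-lim_e, lim_e), ylim = c(-lim_c, lim_c)
    ) +
    ggplot2::labs(
      x = "incremental effect (HB-grade improvement)",
      y = "incremental cost (GBP)",
      title = paste0(
        object$strategies$label[1], " vs ", object$strategies$label[2],
        " (", object$dominance, ")"
      ),
      subtitle = sprintf("dashed: WTP %.0f GBP per unit effect", object$wtp)
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of ledger subtotals by category
#'
#' @param ledger A cost ledger.
#' @param depth Category depth to group at (see [ledger_summary()]).
#' @return A ggplot object.
#' @export
plot_ledger <- function(ledger, depth = 2) {
  smry <- ledger_summary(ledger, depth = depth)
  ggplot2::ggplot(smry, ggplot2::aes(
    x = stats::reorder(.data$category, .data$total_cost),
    y = .data$total_cost / 1e6
  )) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "annual cost (GBP millions)",
      title = "Budget impact by category"
    ) +
    ggplot2::theme_minimal()
}

#' Agreement-by-item chart for a Delphi result
#'
#' @param consensus Tibble from [run_rounds()] (or any tibble with `item`
#'   and `agreement_pct`).
#' @param threshold_pct Consensus threshold to draw (default 66).
#' @return A ggplot object.
#' @export
plot_consensus <- function(consensus, threshold_pct = 66) {
  ggplot2::ggplot(consensus, ggplot2::aes(
    x = stats::reorder(.data$item, .data$agreement_pct),
    y = .data$agreement_pct
  )) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::geom_hline(
      yintercept = threshold_pct,
      linetype = "dashed", colour = "grey30"
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "agreement at modal rating (%)",
      title = "Delphi modal agreement",
      subtitle = sprintf("dashed: ex-ante consensus threshold (%g%%)", threshold_pct)
    ) +
    ggplot2::theme_minimal()
}
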