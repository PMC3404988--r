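# ggplot2 displays of profiles and monthly summaries.

#' Stacked per-sample composition bars
#'
#' One bar per sample, stacked by T-RF category, faceted by collection
#' month - the per-individual composition display.
#'
#' @param profiles Long profile tibble from [relative_abundance()].
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$sample_id, y = .data$ra_pct,
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$month), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = NULL, y = "relative abundance (%)", fill = "category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Monthly Tukey-style boxplot summaries
#'
#' Draws the five-number summaries from [aggregate_by_month()] as boxplots;
#' low-n months (fewer than three samples) are overplotted as points, since
#' a box is not meaningful there.
#'
#' @param monthly Summary tibble from [aggregate_by_month()].
#' @return A ggplot object.
#' @export
plot_month_summary <- function(monthly) {
  ok <- monthly |> filter(!.data$low_n)
  low <- monthly |> filter(.data$low_n)
  p <- ggplot2::ggplot(monthly, ggplot2::aes(x = .data$month)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$category)) +
    ggplot2::labs(x = "collection month", y = "relative abundance (%)") +
    ggplot2::theme_minimal()
  if (nrow(ok) > 0) {
    p <- p + ggplot2::geom_boxplot(
      data = ok,
      ggplot2::aes(ymin = .data$min, lower = .data$q1, middle = .data$median,
                   upper = .data$q3, ymax = .data$max),
      stat = "identity"
    )
  }
  if (nrow(low) > 0) {
    p <- p + ggplot2::geom_point(data = low,
                                 ggplot2::aes(y = .data$median), shape = 18,
                                 size = 3)
  }
  p
}

#' Relative-effect display for a permuted Brunner-Munzel test
#'
#' @param object A `trf_bm_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trf_bm_test <- function(object, ...) {
  tibble(p_hat = object$p_hat) |>
    ggplot2::ggplot(ggplot2::aes(x = "P(X<Y)+0.5P(X=Y)", y = .data$p_hat)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "relative effect",
                  subtitle = sprintf("two-sided permutation p = %.3g",
                                     object$p_value)) +
    ggplot2::theme_minimal()
}
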