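#' Forest plot of quartile odds ratios
#'
#' @param results Tidy association tibble (see [forest_table()]).
#' @return A ggplot object: odds ratios with Wald 95% intervals per quartile,
#'   faceted by outcome level where the outcome is multi-level.
#' @export
plot_forest <- function(results) {
  ft <- forest_table(results) |>
    mutate(
      quartile = stringr::str_remove(.data$term, "^grs_q"),
      panel_lab = ifelse(is.na(.data$level), .data$analysis,
                         paste0(.data$analysis, ": level ", .data$level))
    )
  ggplot2::ggplot(ft, ggplot2::aes(x = .data$or, y = .data$quartile)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2,
      na.rm = TRUE
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~panel_lab) +
    ggplot2::labs(x = "Odds ratio (log scale)", y = "GRS quartile") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Distribution of raw scores by quartile
#'
#' @param object A `grs_scores` tibble.
#' @param score Which score to show: `"u"` or `"w"`.
#' @param ... Unused.
#' @return A ggplot histogram of the raw score coloured by quartile.
#' @exportS3Method ggplot2::autoplot
autoplot.grs_scores <- function(object, score = c("u", "w"), ...) {
  score <- match.arg(score)
  df <- tibble(
    raw = if (score == "u") object$ugrs_raw else object$wgrs_raw,
    quartile = factor(if (score == "u") object$quartile_u else object$quartile_w)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$raw, fill = .data$quartile)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::labs(
      x = if (score == "u") "unweighted GRS (risk alleles)" else
        "weighted GRS (normalized)",
      y = "individuals", fill = "quartile"
    ) +
    ggplot2::theme_minimal()
}
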