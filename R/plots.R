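#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot relative-importance weights
#'
#' Horizontal bar chart of attribute weights, ordered by importance.
#'
#' @param object A `dce_ri` from [relative_importance()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dce_ri <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$pct)
  df$attribute <- factor(df$attribute, levels = df$attribute)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct, y = .data$attribute)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$pct)),
                       hjust = -0.1, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, .12))) +
    ggplot2::labs(x = "Relative importance (%)", y = NULL,
                  title = "Attribute weights from the choice model") +
    ggplot2::theme_minimal()
}

#' Plot SMART weights
#'
#' @param object A `dce_smart` from [smart_weights()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dce_smart <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$mean_weight)
  df$attribute <- factor(df$attribute, levels = df$attribute)
  ggplot2::ggplot(df, ggplot2::aes(x = 100 * .data$mean_weight,
                                   y = .data$attribute)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "Mean normalized score (%)", y = NULL,
                  title = "Attribute weights from SMART direct scoring") +
    ggplot2::theme_minimal()
}

#' Coefficient forest plot for a fitted choice model
#'
#' Point estimates with 95% Wald intervals; for mixed logit the mean
#' component is shown.
#'
#' @param object A `dce_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dce_fit <- function(object, ...) {
  df <- tidy(object)
  if ("component" %in% names(df)) df <- df[df$component == "mean", ]
  df$label <- ifelse(is.na(df$level), df$term,
                     paste0(df$attribute, ": ", df$level))
  df <- df[order(df$estimate), ]
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error)) +
    ggplot2::labs(x = "Part-worth utility", y = NULL) +
    ggplot2::theme_minimal()
}

#' Compare choice-model and SMART weight rankings
#'
#' Slope (bump) chart linking each attribute's rank under the two
#' weighting methods.
#'
#' @param ri A [relative_importance()] result.
#' @param smart A [smart_weights()] result.
#' @param smart_basis `"score"` or `"rank"`: which SMART ordering to show.
#' @return A ggplot.
#' @export
plot_weight_comparison <- function(ri, smart, smart_basis = c("score", "rank")) {
  smart_basis <- match.arg(smart_basis)
  sm_rank <- if (smart_basis == "score") smart$rank_by_weight else smart$rank_by_mean_rank
  df <- tibble::tibble(
    attribute = rep(ri$attribute, 2),
    method = rep(c("DCE (relative importance)", "SMART"), each = nrow(ri)),
    rank = c(ri$rank, sm_rank[match(ri$attribute, smart$attribute)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$rank,
                                   group = .data$attribute,
                                   colour = .data$attribute)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_reverse(breaks = seq_len(nrow(ri))) +
    ggplot2::labs(x = NULL, y = "Rank (1 = most important)",
                  colour = "Attribute") +
    ggplot2::theme_minimal()
}
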