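#' Discovery plot: FDR estimates and interval bands across thresholds
#'
#' FDR point estimates against threshold stringency (\eqn{-\log_{10} t}),
#' with a shaded band for the unadjusted confidence region and — when the
#' table carries FCR-adjusted bounds on selected rows — a lighter band for
#' the adjusted region. The number of discoveries `S` is printed above
#' each threshold, and a dashed line marks FDR = 0.05. Undefined rows
#' (no rejections) are dropped.
#'
#' @param object An `fdr_table`, typically after [fdr_select()].
#' @param annotate_counts Print the discovery count at each threshold.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @examples
#' set.seed(2)
#' p <- c(runif(1900), runif(100, 0, 1e-5))
#' perm <- matrix(runif(2000 * 20), 2000, 20)
#' autoplot(fdr_select(fdr_table(p, perm)))
#' @method autoplot fdr_table
#' @export
autoplot.fdr_table <- function(object, annotate_counts = TRUE, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$defined)
  if (nrow(df) == 0) {
    warning("no defined thresholds to plot", call. = FALSE)
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }
  cl <- attr(object, "cl")
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$neg_log10_t))
  has_adj <- "adj_ci_upper" %in% names(df) && any(!is.na(df$adj_ci_upper))
  if (has_adj) {
    adj <- df |>
      dplyr::mutate(
        lo = dplyr::coalesce(.data$adj_ci_lower, .data$ci_lower),
        hi = dplyr::coalesce(.data$adj_ci_upper, .data$ci_upper)
      )
    gg <- gg + ggplot2::geom_ribbon(
      data = adj, ggplot2::aes(ymin = .data$lo, ymax = pmin(.data$hi, 1)),
      fill = "grey85"
    )
  }
  gg <- gg +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lower, ymax = pmin(.data$ci_upper, 1)),
      fill = "grey60"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fdr)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$fdr), size = 0.8) +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed") +
    ggplot2::labs(
      x = expression(-log[10] ~ "p-value threshold"),
      y = "FDR estimate",
      title = "FDR discovery plot",
      subtitle = sprintf(
        "%.0f%% CI band%s; digits give the number of discoveries",
        100 * cl, if (has_adj) " (light: selection-adjusted)" else ""
      )
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (annotate_counts) {
    gg <- gg + ggplot2::geom_text(
      ggplot2::aes(y = pmin(.data$ci_upper, 1), label = .data$S),
      vjust = -0.5, size = 2.6
    )
  }
  gg
}

#' @rdname autoplot.fdr_table
#' @param table An `fdr_table`.
#' @export
plot_discovery <- function(table, ...) autoplot.fdr_table(table, ...)

#' Plot conditional coverage by true-FDR bin
#'
#' Companion plot to [conditional_coverage()]: one line per selection
#' method over the binned true FDR, with the nominal level marked.
#'
#' @param cc Output of [conditional_coverage()].
#' @param nominal Nominal coverage reference line (default 0.95).
#'
#' @return A ggplot object.
#' @export
plot_conditional_coverage <- function(cc, nominal = 0.95) {
  ggplot2::ggplot(
    dplyr::filter(cc, !is.na(.data$coverage)),
    ggplot2::aes(x = .data$bin_mid, y = .data$coverage,
                 colour = .data$method)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = nominal, linetype = "dashed") +
    ggplot2::labs(x = "true FDR (bin midpoint)",
                  y = "conditional coverage", colour = "selection") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
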