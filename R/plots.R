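#' Plot an RRHO map
#'
#' Heatmap of signed -log10 adjusted overlap p-values, faceted by
#' quadrant (up/down sublist of each signature).
#'
#' @param object A `dlam_rrho` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dlam_rrho <- function(object, ...) {
  px <- object$pixels
  px$qa <- ifelse(px$quadrant %in% c("up_up", "up_down"), "A up", "A down")
  px$qb <- ifelse(px$quadrant %in% c("up_up", "down_up"), "B up", "B down")
  ggplot2::ggplot(px, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$signed_nlp)) +
    ggplot2::geom_raster() +
    ggplot2::facet_grid(.data$qb ~ .data$qa, scales = "free") +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  name = expression(-log[10] ~ adj.~p)) +
    ggplot2::labs(x = "signature A rank prefix (grid steps)",
                  y = "signature B rank prefix (grid steps)") +
    ggplot2::theme_minimal()
}

#' Plot partitioned heritability enrichment
#'
#' Enrichment point estimates with +/- 1.96 jackknife SE intervals per
#' annotation (base annotation shown at its fixed value of 1).
#'
#' @param object A `dlam_h2` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dlam_h2 <- function(object, ...) {
  tb <- object$table
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$annotation,
                                   y = .data$enrichment)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$enrichment - 1.96 * .data$enrichment_se,
      ymax = .data$enrichment + 1.96 * .data$enrichment_se)) +
    ggplot2::labs(x = NULL, y = "heritability enrichment") +
    ggplot2::theme_minimal()
}

#' Plot a motif position histogram
#'
#' @param hist_tbl Tibble from [motif_position_histogram()].
#' @return A ggplot object.
#' @export
plot_motif_histogram <- function(hist_tbl) {
  ggplot2::ggplot(hist_tbl, ggplot2::aes(x = .data$bin_mid,
                                         y = .data$freq)) +
    ggplot2::geom_col(width = min(diff(hist_tbl$bin_mid)),
                      fill = "steelblue") +
    ggplot2::labs(x = "distance from region center (bp)",
                  y = "motif hits per bp per region") +
    ggplot2::theme_minimal()
}

#' Plot bootstrap support of consolidated network edges
#'
#' @param object A `dlam_grn` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dlam_grn <- function(object, ...) {
  pool <- object$pool
  pool$retained <- paste(pool$regulator, pool$target) %in%
    paste(object$edges$regulator, object$edges$target)
  ggplot2::ggplot(pool, ggplot2::aes(x = .data$support,
                                     fill = .data$retained)) +
    ggplot2::geom_histogram(binwidth = 1, position = "stack") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick"),
                               name = "retained") +
    ggplot2::labs(x = "bootstrap support", y = "edges") +
    ggplot2::theme_minimal()
}
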