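#' Barnyard scatter plot
#'
#' Reads (or UMIs) of the two species per barcode, coloured by species call
#' when present.
#'
#' @param table Barnyard tibble (see [simulate_barnyard()],
#'   [assign_species()]).
#' @param use "reads" or "umis".
#'
#' @return A ggplot object.
#' @export
plot_barnyard <- function(table, use = c("reads", "umis")) {
  use <- match.arg(use)
  xcol <- paste0(use, "_a")
  ycol <- paste0(use, "_b")
  p <- ggplot2::ggplot(table, ggplot2::aes(x = .data[[xcol]], y = .data[[ycol]]))
  if ("call" %in% names(table)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$call), alpha = 0.6)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.6)
  }
  sp <- attr(table, "species")
  p + ggplot2::labs(
    x = paste(use, if (!is.null(sp)) sp[["A"]] else "species A"),
    y = paste(use, if (!is.null(sp)) sp[["B"]] else "species B")
  )
}

#' Barcode-rank curve with the estimated knee
#'
#' Log-log plot of sorted per-barcode counts against rank; a dashed line
#' marks the knee estimate when supplied.
#'
#' @param umi_counts Per-barcode total counts.
#' @param knee Optional knee rank (e.g. from [estimate_stamps_knee()]).
#'
#' @return A ggplot object.
#' @export
plot_barcode_ranks <- function(umi_counts, knee = NULL) {
  d <- tibble::tibble(
    rank = seq_along(umi_counts),
    count = sort(as.numeric(umi_counts), decreasing = TRUE)
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "barcode rank", y = "total counts")
  if (!is.null(knee)) {
    p <- p + ggplot2::geom_vline(xintercept = knee, linetype = "dashed")
  }
  p
}

#' Saturation scatter with fitted capture slope
#'
#' @param saturation Tibble with `reads` and `umis`.
#' @param fit Optional [fit_capture_slope()] result; its UMI regression line
#'   is overlaid.
#'
#' @return A ggplot object.
#' @export
plot_saturation <- function(saturation, fit = NULL) {
  p <- ggplot2::ggplot(saturation, ggplot2::aes(x = .data$reads, y = .data$umis)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "total reads", y = "UMIs")
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(intercept = fit$intercept_umis,
                                  slope = fit$slope_umis_per_read,
                                  colour = "red")
  }
  p
}

#' Phase-score heatmap in on-pattern order
#'
#' Tiles of doubly-normalized phase scores with cells ordered by their
#' on-pattern (the ordering of [call_and_order()]).
#'
#' @param norm2 Wide tibble of doubly-normalized scores.
#' @param ordering Tibble from [call_and_order()].
#'
#' @return A ggplot object.
#' @export
plot_phase_heatmap <- function(norm2, ordering) {
  long <- tidyr::pivot_longer(norm2, -"cell", names_to = "phase",
                              values_to = "score")
  long$cell <- factor(long$cell, levels = ordering$cell)
  long$phase <- factor(long$phase, levels = setdiff(names(norm2), "cell"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cell, y = .data$phase,
                                     fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "cells (ordered by on-pattern)", y = NULL)
}
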