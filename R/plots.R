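#' Plot motif position distribution against the uniform background
#'
#' Histogram of motif anchor positions relative to the TSS, overlaid with
#' the uniform-placement expectation implied by the free-position profile
#' `k_i` — the visual counterpart of the bias Z statistic: a functional
#' motif piles up near position 0, a random one follows the background.
#'
#' @param hits Hit tibble from [scan_promoters()].
#' @param bg Optional [bias_background()] for the same promoters; when
#'   given, the expected density over free positions is drawn as a line.
#' @param binwidth Histogram bin width in bp.
#' @return A ggplot object.
#' @export
plot_position_bias <- function(hits, bg = NULL, binwidth = 50) {
  p <- ggplot2::ggplot(hits, ggplot2::aes(x = .data$anchor)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "position relative to TSS (bp)", y = "density",
                  title = "Motif position distribution")
  if (!is.null(bg)) {
    bg_df <- tibble::tibble(position = seq.int(-bg$M, bg$N),
                            density = bg$k_i / bg$K)
    p <- p + ggplot2::geom_line(data = bg_df,
                                ggplot2::aes(x = .data$position, y = .data$density),
                                colour = "firebrick")
  }
  p
}

#' Plot the partial-correlation distribution with the edge cutoff
#'
#' @param pcor A `pcor_result` tibble.
#' @param cutoff Edge cutoff to mark (default 0.04).
#' @return A ggplot object.
#' @export
plot_pcor_distribution <- function(pcor, cutoff = 0.04) {
  ggplot2::ggplot(tidy(pcor), ggplot2::aes(x = .data$pcor)) +
    ggplot2::geom_histogram(bins = 80, fill = "grey35") +
    ggplot2::geom_vline(xintercept = cutoff, colour = "firebrick", linetype = 2) +
    ggplot2::labs(x = "partial correlation", y = "gene pairs",
                  title = "Pairwise partial correlations")
}

#' Plot module sizes of a partition
#'
#' @param partition A [mcl_cluster()] partition.
#' @return A ggplot object.
#' @export
plot_module_sizes <- function(partition) {
  sizes <- dplyr::count(tidy(partition), .data$module, name = "size")
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$module, y = .data$size)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "module (1 = largest)", y = "genes",
                  title = "Module sizes")
}

#' @rdname plot_position_bias
#' @param object,... Autoplot dispatch.
#' @export
autoplot.module_partition <- function(object, ...) plot_module_sizes(object)

#' @rdname plot_position_bias
#' @export
autoplot.pcor_result <- function(object, ...) plot_pcor_distribution(object, ...)
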