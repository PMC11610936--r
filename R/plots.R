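# ggplot2 presentation of the result types. Figures are presentation-only:
# every number they show comes from a result tibble.

#' Square-tile heat map of a terminal k-mer table
#'
#' The top `top_n` k-mers laid out as a tile grid (rank order, left to
#' right, top to bottom) with the count as fill.
#'
#' @param x A `kmer_table`.
#' @param top_n Number of k-mers shown.
#' @param ncol Tiles per row.
#' @return A ggplot object.
#' @export
plot_kmer_table <- function(x, top_n = 16L, ncol = 4L) {
  tb <- as_tibble(x) |> slice_head(n = top_n)
  tb <- tb |>
    mutate(col = (.data$rank - 1L) %% ncol,
           row = -((.data$rank - 1L) %/% ncol))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$count)) +
    ggplot2::geom_tile(color = "white", linewidth = 1) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%s\n%g", .data$kmer, .data$count)),
      color = "black", size = 3) +
    ggplot2::scale_fill_gradient(low = "lightyellow", high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "count",
                  title = sprintf("Top terminal %d-mers (coding strand)",
                                  attr(x, "k")))
}

#' @export
autoplot.kmer_table <- function(object, ...) plot_kmer_table(object, ...)

#' Mean metagene curve of a meta matrix
#'
#' @param x A `meta_matrix`.
#' @return A ggplot object.
#' @export
plot_metaprofile <- function(x) {
  tb <- tibble(metapos = x$axis$metapos, segment = x$axis$segment,
               mean_value = colMeans(x$matrix))
  seg_bounds <- cumsum(rle(x$axis$segment)$lengths)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$metapos,
                                   y = .data$mean_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = head(seg_bounds, -1) + 0.5,
                        linetype = "dashed", color = "grey50") +
    ggplot2::labs(x = "meta-position (sense, 0-based bins)",
                  y = "mean signal") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.meta_matrix <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$metapos, y = .data$tu_id,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "meta-position (sense)", y = NULL,
                  fill = "value") +
    ggplot2::theme_minimal()
}

#' Distance-binned fold-change meta-curves over T-runs
#'
#' @param curve Output of [fc_over_motifs()].
#' @return A ggplot object.
#' @export
plot_motif_meta <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$metapos,
                                      y = .data$mean_log2fc,
                                      color = .data$bin)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "meta-position (flank | scaled run | flank)",
                  y = "mean log2 change", color = "distance from TSS") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
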