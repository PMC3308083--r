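#' Plot a fitted T2 map slice
#'
#' Raster display of one slice of a fitted T2 map; invalid and background
#' pixels are blank.
#'
#' @param x A `t2_map`.
#' @param slice Slice index.
#' @param limits T2 colour limits (ms).
#' @return A ggplot object.
#' @export
plot_t2_map <- function(x, slice = 1, limits = c(0, 80)) {
  t2s <- x$t2[, , slice]
  ok <- x$valid[, , slice]
  idx <- which(ok, arr.ind = TRUE)
  df <- tibble::tibble(row = idx[, 1], col = idx[, 2],
                       t2 = t2s[ok])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$t2)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = limits, name = "T2 (ms)",
                                  oob = scales_squish) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Fitted T2 map, slice %d", slice))
}

# minimal squish so we don't need the scales package in Imports
scales_squish <- function(x, range = c(0, 1), ...) {
  pmin(pmax(x, range[1]), range[2])
}

#' Plot group-comparison coefficients
#'
#' Forest-style display of a [comparison_table()]: group coefficient
#' (control minus incidence) with its confidence interval per outcome.
#'
#' @param object A tibble from [comparison_table()] (or a single
#'   `cartex_comparison`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cartex_comparison
#' @export
autoplot.cartex_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coefficient, y = .data$outcome)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "Group coefficient (control - incidence)", y = NULL)
}

#' @rdname autoplot.cartex_comparison
#' @export
plot_comparisons <- function(object, ...) {
  class(object) <- c("cartex_comparison", class(object))
  autoplot.cartex_comparison(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
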