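#' Forest plot of autosome-vs-X f4 contrasts
#'
#' One row per configuration, points at the pooled f4 estimates with
#' 2-SE whiskers, autosomes and X side by side; the vertical zero line marks
#' treeness.
#'
#' @param contrasts A single `swampx_contrast` or a list of them.
#' @return A ggplot object.
#' @export
plot_f4_forest <- function(contrasts) {
  if (inherits(contrasts, "swampx_contrast")) contrasts <- list(contrasts)
  dat <- purrr::map(contrasts, tidy.swampx_contrast) |> dplyr::bind_rows()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$statistic,
                                    colour = .data$class)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$estimate - 2 * .data$se,
                   xmax = .data$estimate + 2 * .data$se),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_colour_manual(values = c(autosome = "#c03030", X = "#3050c0")) +
    ggplot2::labs(x = "f4 estimate (±2 SE)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_f4_forest
#' @param object A `swampx_contrast`.
#' @param ... Unused.
#' @export
autoplot.swampx_contrast <- function(object, ...) plot_f4_forest(object)

#' Plot an f4 scan along a chromosome
#'
#' @param scan Output of [f4_scan()] (per-site or windowed).
#' @return A ggplot object.
#' @export
plot_f4_scan <- function(scan) {
  xvar <- if ("pos" %in% names(scan)) "pos" else "window_start"
  ggplot2::ggplot(scan, ggplot2::aes(x = .data[[xvar]] / 1e6, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    (if (xvar == "pos") ggplot2::geom_point(alpha = 0.3, size = 0.4)
     else ggplot2::geom_line()) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "f4") +
    ggplot2::theme_minimal()
}
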