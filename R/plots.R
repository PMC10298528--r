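#' Manhattan-style plot of a probe or locus scan
#'
#' @param res A `cnvclim_assoc` tibble.
#' @param probes Optional probe map supplying genomic positions (joined by
#'   `probe`); without it, units are plotted in table order.
#' @param threshold Optional horizontal significance line (raw p).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(res, probes = NULL, threshold = NULL) {
  df <- tibble::as_tibble(res)
  if (!is.null(probes) && "probe" %in% names(df)) {
    df <- dplyr::inner_join(df, probes, by = "probe") |>
      dplyr::arrange(.data$chrom, .data$position)
  }
  df$index <- seq_len(nrow(df))
  df <- dplyr::filter(df, !is.na(.data$p_raw))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$index,
                                        y = -log10(.data$p_raw))) +
    ggplot2::labs(x = "genomic order", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  p <- if ("chrom" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$chrom), size = 0.8) +
      ggplot2::guides(colour = "none")
  } else {
    p + ggplot2::geom_point(size = 0.8)
  }
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed")
  }
  p
}

#' @method autoplot cnvclim_assoc
#' @export
autoplot.cnvclim_assoc <- function(object, ...) plot_manhattan(object, ...)

#' Plot site solar radiation against latitude
#'
#' @param object An [estimate_solar()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cnvclim_solar
#' @export
autoplot.cnvclim_solar <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$latitude, y = .data$H,
                                       colour = .data$sun)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "latitude (deg)", y = "annual radiation (MJ/m²/day)",
                  colour = "sunshine\nfraction") +
    ggplot2::theme_minimal()
}

#' Bar chart of CNV class composition
#'
#' @param summary A [summarize_cnvs()] result.
#' @return A ggplot object.
#' @export
plot_cnv_summary <- function(summary) {
  stopifnot(inherits(summary, "cnv_summary"))
  ggplot2::ggplot(summary$calls,
                  ggplot2::aes(x = .data$class, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "CNV count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
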