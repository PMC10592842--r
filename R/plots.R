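#' Plot an FROC curve
#'
#' Detection sensitivity (TPR) against false positives per section across
#' probability thresholds, with the elbow threshold marked.
#'
#' @param object an `ft_froc` tibble from [froc_curve()].
#' @param ... further `ft_froc` objects to overlay, named (e.g.
#'   `raw = froc_raw`).
#' @return A ggplot object.
#' @method autoplot ft_froc
#' @export
autoplot.ft_froc <- function(object, ...) {
  extra <- list(...)
  df <- dplyr::mutate(as_tibble(object), curve = "post-processed")
  for (nm in names(extra)) {
    df <- dplyr::bind_rows(df, dplyr::mutate(as_tibble(extra[[nm]]),
                                             curve = nm))
  }
  elbow <- attr(object, "elbow")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fp_per_section, y = .data$tpr,
                                   colour = .data$curve)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = dplyr::filter(df, .data$curve == "post-processed",
                                             .data$threshold == elbow),
                        shape = 1, size = 4) +
    ggplot2::labs(x = "false positives / section", y = "bundle TPR",
                  colour = NULL,
                  title = "FROC: fiber-bundle detection") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Boxplot of fiber density by pathway
#'
#' @param fd_table tibble with `fd` and `pathway` columns (optionally a
#'   `source` column, e.g. manual vs predicted).
#' @return A ggplot object.
#' @export
plot_fd_by_pathway <- function(fd_table) {
  fd_table <- dplyr::filter(fd_table, .data$pathway != "none")
  mapping <- if ("source" %in% names(fd_table)) {
    ggplot2::aes(x = .data$pathway, y = .data$fd, fill = .data$source)
  } else {
    ggplot2::aes(x = .data$pathway, y = .data$fd)
  }
  ggplot2::ggplot(fd_table, mapping) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "white-matter pathway", y = "fiber density (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
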