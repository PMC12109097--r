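# Lightweight ggplot2 helpers for the tabular outputs.

#' Plot a training log
#'
#' Loss curves plus the masked-fraction and schedule traces of one run.
#'
#' @param log the `log` tibble of a [fit_pemt()] result (or the fit itself)
#' @return a ggplot object
#' @export
plot_training_log <- function(log) {
  if (inherits(log, "pemt_fit")) log <- log$log
  keep <- c("supervised", "consistency", "masked_fraction", "lambda", "tau")
  long <- do.call(rbind, lapply(keep, function(k)
    data.frame(t = log$t, series = k, value = log[[k]])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL)
}

#' Heatmap of an uncertainty map
#'
#' @param u `H x W` matrix from [rum()] or [eum()]
#' @return a ggplot object
#' @export
plot_uncertainty <- function(u) {
  df <- data.frame(x = as.vector(row(u)), y = as.vector(col(u)),
                   value = as.vector(u))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "uncertainty") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @importFrom ggplot2 .data
NULL
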