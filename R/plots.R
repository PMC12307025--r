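#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a connectivity matrix
#'
#' @param object A `connectivity_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot connectivity_matrix
#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(from = object$labels, to = object$labels)
  df$weight <- as.vector(t(object$weights))
  df$from <- factor(df$from, levels = object$labels)
  df$to <- factor(df$to, levels = rev(object$labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(title = sprintf("dwPLI, %s band", object$band),
                  x = NULL, y = NULL, fill = "|dwPLI|") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_text(size = 5),
                   axis.text.x = ggplot2::element_text(angle = 90))
}

#' Global-cost-efficiency curve of an OMST selection
#'
#' @param object An `omst_selection`.
#' @param ... Unused.
#' @return A ggplot of cost, global efficiency and J by round, with the
#'   selected round marked.
#' @method autoplot omst_selection
#' @export
autoplot.omst_selection <- function(object, ...) {
  long <- tidyr::pivot_longer(object$gce_curve, c("cost", "ge", "J"),
                              names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$m, y = .data$value,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$m_star, linetype = "dashed") +
    ggplot2::labs(x = "spanning-tree rounds (m)", y = NULL,
                  title = sprintf("OMST selection: m* = %d", object$m_star)) +
    ggplot2::theme_minimal()
}

#' Fitted metric-by-age effect of a fluency model
#'
#' Raw outcome against the (scaled) first metric of the model's family,
#' split by age group with per-group least-squares lines — the usual
#' way a metric x age interaction is displayed.
#'
#' @param object A `fluency_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fluency_model
#' @export
autoplot.fluency_model <- function(object, ...) {
  metric <- model_family_terms(object$family)[1L]
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[metric]],
                                  y = .data[[object$outcome]],
                                  colour = .data$age_group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = paste0(metric, " (z)"), y = object$outcome,
                  colour = "age group", title = object$model_id) +
    ggplot2::theme_minimal()
}

#' Channel power spectra with the IAPF search window
#'
#' @param csd A `csd` object.
#' @param channels Channels to draw (defaults to the first 6).
#' @param iapf Optional `iapf_estimate` to mark.
#' @return A ggplot of epoch-averaged log-power per channel.
#' @export
plot_psd <- function(csd, channels = NULL, iapf = NULL) {
  df <- psd_from_csd(csd)
  if (is.null(channels)) channels <- utils::head(csd$channel_labels, 6L)
  df <- df[df$channel %in% channels & df$freq > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$power,
                                        colour = .data$channel)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "power (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(iapf) && iapf$quality_flag == "ok") {
    p <- p + ggplot2::geom_vline(xintercept = iapf$iapf, linetype = "dashed")
  }
  p
}

#' @importFrom rlang .data
NULL
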