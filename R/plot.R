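# ggplot2 views of the pipeline's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot an AP expression profile
#'
#' @param object An `ap_profile`.
#' @param ... Unused.
#' @return A ggplot: masked summed intensity against AP position.
#' @export
autoplot.ap_profile <- function(object, ...) {
  df <- tibble::tibble(ap = (object$bin_lo + object$bin_hi) / 2,
                       value = object$value)
  ylab <- if (isTRUE(attr(object, "normalized"))) {
    "normalized summed intensity"
  } else "summed intensity (a.u.)"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ap, y = .data$value)) +
    ggplot2::geom_line(color = "#2e7d32") +
    ggplot2::labs(x = "anterior-posterior position (px)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot a cross-larva average AP profile with an sd ribbon
#'
#' @param profile Tibble from [normalize_and_average()].
#' @return A ggplot.
#' @export
plot_average_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$ap, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                      ymax = .data$mean + .data$sd),
                         fill = "#2e7d32", alpha = 0.25) +
    ggplot2::geom_line(color = "#2e7d32") +
    ggplot2::labs(x = "normalized AP position",
                  y = "normalized expression (mean ± sd)") +
    ggplot2::theme_minimal()
}

#' Plot single-cell activation traces
#'
#' @param traces Tibble from [extract_traces()].
#' @return A ggplot of per-cell traces, colored by region when present.
#' @export
plot_traces <- function(traces) {
  p <- ggplot2::ggplot(traces,
                       ggplot2::aes(x = .data$time, y = .data$value,
                                    group = interaction(.data$larva_id,
                                                        .data$cell_id)))
  p <- if ("region" %in% names(traces)) {
    p + ggplot2::geom_line(ggplot2::aes(color = .data$region), alpha = 0.5)
  } else {
    p + ggplot2::geom_line(alpha = 0.5, color = "grey30")
  }
  p + ggplot2::labs(x = "time post infection (h)",
                    y = "disk-summed intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot regional activation-rate summaries
#'
#' @param object A `rate_summary` from [summarize_rates()].
#' @param ... Unused.
#' @return A ggplot of median rates with quartile bars per region.
#' @export
autoplot.rate_summary <- function(object, ...) {
  df <- object$regions
  df$region <- factor(df$region, levels = c("anterior", "middle", "posterior"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$median_rate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                             color = "#2e7d32") +
    ggplot2::labs(x = NULL, y = "activation rate (a.u./h)") +
    ggplot2::theme_minimal()
}

#' Plot an AP transcript-frequency profile with bootstrap error bars
#'
#' @param object An `ap_expression_profile` from [ap_bootstrap_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ap_expression_profile <- function(object, ...) {
  df <- tibble::tibble(ap = (object$bin_lo + object$bin_hi) / 2,
                       mean = object$mean_freq, sd = object$boot_sd)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ap, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             color = "#1565c0") +
    ggplot2::labs(x = "AP position", y = "mean transcript frequency",
                  title = object$gene[1L]) +
    ggplot2::theme_minimal()
}
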