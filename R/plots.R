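#' Plot a three-colour kymograph
#'
#' Raster view of the three channels (time running down, DNA axis across),
#' faceted by channel with fluorophore-matched colour scales.
#'
#' @param object A [render_kymograph()] object.
#' @param ... Unused.
#' @returns A ggplot object.
#' @export
autoplot.kymograph <- function(object, ...) {
  long <- purrr::map_dfr(c("green", "blue", "magenta"), function(ch) {
    m <- object[[ch]]
    tibble(
      channel = ch,
      frame = rep(seq_len(nrow(m)), times = ncol(m)),
      pixel = rep(seq_len(ncol(m)), each = nrow(m)),
      intensity = as.vector(m)
    )
  }) |>
    mutate(channel = factor(.data$channel,
                            levels = c("green", "blue", "magenta"),
                            labels = c("GFP-Rad54", "Atto647N ssDNA",
                                       "RPA-mCherry")))
  ggplot2::ggplot(long, ggplot2::aes(.data$pixel, .data$frame,
                                     fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "position (pixel)", y = "time (frame)") +
    ggplot2::theme_minimal()
}

#' Plot a mixture fit over its sample histogram
#'
#' @param object A `mixture_fit`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @returns A ggplot object.
#' @export
autoplot.mixture_fit <- function(object, bins = 30, ...) {
  x <- object$data
  grid <- seq(min(x), max(x), length.out = 400)
  comp <- object$components
  dens <- purrr::map_dfr(seq_len(nrow(comp)), function(j) {
    tibble(x = grid, component = factor(j),
           density = comp$weight[j] * dnorm(grid, comp$mean[j], comp$sd[j]))
  })
  total <- dens |>
    group_by(.data$x) |>
    summarise(density = sum(.data$density), .groups = "drop")
  ggplot2::ggplot(tibble(x = x), ggplot2::aes(.data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component)) +
    ggplot2::geom_line(data = total, ggplot2::aes(y = .data$density),
                       linewidth = 1) +
    ggplot2::labs(x = "value", y = "density",
                  title = paste("model:", object$model)) +
    ggplot2::theme_minimal()
}

#' Plot a binding probability profile
#'
#' @param object A [binding_profile()].
#' @param ... Unused.
#' @returns A ggplot object; the target bin, when set, is marked.
#' @export
autoplot.binding_profile <- function(object, ...) {
  tb <- attr(object, "target_bin")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes((.data$start_bp + .data$end_bp) / 2000,
                                    .data$prob)) +
    ggplot2::geom_col(width = diff(range(object$start_bp)) /
                        (1000 * nrow(object)), fill = "grey40") +
    ggplot2::labs(x = "position (kb)", y = "binding probability") +
    ggplot2::theme_minimal()
  if (!is.na(tb)) {
    tgt <- object[object$bin == tb, ]
    p <- p + ggplot2::geom_vline(
      xintercept = (tgt$start_bp + tgt$end_bp) / 2000,
      linetype = "dashed", colour = "red")
  }
  p
}

#' Plot outcome fractions with replicate error bars
#'
#' @param object An `outcome_tally`.
#' @param ... Unused.
#' @returns A ggplot object (mean percentage per outcome, +/- sd across
#'   replicates).
#' @export
autoplot.outcome_tally <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$outcome, .data$mean_pct)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_pct - .data$sd_pct,
                                        ymax = .data$mean_pct + .data$sd_pct),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "% of population",
                  title = paste("population:", object$population)) +
    ggplot2::theme_minimal()
}
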