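#' Plot shoal trajectories
#'
#' Paths of all individuals in the arena, focal fish highlighted.
#'
#' @param frames A [frame_set()].
#' @return A ggplot object.
#' @export
plot_trajectories <- function(frames) {
  stopifnot(inherits(frames, "frame_set"))
  pos <- dplyr::mutate(
    frames$positions,
    role = ifelse(.data$individual == frames$focal_id, "focal", "companion")
  )
  ggplot2::ggplot(pos, ggplot2::aes(.data$x, .data$y,
                                    group = .data$individual,
                                    colour = .data$role)) +
    ggplot2::geom_path(alpha = 0.6, na.rm = TRUE) +
    ggplot2::coord_fixed(xlim = c(0, frames$arena[1]),
                         ylim = c(0, frames$arena[2])) +
    ggplot2::labs(x = "x (mm, downstream)", y = "y (mm, cross-stream)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname variance_map
#' @param object A `variance_map`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.variance_map <- function(object, ...) {
  df <- tidyr::expand_grid(xi = seq_along(object$x),
                           yi = seq_along(object$y))
  df$x <- object$x[df$xi]
  df$y <- object$y[df$yi]
  df$variance <- object$variance[cbind(df$xi, df$yi)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$variance)) +
    ggplot2::geom_raster() +
    ggplot2::annotate("point", x = object$argmax["x"],
                      y = object$argmax["y"], shape = 4, colour = "white") +
    ggplot2::scale_fill_viridis_c(na.value = "grey30") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (m)", y = "y (m)",
                  fill = "speed variance\n(m2 s-2)") +
    ggplot2::theme_minimal()
}

#' @rdname pore_size_sweep
#' @param object A `pore_sweep`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.pore_sweep <- function(object, ...) {
  df <- purrr::imap_dfr(object$responses, function(r, nm) {
    tibble::tibble(pore = nm, u = r$series$u_internal)
  })
  df$pore <- factor(df$pore, levels = names(object$responses))
  ggplot2::ggplot(df, ggplot2::aes(.data$pore, .data$u)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA, scale = "width") +
    ggplot2::stat_summary(fun.min = function(z) quantile(z, 0.25),
                          fun.max = function(z) quantile(z, 0.75),
                          fun = median, geom = "pointrange",
                          linewidth = 1.2) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 21,
                          fill = "white", size = 2) +
    ggplot2::labs(x = "pore diameter", y = "internal velocity (m/s)") +
    ggplot2::theme_minimal()
}

#' Plot a support table as a coded grid
#'
#' Tile plot of [build_support_table()] codes: sign of supported slopes,
#' `U` for unsupported cells, `*` for a strongly supported interaction.
#'
#' @param support Output of [build_support_table()].
#' @return A ggplot object.
#' @export
plot_support_table <- function(support) {
  df <- dplyr::mutate(
    support,
    column = paste(.data$response, .data$dataset, sep = "\n"),
    fill = dplyr::case_when(
      is.na(.data$code) ~ "unavailable",
      startsWith(.data$code, "+") ~ "positive",
      startsWith(.data$code, "-") ~ "negative",
      TRUE ~ "unsupported"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$column, .data$predictor,
                                   fill = .data$fill)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$code), na.rm = TRUE) +
    ggplot2::scale_fill_manual(values = c(
      positive = "#8fd18f", negative = "#9fc3e8",
      unsupported = "grey90", unavailable = "grey70"
    )) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
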