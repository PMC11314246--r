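klass_scale <- function() {
  ggplot2::scale_fill_manual(values = c(
    hydrophobic = "#d62728", polar = "#2ca02c",
    negative = "#1f77b4", positive = "#e377c2"
  ), name = "class")
}

#' @export
autoplot.ps_separation <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$frame, y = .data$separation)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$closest_distance),
                       colour = "#d62728", alpha = 0.7) +
    ggplot2::labs(x = "frame",
                  y = "separation from surface plane (Å)",
                  subtitle = "black: centre of mass; red: closest residue") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ps_contacts <- function(object, ...) {
  ggplot2::ggplot(object$probability,
                  ggplot2::aes(x = factor(.data$author_index),
                               y = .data$probability, fill = .data$klass)) +
    ggplot2::geom_col() +
    klass_scale() +
    ggplot2::labs(x = "residue", y = "surface contact probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @export
autoplot.ps_sstruct <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$propensity, cols = c("H", "G", "E", "T", "C"),
    names_to = "state", values_to = "propensity"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$author_index,
                                     y = .data$propensity,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "secondary structure propensity") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ps_cluster <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(head(tb, 20),
                  ggplot2::aes(x = .data$cluster, y = .data$population)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "cluster rank", y = "population") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ps_overlap <- function(object, ...) {
  long <- tidyr::pivot_longer(
    head(object$table, 20), cols = -c("cluster", "population"),
    names_to = "system", values_to = "occupancy"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cluster, y = .data$occupancy,
                                     fill = .data$system)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "pooled cluster rank", y = "per-system occupancy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ps_rest <- function(object, ...) {
  cold <- filter(object$samples, .data$replica == 1L)
  ggplot2::ggplot(cold, ggplot2::aes(x = .data$step, y = .data$x)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = 2,
                        colour = "#d62728") +
    ggplot2::labs(x = "step", y = "double-well coordinate x (beta = 1)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ps_wheel <- function(object, ...) {
  df <- as_tibble(object)
  df$theta <- df$angle * pi / 180
  ggplot2::ggplot(df, ggplot2::aes(x = cos(.data$theta), y = sin(.data$theta),
                                   fill = .data$klass)) +
    ggplot2::geom_point(size = 10, shape = 21) +
    ggplot2::geom_text(ggplot2::aes(
      label = paste0(.data$code, .data$author_index)
    ), nudge_y = 0.18, size = 3) +
    klass_scale() +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void()
}

#' Residue separation profile plot
#'
#' @param profile Tibble from [residue_surface_profile()].
#' @return A ggplot object.
#' @export
plot_residue_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$author_index,
                                        y = .data$mean_separation,
                                        fill = .data$klass)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_separation - .data$sd_separation,
      ymax = .data$mean_separation + .data$sd_separation
    ), width = 0.3, colour = "grey40") +
    ggplot2::geom_hline(yintercept = attr(profile, "overall_mean"),
                        linetype = 3) +
    klass_scale() +
    ggplot2::labs(x = "residue", y = "mean separation (Å)") +
    ggplot2::theme_minimal()
}
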