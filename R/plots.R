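#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a centroided spectrum
#'
#' Stick plot of a peak list; assigned peaks (when an assignment table is
#' given) are coloured by species label.
#'
#' @param peaks Peak list, or an [assign_peaks()] table.
#' @param top_n Label the `top_n` most intense assigned peaks.
#' @return A ggplot.
#' @export
plot_spectrum <- function(peaks, top_n = 10) {
  df <- tibble::as_tibble(peaks)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0),
                          linewidth = 0.4) +
    ggplot2::labs(x = "m/z", y = "intensity") +
    ggplot2::theme_minimal()
  if ("assigned" %in% names(df)) {
    lab <- df |>
      dplyr::filter(.data$assigned) |>
      dplyr::slice_max(.data$intensity, n = top_n)
    p <- p + ggplot2::geom_text(
      data = lab, ggplot2::aes(label = .data$label),
      vjust = -0.4, size = 2.8, check_overlap = TRUE)
  }
  p
}

#' @export
autoplot.breakdown_curve <- function(object, e50 = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$energy, y = .data$pct,
                                        colour = .data$species,
                                        shape = .data$species)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "laboratory-frame energy (eV)", y = "species (%)") +
    ggplot2::theme_minimal()
  if (!is.null(e50)) {
    v <- if (inherits(e50, "e50_fit")) e50$e50 else as.numeric(e50)
    p <- p + ggplot2::geom_vline(xintercept = v, colour = "violet")
  }
  p
}

#' @export
autoplot.melt_fit <- function(object, derivative = FALSE, ...) {
  if (derivative) {
    d <- derivative_profile(object)
    return(
      ggplot2::ggplot(d$profile,
                      ggplot2::aes(x = .data$temperature, y = .data$dA_dT)) +
        ggplot2::geom_line(colour = "red") +
        ggplot2::geom_vline(data = d$extrema,
                            ggplot2::aes(xintercept = .data$temperature),
                            linetype = "dashed") +
        ggplot2::labs(x = "temperature (°C)", y = "dA/dT") +
        ggplot2::theme_minimal()
    )
  }
  grid <- tibble::tibble(temperature = seq(min(object$data$temperature),
                                           max(object$data$temperature),
                                           length.out = 300))
  grid$absorbance <- predict(object, grid)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$temperature, y = .data$absorbance)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "temperature (°C)", y = "absorbance (AU)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.species_quant <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$species,
                                       y = .data$species_pct)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "species (%)") +
    ggplot2::theme_minimal()
}
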