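#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.e50_fit <- function(x, ...) {
  tibble::tibble(
    term = c("p0", "e_mid", "width"),
    estimate = c(x$p0, x$e_mid, x$width)
  )
}

#' @export
glance.e50_fit <- function(x, ...) {
  tibble::tibble(
    e50 = x$e50, e50_interp = x$e50_interp, e50_relative = x$e50_relative,
    initial_q_pct = x$initial_q_pct %||% NA_real_,
    method = x$method, n_points = nrow(x$data)
  )
}

#' @export
tidy.melt_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::filter(x$coefficients, .data$term %in% c("c0", "c1")) |>
      dplyr::mutate(kind = "baseline"),
    x$transitions |>
      tidyr::pivot_longer(c("amplitude", "t_mid", "width", "delta_t_10_90"),
                          names_to = "term", values_to = "estimate") |>
      dplyr::mutate(term = paste0(.data$term, "_", .data$sigmoid),
                    kind = "transition") |>
      dplyr::select("term", "estimate", "kind")
  )
}

#' @export
glance.melt_fit <- function(x, ...) {
  tibble::tibble(
    n_sigmoids = x$n_sigmoids, sigma = x$sigma,
    n_points = nrow(x$data), aic = AIC(x$fit),
    any_degenerate = any(x$transitions$degenerate)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
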