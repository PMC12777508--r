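#' Fit a UV melting heating curve
#'
#' Least-squares fit of absorbance versus temperature with a linear
#' baseline plus one or two logistic sigmoids,
#' A(T) = c0 + c1 T + sum_k a_k / (1 + exp(-(T - Tmid_k)/w_k)).
#' Amplitudes are signed (hyperchromic transitions at 260 nm rise,
#' 295 nm quadruplex transitions fall). The midpoint Tm of each sigmoid is
#' the extremum of its dA/dT contribution; the transition width is
#' reported as the 10-90% amplitude span, 2 ln(9) w. Only heating curves
#' are fitted: at the low strand concentrations used for electrospray,
#' tetramolecular association is far slower than dissociation, so cooling
#' branches are hysteretic and carry no equilibrium midpoint.
#'
#' @param data Data frame with numeric columns `temperature` (degrees C,
#'   strictly monotone, >= 10 points) and `absorbance`; if a `direction`
#'   column is present only `"heating"` rows are used (an all-cooling
#'   input is an error).
#' @param n_sigmoids 1 or 2.
#' @return A `melt_fit` object with components `coefficients` (tibble:
#'   `term`, `estimate`), `transitions` (tibble: `sigmoid`, `amplitude`,
#'   `t_mid`, `width`, `delta_t_10_90`, `degenerate`), `n_sigmoids`,
#'   `sigma` (residual SD), `fit` (the `nls` object), `data`. Supports
#'   `tidy()`, `glance()`, `predict()`, and [ggplot2::autoplot()].
#' @export
fit_melting <- function(data, n_sigmoids = 1L) {
  stopifnot(n_sigmoids %in% c(1L, 2L))
  df <- tibble::as_tibble(data)
  if ("direction" %in% names(df)) {
    df <- dplyr::filter(df, .data$direction == "heating")
    if (nrow(df) == 0) abort("no heating-direction points: cooling branches are hysteretic and are not fitted")
  }
  stopifnot(all(c("temperature", "absorbance") %in% names(df)))
  df <- df[order(df$temperature), c("temperature", "absorbance")]
  if (nrow(df) < 10) abort("need at least 10 points to fit a melting curve")
  if (any(diff(df$temperature) == 0)) abort("temperatures must be strictly monotone")

  init <- melt_inits(df, n_sigmoids)
  fml <- if (n_sigmoids == 1L) {
    absorbance ~ c0 + c1 * temperature +
      a1 / (1 + exp(-(temperature - t1) / w1))
  } else {
    absorbance ~ c0 + c1 * temperature +
      a1 / (1 + exp(-(temperature - t1) / w1)) +
      a2 / (1 + exp(-(temperature - t2) / w2))
  }
  fits <- lapply(init, function(st) {
    tryCatch(
      minpack.lm::nlsLM(fml, data = df, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL
    )
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    abort(paste0("melting fit did not converge from any of ", length(init),
                 " initialization(s)"))
  }
  fit <- fits[[which.min(vapply(fits, function(f) sum(residuals(f)^2),
                                numeric(1)))]]
  cf <- coef(fit)
  sg <- seq_len(n_sigmoids)
  amp <- cf[paste0("a", sg)]
  tmid <- cf[paste0("t", sg)]
  wid <- abs(cf[paste0("w", sg)])
  sigma <- sqrt(sum(residuals(fit)^2) / max(1, nrow(df) - length(cf)))
  transitions <- tibble::tibble(
    sigmoid = sg, amplitude = unname(amp), t_mid = unname(tmid),
    width = unname(wid), delta_t_10_90 = 2 * log(9) * unname(wid),
    degenerate = abs(unname(amp)) < 3 * sigma |
      unname(tmid) < min(df$temperature) | unname(tmid) > max(df$temperature) |
      2 * log(9) * unname(wid) > diff(range(df$temperature))
  )
  structure(
    list(coefficients = tibble::tibble(term = names(cf), estimate = unname(cf)),
         transitions = transitions, n_sigmoids = n_sigmoids, sigma = sigma,
         fit = fit, data = df),
    class = "melt_fit"
  )
}

# starting values: end-segment means anchor the baseline and total
# amplitude, level crossings of the smoothed curve locate midpoints (far
# more noise-robust than derivative extrema), and the 25-75% crossing span
# sets the width (t75 - t25 = 2 ln(3) w for a logistic)
melt_inits <- function(df, n_sigmoids) {
  t <- df$temperature; a <- df$absorbance
  n <- length(t)
  k <- max(3L, min(11L, 2L * (n %/% 20L) + 1L))
  sm <- stats::filter(a, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- a[is.na(sm)]
  sm <- as.numeric(sm)
  edge <- max(3L, n %/% 10L)
  a_lo <- mean(sm[seq_len(edge)])
  a_hi <- mean(sm[(n - edge + 1L):n])
  amp0 <- a_hi - a_lo
  if (abs(amp0) < 1e-12) amp0 <- diff(range(a)) + 1e-9
  cross <- function(frac) {
    lvl <- a_lo + frac * amp0
    idx <- if (amp0 > 0) which(sm >= lvl) else which(sm <= lvl)
    if (length(idx) == 0) return(mean(range(t)))
    t[idx[1]]
  }
  t50 <- cross(0.5)
  w0 <- max((cross(0.75) - cross(0.25)) / (2 * log(3)), diff(range(t)) / 100)
  c1 <- (sm[edge] - sm[1]) / (t[edge] - t[1])
  if (!is.finite(c1)) c1 <- 0
  c0 <- a_lo - c1 * t[1]
  span <- diff(range(t))
  if (n_sigmoids == 1L) {
    list(
      list(c0 = c0, c1 = c1, a1 = amp0, t1 = t50, w1 = w0),
      list(c0 = c0, c1 = 0, a1 = amp0, t1 = mean(range(t)), w1 = span / 8)
    )
  } else {
    list(
      list(c0 = c0, c1 = c1, a1 = amp0 / 2, t1 = cross(0.3), w1 = w0,
           a2 = amp0 / 2, t2 = cross(0.8), w2 = w0),
      list(c0 = c0, c1 = c1, a1 = amp0 / 2, t1 = t50 - span / 6, w1 = w0,
           a2 = amp0 / 2, t2 = t50 + span / 6, w2 = w0),
      list(c0 = c0, c1 = 0, a1 = amp0 / 2, t1 = min(t) + span / 3,
           w1 = span / 10, a2 = amp0 / 2, t2 = min(t) + 2 * span / 3,
           w2 = span / 10)
    )
  }
}

derivative_raw <- function(df) {
  t <- df$temperature; a <- df$absorbance
  n <- length(t)
  dd <- (a[c(2:n, n)] - a[c(1, 1:(n - 1))]) / (t[c(2:n, n)] - t[c(1, 1:(n - 1))])
  tibble::tibble(temperature = t, dA_dT = dd)
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("<melting fit> linear baseline + %d sigmoid(s), residual SD %.2g AU\n",
              x$n_sigmoids, x$sigma))
  for (i in seq_len(nrow(x$transitions))) {
    tr <- x$transitions[i, ]
    cat(sprintf("  transition %d: Tm = %.1f degC, amplitude %+.3g AU, 10-90%% width %.1f degC%s\n",
                tr$sigmoid, tr$t_mid, tr$amplitude, tr$delta_t_10_90,
                if (tr$degenerate) " [degenerate]" else ""))
  }
  invisible(x)
}

#' @export
predict.melt_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  predict(object$fit, newdata = newdata)
}

#' dA/dT profile of a melting curve or fit
#'
#' For a `melt_fit`, the analytic derivative of the fitted model evaluated
#' on a temperature grid, together with the extremum temperature of each
#' sigmoid term (which equals its midpoint Tm). For raw data, centred
#' finite differences.
#'
#' @param x A `melt_fit` or a data frame with `temperature`/`absorbance`.
#' @param n Grid size for the analytic profile.
#' @return A list with `profile` (tibble `temperature`, `dA_dT`) and
#'   `extrema` (tibble `sigmoid`, `temperature`; empty for raw data).
#' @export
derivative_profile <- function(x, n = 200L) {
  if (inherits(x, "melt_fit")) {
    cf <- setNames(x$coefficients$estimate, x$coefficients$term)
    tt <- seq(min(x$data$temperature), max(x$data$temperature), length.out = n)
    d <- rep(cf[["c1"]], n)
    for (k in seq_len(x$n_sigmoids)) {
      a <- cf[[paste0("a", k)]]; t0 <- cf[[paste0("t", k)]]
      w <- cf[[paste0("w", k)]]
      z <- exp(-(tt - t0) / w)
      d <- d + a * z / (w * (1 + z)^2)
    }
    list(profile = tibble::tibble(temperature = tt, dA_dT = d),
         extrema = tibble::tibble(sigmoid = seq_len(x$n_sigmoids),
                                  temperature = x$transitions$t_mid))
  } else {
    df <- tibble::as_tibble(x)
    if (nrow(df) < 10) abort("need at least 10 points for a derivative profile")
    list(profile = derivative_raw(df),
         extrema = tibble::tibble(sigmoid = integer(), temperature = numeric()))
  }
}

#' Choose between one- and two-transition melting models
#'
#' Fits both models and selects two sigmoids only when the small-sample
#' corrected information criterion (AICc) improves. Both fits are
#' returned; a near-zero-amplitude selected transition (e.g. on pure
#' noise) is flagged via the fit's `degenerate` column.
#'
#' @param data As in [fit_melting()].
#' @return A list with `n_sigmoids`, `fits` (list of the two `melt_fit`s,
#'   entry NULL if that fit failed), `aicc` (named numeric).
#' @export
select_model <- function(data) {
  fits <- list(
    `1` = tryCatch(fit_melting(data, 1L), error = function(e) NULL),
    `2` = tryCatch(fit_melting(data, 2L), error = function(e) NULL)
  )
  aicc_of <- function(f) {
    if (is.null(f)) return(Inf)
    k <- length(coef(f$fit)) + 1
    n <- nrow(f$data)
    AIC(f$fit) + 2 * k * (k + 1) / max(1, n - k - 1)
  }
  aicc <- vapply(fits, aicc_of, numeric(1))
  if (all(!is.finite(aicc))) abort("neither melting model converged")
  n_sig <- if (aicc[["2"]] < aicc[["1"]]) 2L else 1L
  list(n_sigmoids = n_sig, fits = fits, aicc = aicc)
}
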