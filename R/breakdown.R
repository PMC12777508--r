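#' Laboratory-frame collision energy
#'
#' The collision-cell setting is a potential in volts; the energy available
#' to an ion of absolute net charge n is voltage * n, in eV.
#'
#' @param voltage Collision voltage(s), V (>= 0).
#' @param n Absolute net charge (>= 1).
#' @return Energy in eV.
#' @examples
#' lab_frame_energy(30, 5)  # 150 eV
#' @export
lab_frame_energy <- function(voltage, n) {
  if (any(voltage < 0)) abort("collision voltage must be >= 0")
  if (any(n < 1)) abort("net charge must be >= 1")
  voltage * n
}

#' Bundle a CAD energy series
#'
#' @param voltages Strictly increasing collision voltages (V).
#' @param peak_lists List of peak lists, one per voltage.
#' @param precursor List describing the isolated precursor: `cation`, `x`,
#'   `n` (net charge used for the lab-frame energy conversion).
#' @return An `energy_series` tibble with columns `voltage`, `energy`,
#'   `peaks` (list-column) and a `precursor` attribute.
#' @export
energy_series <- function(voltages, peak_lists, precursor) {
  if (length(voltages) != length(peak_lists)) {
    abort("one peak list per voltage required")
  }
  if (any(diff(voltages) <= 0)) abort("voltages must be strictly increasing")
  if (is.null(precursor$n)) abort("precursor must carry its net charge n")
  out <- tibble::tibble(
    voltage = voltages,
    energy = lab_frame_energy(voltages, precursor$n),
    peaks = lapply(peak_lists, as_peak_list)
  )
  attr(out, "precursor") <- precursor
  class(out) <- c("energy_series", class(out))
  out
}

#' Build a breakdown curve from a CAD energy series
#'
#' Quantifies each energy point with the CAD aggregation rules (NH3-loss
#' satellites fold into Q; all covalent-cleavage products form one class F)
#' and returns species-percentage trajectories versus laboratory-frame
#' energy. A failed quantification at one point is reported and skipped,
#' not fatal.
#'
#' @param series An [energy_series()].
#' @param strand An [rna_strand()] or sequence string.
#' @param annot Optional [tetrad_annotation()] for fragment region labels.
#' @param candidates Optional candidate table; by default assemblies of
#'   order 1-4 (cation counts 0..precursor x, charges 1..precursor n, NH3
#'   losses up to x for ammonium) plus a/c/w/y fragment ions.
#' @param tol_ppm Peak-matching tolerance.
#' @return A `breakdown_curve`: long tibble with columns `energy`,
#'   `species`, `pct`, plus attributes `precursor`, `initial_q_pct`, and
#'   `assignments` (per-point assignment tables).
#' @export
build_breakdown <- function(series, strand, annot = NULL, candidates = NULL,
                            tol_ppm = 10) {
  stopifnot(inherits(series, "energy_series"))
  if (nrow(series) < 4) abort("a breakdown curve needs at least 4 energy points")
  strand <- as_strand(strand)
  prec <- attr(series, "precursor")
  if (is.null(candidates)) {
    nh3 <- if (identical(prec$cation, "NH4")) 0:prec$x else 0L
    candidates <- dplyr::bind_rows(
      species_table(strand, order = 1:4, cation = prec$cation,
                    x = 0:prec$x, n = seq_len(prec$n), nh3_losses = nh3),
      candidate_fragments(strand, annot, max_charge = max(1L, prec$n - 1L)),
      candidate_base_losses(strand, order = 4L, cation = prec$cation,
                            x = prec$x, n = prec$n)
    )
  }
  quant_one <- function(pl, energy) {
    tryCatch({
      asg <- assign_peaks(pl, candidates, tol_ppm)
      sp <- species_percentages(asg)
      list(pct = dplyr::mutate(sp, energy = energy), asg = dplyr::mutate(asg, energy = energy))
    }, error = function(e) {
      warn(sprintf("quantification failed at %.1f eV: %s", energy, conditionMessage(e)))
      NULL
    })
  }
  res <- purrr::map2(series$peaks, series$energy, quant_one)
  res <- purrr::compact(res)
  if (length(res) == 0) abort("quantification failed at every energy point")
  curve <- purrr::map_dfr(res, "pct") |>
    dplyr::select("energy", "species", "pct" = "species_pct") |>
    dplyr::arrange(.data$energy, .data$species)
  q0 <- dplyr::filter(curve, .data$energy == min(.data$energy),
                      .data$species == "Q")$pct
  attr(curve, "precursor") <- prec
  attr(curve, "initial_q_pct") <- if (length(q0)) q0 else 0
  attr(curve, "assignments") <- purrr::map_dfr(res, "asg")
  class(curve) <- c("breakdown_curve", class(curve))
  curve
}

#' Breakdown curve directly from percentage trajectories
#'
#' Convenience constructor when species percentages per energy are already
#' known (e.g. digitised or simulated trajectories) without peak lists.
#'
#' @param data Tibble with columns `energy`, `species`, `pct`.
#' @param precursor Optional precursor description.
#' @return A `breakdown_curve`.
#' @export
as_breakdown_curve <- function(data, precursor = NULL) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("energy", "species", "pct") %in% names(data)))
  q0 <- dplyr::filter(data, .data$energy == min(.data$energy),
                      .data$species == "Q")$pct
  attr(data, "precursor") <- precursor
  attr(data, "initial_q_pct") <- if (length(q0)) q0 else 0
  class(data) <- c("breakdown_curve", class(data))
  data
}

#' Fit the energy of 50% quadruplex dissociation (E50)
#'
#' Fits the surviving-quadruplex percentage versus laboratory-frame energy
#' with a three-parameter logistic, Q(E) = P0 / (1 + exp((E - E_mid)/w)),
#' and solves for the energy where the fitted curve crosses 50% of all
#' detected species (the absolute convention): E50 = E_mid + w log(P0/50 - 1).
#' Linear interpolation between the bracketing points is always computed as
#' the reference method and is returned as the fallback when the nonlinear
#' fit fails. When the precursor enters pre-depleted (initial Q < 100%,
#' from unintended source activation), the energy at which half of the
#' *initial* quadruplexes survive is reported alongside as `e50_relative`.
#'
#' @param curve A `breakdown_curve`.
#' @return An `e50_fit` object (list with `e50`, `e50_interp`,
#'   `e50_relative`, `p0`, `e_mid`, `width`, `initial_q_pct`, `method`,
#'   `fit`, `data`). Supports [generics::tidy()] and [generics::glance()].
#' @export
fit_e50 <- function(curve) {
  stopifnot(inherits(curve, "breakdown_curve"))
  q <- dplyr::filter(tibble::as_tibble(curve), .data$species == "Q") |>
    dplyr::arrange(.data$energy)
  if (nrow(q) < 4) abort("need at least 4 energy points on the Q trajectory")
  if (min(q$pct) > 50 || max(q$pct) < 50) {
    abort("E50 not bracketed: Q trajectory does not cross 50% within the scanned range")
  }
  # reference method: first downward crossing, linear interpolation
  below <- which(q$pct <= 50)[1]
  e50_interp <- if (q$pct[below] == 50) q$energy[below] else {
    i <- below - 1L
    q$energy[i] + (50 - q$pct[i]) * (q$energy[below] - q$energy[i]) /
      (q$pct[below] - q$pct[i])
  }
  p0_start <- max(q$pct)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      pct ~ p0 / (1 + exp((energy - e_mid) / w)),
      data = q,
      start = list(p0 = p0_start, e_mid = e50_interp,
                   w = diff(range(q$energy)) / 10),
      lower = c(p0 = 1, e_mid = -Inf, w = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    cf <- coef(fit)
    e50 <- if (cf[["p0"]] > 50) {
      cf[["e_mid"]] + cf[["w"]] * log(cf[["p0"]] / 50 - 1)
    } else NA_real_
    method <- "logistic_fit"
    if (!is.finite(e50)) { e50 <- e50_interp; method <- "interpolation" }
  } else {
    cf <- c(p0 = p0_start, e_mid = NA_real_, w = NA_real_)
    e50 <- e50_interp
    method <- "interpolation"
  }
  init_q <- attr(curve, "initial_q_pct")
  e50_rel <- if (!is.null(init_q) && init_q < 99.5 && !is.null(fit)) {
    cf2 <- coef(fit)
    half <- init_q / 2
    if (cf2[["p0"]] > half) cf2[["e_mid"]] + cf2[["w"]] * log(cf2[["p0"]] / half - 1)
    else NA_real_
  } else e50
  structure(
    list(e50 = e50, e50_interp = e50_interp, e50_relative = e50_rel,
         p0 = unname(cf[["p0"]]), e_mid = unname(cf[["e_mid"]]),
         width = unname(cf[["w"]]), initial_q_pct = init_q,
         method = method, fit = fit, data = q),
    class = "e50_fit"
  )
}

#' @export
print.e50_fit <- function(x, ...) {
  cat(sprintf("<E50 fit> E50 = %.1f eV (%s; interpolation %.1f eV)\n",
              x$e50, x$method, x$e50_interp))
  cat(sprintf("  logistic: P0 = %.1f%%, midpoint = %.1f eV, width = %.1f eV\n",
              x$p0, x$e_mid, x$width))
  if (!is.null(x$initial_q_pct) && x$initial_q_pct < 99.5) {
    cat(sprintf("  precursor pre-depleted (initial Q = %.1f%%); half-of-initial E50 = %.1f eV\n",
                x$initial_q_pct, x$e50_relative))
  }
  invisible(x)
}

#' Compare quadruplex stabilities across precursors
#'
#' Pairwise E50 ratios and percent differences between fitted breakdown
#' curves, plus (when net charges are supplied) a report on whether E50
#' decreases monotonically with increasing net charge — the Coulombic
#' destabilisation signature.
#'
#' @param fits List of [fit_e50()] objects (or numeric E50 values).
#' @param labels Character labels, one per fit.
#' @param n Optional net charges, one per fit, for the monotonicity report.
#' @return A `stability_comparison` tibble of pairwise comparisons with
#'   columns `label_a`, `label_b`, `e50_a`, `e50_b`, `ratio`, `pct_diff`
#'   (100*(a-b)/b), and attribute `monotone_decreasing_in_n` (logical or NA).
#' @export
compare_stabilities <- function(fits, labels = NULL, n = NULL) {
  e50 <- vapply(fits, function(f) if (inherits(f, "e50_fit")) f$e50 else as.numeric(f),
                numeric(1))
  k <- length(e50)
  if (k < 2) abort("need at least two curves to compare")
  if (is.null(labels)) labels <- paste0("curve", seq_len(k))
  pairs <- utils::combn(k, 2)
  out <- tibble::tibble(
    label_a = labels[pairs[1, ]], label_b = labels[pairs[2, ]],
    e50_a = e50[pairs[1, ]], e50_b = e50[pairs[2, ]],
    ratio = e50[pairs[1, ]] / e50[pairs[2, ]],
    pct_diff = 100 * (e50[pairs[1, ]] - e50[pairs[2, ]]) / e50[pairs[2, ]]
  )
  mono <- if (!is.null(n)) {
    ord <- order(n)
    all(diff(e50[ord]) < 0)
  } else NA
  attr(out, "monotone_decreasing_in_n") <- mono
  class(out) <- c("stability_comparison", class(out))
  out
}
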