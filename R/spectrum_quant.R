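#' Validate a centroided peak list
#'
#' @param x A data frame with numeric columns `mz` and `intensity`.
#' @return A tibble sorted by m/z.
#' @export
as_peak_list <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("mz", "intensity") %in% names(x))) {
    abort("a peak list needs 'mz' and 'intensity' columns")
  }
  if (any(x$mz <= 0)) abort("m/z values must be positive")
  if (any(x$intensity < 0)) abort("intensities must be non-negative")
  dplyr::arrange(x, .data$mz)
}

#' Fragment-ion candidates for peak assignment
#'
#' Expands the neutral a/c/w/y fragments of a strand over charge states
#' 1..`max_charge` as deprotonated anions, m/z = (mass - n m(H+)) / n.
#' Undetectable fragments (y1) are excluded.
#'
#' @param strand An [rna_strand()] or sequence string.
#' @param annot Optional [tetrad_annotation()] carried through to `region`.
#' @param series Fragment series to include.
#' @param max_charge Highest fragment net charge (typically parent n - 1).
#' @return A tibble with columns `label`, `class` (`"fragment"`), `series`,
#'   `index`, `site`, `region`, `order`, `cation`, `x`, `h`, `n`, `nh3`, `mz`.
#' @export
candidate_fragments <- function(strand, annot = NULL,
                                series = c("a", "c", "w", "y"),
                                max_charge = 3L) {
  stopifnot(max_charge >= 1)
  frs <- enumerate_fragments(strand, annot, series)
  frs <- dplyr::filter(frs, .data$detectable)
  tidyr::expand_grid(frs, n = seq_len(max_charge)) |>
    dplyr::mutate(
      mz = (.data$mass - .data$n * ms_constants[["proton"]]) / .data$n,
      label = paste0(.data$series, .data$index, "^", .data$n, "-"),
      class = "fragment", order = NA_integer_, cation = "none",
      x = 0L, h = .data$n, nh3 = 0L
    ) |>
    dplyr::select("label", "class", "series", "index", "site", "region",
                  "order", "cation", "x", "h", "n", "nh3", "mz")
}

#' Assign spectrum peaks to theoretical species
#'
#' Matches each peak to the nearest candidate within a ppm tolerance.
#' Ambiguities resolve to the smallest ppm error; exact ties resolve to
#' the lower charge state. Unassigned peaks are kept with `assigned =
#' FALSE` so that nothing silently disappears from the intensity budget.
#'
#' @param peaks A peak list (see [as_peak_list()]).
#' @param candidates A candidate table from [species_table()] and/or
#'   [candidate_fragments()] (rows bound together); must contain `label`,
#'   `class`, `n`, `mz`.
#' @param tol_ppm Matching tolerance in parts per million (default 10).
#' @return A tibble: the peak list plus the matched candidate columns,
#'   `ppm_error`, and `assigned`.
#' @export
assign_peaks <- function(peaks, candidates, tol_ppm = 10) {
  peaks <- as_peak_list(peaks)
  if (nrow(candidates) == 0) abort("candidate list is empty")
  if (tol_ppm <= 0) abort("tol_ppm must be positive")
  cand <- dplyr::mutate(candidates, .cand_row = dplyr::row_number())
  pick <- function(mz) {
    ppm <- (mz - cand$mz) / cand$mz * 1e6
    ok <- which(abs(ppm) <= tol_ppm)
    if (length(ok) == 0) return(NA_integer_)
    # ties within 1e-4 ppm (far below any real mass accuracy) resolve to
    # the lower charge state; exact ties arise for mass-degenerate species
    best <- ok[abs(ppm[ok]) <= min(abs(ppm[ok])) + 1e-4]
    if (length(best) > 1) best <- best[which.min(cand$n[best])]
    best[1]
  }
  idx <- vapply(peaks$mz, pick, integer(1))
  matched <- cand[ifelse(is.na(idx), 1L, idx), setdiff(names(cand), ".cand_row")]
  matched <- dplyr::rename(matched, mz_theoretical = "mz")
  matched[is.na(idx), ] <- NA
  out <- dplyr::bind_cols(peaks, matched)
  out$ppm_error <- (out$mz - out$mz_theoretical) / out$mz_theoretical * 1e6
  out$assigned <- !is.na(idx)
  out
}

#' Species percentages from an assignment table
#'
#' Sums assigned intensity over all charge states, adduct counts, and
#' NH3-loss satellites of each species and expresses each species as a
#' percentage of total assigned signal. Aggregation follows the
#' native-MS interpretation rules for these quadruplexes: tetramers with
#' extra cations (adducts on deprotonated phosphates) and tetramers that
#' have shed NH3 still count as Q; fragment ions pool into one covalent-
#' cleavage class `"F"`.
#'
#' @param assignments Output of [assign_peaks()].
#' @return A `species_quant` tibble with columns `species` (M/D/T/Q/F),
#'   `intensity`, `species_pct` (sums to 100).
#' @export
species_percentages <- function(assignments) {
  asg <- dplyr::filter(assignments, .data$assigned)
  if (nrow(asg) == 0) abort("no assigned peaks to quantify")
  out <- asg |>
    dplyr::mutate(species = dplyr::case_when(
      .data$class %in% c("fragment", "base_loss") ~ "F",
      .data$order == 1L ~ "M",
      .data$order == 2L ~ "D",
      .data$order == 3L ~ "T",
      .data$order >= 4L ~ "Q"
    )) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    dplyr::mutate(species_pct = 100 * .data$intensity / sum(.data$intensity)) |>
    dplyr::arrange(factor(.data$species, levels = c("Q", "T", "D", "M", "F")))
  class(out) <- c("species_quant", class(out))
  out
}

#' Strand-weighted molecule percentages
#'
#' Converts species percentages (share of ion signal per species) into the
#' percentage of RNA molecules residing in each species, weighting each
#' species by its stoichiometry: 1 strand per monomer, 2 per dimer, 3 per
#' trimer, 4 per tetramer. With species shares Q 62, M 28, D 10 this gives
#' 4*62 / (4*62 + 28 + 2*10) = 83.8% of molecules in the quadruplex.
#' Fragment classes carry no strand stoichiometry and are excluded.
#'
#' @param species_pct A data frame with columns `species` (labels among
#'   M, D, T, Q) and `species_pct`, e.g. from [species_percentages()].
#' @return The input with a `molecule_pct` column added (sums to 100 over
#'   the stoichiometric species).
#' @examples
#' molecule_percentages(
#'   tibble::tibble(species = c("Q", "M", "D"), species_pct = c(62, 28, 10))
#' )
#' @export
molecule_percentages <- function(species_pct) {
  orders <- c(M = 1, D = 2, T = 3, Q = 4)
  df <- tibble::as_tibble(species_pct)
  if (!all(c("species", "species_pct") %in% names(df))) {
    abort("need columns 'species' and 'species_pct'")
  }
  df <- dplyr::filter(df, .data$species %in% names(orders))
  if (nrow(df) == 0 || sum(df$species_pct) == 0) {
    abort("no stoichiometric species with nonzero share")
  }
  w <- unname(orders[df$species]) * df$species_pct
  df$molecule_pct <- 100 * w / sum(w)
  df
}
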