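#' Classify covalent-cleavage products and tally their shares
#'
#' Splits assigned covalent products into three classes — nucleobase loss,
#' c/y backbone fragments, and a/w backbone fragments — per energy, and
#' further splits the c/y class by cleavage region (overhang versus
#' inter-tetrad). The low-energy excess of overhang cleavage over its
#' random expectation is the covalent-chemistry fingerprint of an intact
#' gas-phase quadruplex.
#'
#' @param assignments Assignment table containing fragment and/or
#'   neutral-loss rows; an `energy` column groups per-energy tallies (a
#'   single implicit energy otherwise). Fragment rows are recognised by
#'   `class == "fragment"` with a `series` column; base-loss rows by
#'   `class == "base_loss"`.
#' @param strand An [rna_strand()] or sequence string.
#' @param annot A [tetrad_annotation()]; used to (re)derive fragment
#'   regions from cleavage sites.
#' @param weight `"intensity"` (default) or `"count"`.
#' @param detectable_only Exclude MS-silent fragments (y1) from all
#'   tallies (default TRUE; y1 is never observable for 3'-OH RNA anyway).
#' @return A `fragment_tally` list with tibbles `classes` (`energy`,
#'   `class`, `share`) and `cy_regions` (`energy`, `region`, `share`);
#'   shares are percentages summing to 100 within each energy.
#' @export
classify_covalent_products <- function(assignments, strand, annot,
                                       weight = c("intensity", "count"),
                                       detectable_only = TRUE) {
  weight <- match.arg(weight)
  strand <- as_strand(strand)
  sites <- cleavage_sites(strand, annot)
  asg <- tibble::as_tibble(assignments)
  if (!"energy" %in% names(asg)) asg$energy <- NA_real_
  if ("assigned" %in% names(asg)) asg <- dplyr::filter(asg, .data$assigned)
  cov <- dplyr::filter(asg, .data$class %in% c("fragment", "base_loss"))
  if (nrow(cov) == 0) abort("no covalent-cleavage products among the assignments")
  unclassifiable <- dplyr::filter(
    cov, .data$class == "fragment" & !(.data$series %in% c("a", "c", "w", "y")))
  if (nrow(unclassifiable) > 0) {
    warn(sprintf("%d fragment assignment(s) outside the a/c/w/y series were dropped",
                 nrow(unclassifiable)))
    cov <- dplyr::anti_join(cov, unclassifiable, by = names(cov))
  }
  if (detectable_only && "index" %in% names(cov)) {
    cov <- dplyr::filter(cov, !(.data$class == "fragment" &
                                  .data$series == "y" & .data$index == 1L))
  }
  cov <- dplyr::mutate(
    cov,
    w = if (weight == "intensity") .data$intensity else 1,
    prod_class = dplyr::case_when(
      .data$class == "base_loss" ~ "base_loss",
      .data$series %in% c("c", "y") ~ "cy",
      .data$series %in% c("a", "w") ~ "aw"
    )
  )
  classes <- cov |>
    dplyr::group_by(.data$energy, .data$prod_class) |>
    dplyr::summarise(w = sum(.data$w), .groups = "drop_last") |>
    dplyr::mutate(share = 100 * .data$w / sum(.data$w)) |>
    dplyr::ungroup() |>
    dplyr::select("energy", class = "prod_class", "share")
  cy <- dplyr::filter(cov, .data$prod_class == "cy") |>
    dplyr::select(-dplyr::any_of("region")) |>
    dplyr::left_join(sites, by = "site") |>
    dplyr::group_by(.data$energy, .data$region) |>
    dplyr::summarise(w = sum(.data$w), .groups = "drop_last") |>
    dplyr::mutate(share = 100 * .data$w / sum(.data$w)) |>
    dplyr::ungroup() |>
    dplyr::select("energy", "region", "share")
  structure(list(classes = classes, cy_regions = cy), class = "fragment_tally")
}

#' Expected region shares under random backbone cleavage
#'
#' If every phosphodiester bond were equally likely to cleave, the share of
#' c/y fragments from the overhang would equal the fraction of cleavage
#' sites lying in the overhang — 2 of 5 sites (40%) for UAGGGU with its
#' tetrad core at positions 3-6. With `unit = "ions"` the expectation is
#' instead taken over detectable fragment ions (each site yields one c and
#' one y, minus the MS-silent y1).
#'
#' @param strand An [rna_strand()] or sequence string.
#' @param annot A [tetrad_annotation()].
#' @param unit `"sites"` (default, the random-cleavage convention) or
#'   `"ions"`.
#' @return A tibble with columns `region`, `n`, `expected_share` (%).
#' @export
random_cleavage_expectation <- function(strand, annot,
                                        unit = c("sites", "ions")) {
  unit <- match.arg(unit)
  strand <- as_strand(strand)
  sites <- cleavage_sites(strand, annot)
  L <- strand$length
  if (unit == "sites") {
    counts <- dplyr::count(sites, .data$region, name = "n")
  } else {
    ions <- dplyr::bind_rows(
      dplyr::mutate(sites, series = "c", index = .data$site),
      dplyr::mutate(sites, series = "y", index = L - .data$site)
    ) |>
      dplyr::filter(!(.data$series == "y" & .data$index == 1L))
    counts <- dplyr::count(ions, .data$region, name = "n")
  }
  counts <- tidyr::complete(counts,
                            region = c("overhang", "inter_tetrad"),
                            fill = list(n = 0L))
  dplyr::mutate(counts, expected_share = 100 * .data$n / sum(.data$n))
}
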