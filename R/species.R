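#' Monoisotopic mass of an adducted cation
#'
#' Ion masses carry the electron correction: m(K+) = m(K) - m(e),
#' m(NH4+) = m(N) + 4 m(H) - m(e).
#'
#' @param cation One of `"K"`, `"NH4"`, `"Na"`, `"none"`.
#' @return Mass in Da (`0` for `"none"`).
#' @export
cation_mass <- function(cation = c("K", "NH4", "Na", "none")) {
  cation <- match.arg(cation)
  am <- the$mono_mass
  e <- ms_constants[["electron"]]
  switch(cation,
         K    = am[["K"]] - e,
         Na   = am[["Na"]] - e,
         NH4  = am[["N"]] + 4 * am[["H"]] - e,
         none = 0)
}

#' m/z of a multimeric RNA-cation species
#'
#' Computes the monoisotopic m/z of an `(a RNA + x Cat+ - h H+)^n-` ion,
#' the species nomenclature of native MS of tetramolecular quadruplexes:
#' `a` strands (1 = monomer M, 2 = dimer D, 3 = trimer T, 4 = tetramer Q),
#' `x` adducted monovalent cations, and `h` deprotonations. Charge balance
#' requires `n = h - x`. Optionally `nh3_losses` neutral NH3 molecules are
#' subtracted (ammonium-adducted quadruplexes shed NH3 on gentle
#' activation, leaving the proton behind).
#'
#' @param strand An [rna_strand()] or sequence string.
#' @param order Number of strands `a` (1-4 in practice, any >= 1 allowed).
#' @param cation Adducted cation: `"K"`, `"NH4"`, `"Na"` or `"none"`.
#' @param x Cation count (>= 0).
#' @param n Net negative charge (>= 1 for an observable ion).
#' @param h Deprotonation count; defaults to `n + x` by charge balance and
#'   is checked against it if supplied.
#' @param nh3_losses Number of NH3 molecules lost (default 0).
#' @return m/z in Th.
#' @examples
#' mz_species("UAGGGU", order = 4, cation = "K", x = 3, n = 4)   # 1941.749
#' mz_species("UAGGGU", order = 4, cation = "NH4", x = 3, n = 5) # 1540.640
#' @export
mz_species <- function(strand, order = 4L, cation = "K", x = 3L, n,
                       h = n + x, nh3_losses = 0L) {
  strand <- as_strand(strand)
  stopifnot(order >= 1, x >= 0, nh3_losses >= 0)
  if (n == 0) abort("uncharged species has no m/z")
  if (n < 0) abort("net charge n must be >= 1 (negative-mode charge count)")
  if (h != n + x) {
    abort(sprintf("charge balance violated: h (%d) must equal n + x (%d)",
                  as.integer(h), as.integer(n + x)))
  }
  m_nh3 <- mono_mass(comp_nh3())
  (order * strand$mono_mass + x * cation_mass(cation) -
     h * ms_constants[["proton"]] - nh3_losses * m_nh3) / n
}

#' Theoretical species grid
#'
#' Tabulates m/z for every combination of oligomer order, cation count and
#' net charge requested — the table of candidate ions that peak assignment
#' matches against, and (for `order = 4`, `x = 1:3`, `n = 4:8`) the
#' calculated m/z grid of the tetrameric quadruplex ions.
#'
#' @param strand An [rna_strand()] or sequence string.
#' @param order Integer vector of oligomer orders.
#' @param cation Single cation type for the adducted species.
#' @param x Integer vector of cation counts.
#' @param n Integer vector of net charges.
#' @param nh3_losses Integer vector of NH3-loss counts (only meaningful for
#'   `cation = "NH4"`; losses exceeding `x` are dropped).
#' @return A tibble with columns `label`, `class` (`"assembly"`), `order`,
#'   `cation`, `x`, `h`, `n`, `nh3`, `mz`, one row per species, sorted by
#'   `order`, `x`, `n`.
#' @examples
#' species_table("UAGGGU", order = 4, cation = "K", x = 1:3, n = 4:8)
#' @export
species_table <- function(strand, order = 1:4, cation = "K", x = 0:3,
                          n = 2:8, nh3_losses = 0L) {
  strand <- as_strand(strand)
  grid <- tidyr::expand_grid(order = as.integer(order), x = as.integer(x),
                             n = as.integer(n), nh3 = as.integer(nh3_losses))
  grid <- dplyr::filter(grid, .data$nh3 <= .data$x | .data$nh3 == 0L)
  if (cation != "NH4") grid <- dplyr::filter(grid, .data$nh3 == 0L)
  if (cation == "none") grid <- dplyr::filter(grid, .data$x == 0L)
  cat_type <- cation
  grid |>
    dplyr::mutate(
      cation = cat_type,
      h = .data$n + .data$x,
      mz = purrr::pmap_dbl(
        list(.data$order, .data$x, .data$n, .data$nh3),
        function(a, x, n, nh3) {
          mz_species(strand, order = a, cation = cat_type, x = x, n = n,
                     nh3_losses = nh3)
        }
      ),
      label = species_label(.data$order, cat_type, .data$x, .data$n, .data$nh3),
      class = "assembly"
    ) |>
    dplyr::arrange(.data$order, .data$x, .data$n) |>
    dplyr::select("label", "class", "order", "cation", "x", "h", "n",
                  "nh3", "mz")
}

species_label <- function(order, cation, x, n, nh3 = 0L) {
  letter <- c("M", "D", "T", "Q")[pmin(order, 4L)]
  letter[order > 4] <- paste0(order[order > 4], "mer")
  base <- ifelse(x > 0, paste0("(", letter, "+", x, cation, ")"), letter)
  base <- ifelse(nh3 > 0, paste0(base, "-", nh3, "NH3"), base)
  paste0(base, n, "-")
}
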