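#' Base-loss product candidates
#'
#' Covalent nucleobase-loss products (guanine, adenine) from an otherwise
#' intact assembly, at the precursor charge: the dominant covalent channel
#' of low-charge quadruplex ions below the backbone-cleavage regime.
#'
#' @param strand An [rna_strand()] or sequence string.
#' @param order,cation,x,n Precursor species description.
#' @param losses Bases considered lost.
#' @param max_count Highest loss count per base.
#' @return Candidate tibble rows with `class = "base_loss"`.
#' @export
candidate_base_losses <- function(strand, order = 4L, cation = "K", x = 3L,
                                  n = 4L, losses = c("guanine", "adenine"),
                                  max_count = 2L) {
  parent <- species_table(strand, order = order, cation = cation, x = x, n = n)
  grid <- tidyr::expand_grid(loss = losses, count = seq_len(max_count))
  purrr::pmap_dfr(grid, function(loss, count) {
    nl <- neutral_loss_products(parent, loss, count)
    tibble::tibble(
      label = paste0(parent$label, "-", count, toupper(substr(loss, 1, 1))),
      class = "base_loss", loss = loss, count = count,
      order = parent$order, cation = cation, x = as.integer(x),
      h = parent$h, n = as.integer(n), nh3 = 0L, mz = nl$mz
    )
  })
}

#' Expand candidates over their isotope envelopes
#'
#' Replicates each candidate row at the m/z positions of its first
#' `max_peaks` isotopologue bins (spacing ~1 nucleon / charge), so that
#' envelope peaks are assigned and summed into the same species. This is
#' the envelope-matching mode of quantification; monoisotopic-only
#' matching is the default elsewhere.
#'
#' @param candidates Candidate table from [species_table()],
#'   [candidate_fragments()] or [candidate_base_losses()].
#' @param strand The [rna_strand()] the candidates were built from.
#' @param max_peaks Isotopologue bins per candidate.
#' @return The candidate table with one row per isotope peak and an
#'   `isotope` column (0 = monoisotopic).
#' @export
expand_isotopes <- function(candidates, strand, max_peaks = 5L) {
  strand <- as_strand(strand)
  purrr::pmap_dfr(candidates, function(...) {
    row <- tibble::tibble(...)
    comp <- ion_composition(strand, row)
    pat <- isotope_pattern(comp, max_peaks = max_peaks)
    offs <- pat$mass - pat$mass[1]
    out <- row[rep(1L, nrow(pat)), ]
    out$isotope <- seq_len(nrow(pat)) - 1L
    out$mz <- row$mz + offs / row$n
    out$rel_abundance <- pat$abundance
    out
  })
}

# elemental composition of a candidate ion (charge-carrier hydrogens
# removed; electron masses ignored, irrelevant for envelope shape)
ion_composition <- function(strand, row) {
  comp <- if (identical(row$class, "fragment")) {
    parse_formula(row$formula)
  } else {
    as.integer(row$order) * strand$composition
  }
  if (!is.null(row$x) && !is.na(row$x) && row$x > 0) {
    add <- switch(row$cation,
                  K = elemental_composition(K = 1),
                  Na = elemental_composition(Na = 1),
                  NH4 = elemental_composition(N = 1, H = 4),
                  abort("unknown cation for isotope expansion"))
    comp <- comp + as.integer(row$x) * add
  }
  h <- if (!is.null(row$h) && !is.na(row$h)) as.integer(row$h) else as.integer(row$n)
  comp <- comp - elemental_composition(H = h)
  if (!is.null(row$nh3) && !is.na(row$nh3) && row$nh3 > 0) {
    comp <- comp - as.integer(row$nh3) * comp_nh3()
  }
  if (identical(row$class, "base_loss")) {
    lc <- switch(row$loss, guanine = comp_guanine(), adenine = comp_adenine())
    comp <- comp - as.integer(row$count) * lc
  }
  comp
}
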