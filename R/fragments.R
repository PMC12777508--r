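#' Annotate tetrad-forming positions of a quadruplex strand
#'
#' Records which residues of a strand participate in stacked tetrads of a
#' tetramolecular quadruplex; the remaining positions form the overhang.
#' For the 6-mer UAGGGU the three G residues and the 3'-terminal U form
#' tetrads (positions 3-6), leaving the 5' UA dinucleotide overhang.
#'
#' @param length Strand length L.
#' @param tetrad_positions 1-based residue indices participating in tetrads.
#' @param tetrad_kinds Character vector, one of `"G"`/`"U"` per position;
#'   defaults to `"G"` everywhere.
#' @return A `tetrad_annotation`: a tibble with columns `position`, `kind`
#'   and a `strand_length` attribute.
#' @examples
#' tetrad_annotation(6, 3:6, c("G", "G", "G", "U"))
#' @export
tetrad_annotation <- function(length, tetrad_positions,
                              tetrad_kinds = rep("G", base::length(tetrad_positions))) {
  stopifnot(length >= 1)
  tetrad_positions <- as.integer(tetrad_positions)
  if (any(tetrad_positions < 1 | tetrad_positions > length)) {
    abort("tetrad positions must lie within 1..L")
  }
  if (anyDuplicated(tetrad_positions)) abort("tetrad positions must be distinct")
  if (base::length(tetrad_kinds) != base::length(tetrad_positions)) {
    abort("one tetrad kind per tetrad position required")
  }
  if (!all(tetrad_kinds %in% c("G", "U"))) abort("tetrad kinds must be 'G' or 'U'")
  out <- tibble::tibble(position = tetrad_positions, kind = tetrad_kinds) |>
    dplyr::arrange(.data$position)
  attr(out, "strand_length") <- as.integer(length)
  class(out) <- c("tetrad_annotation", class(out))
  out
}

check_annotation <- function(strand, annot) {
  if (!inherits(annot, "tetrad_annotation")) abort("annot must be a tetrad_annotation")
  if (attr(annot, "strand_length") != strand$length) {
    abort(sprintf("annotation length (%d) does not match strand length (%d)",
                  attr(annot, "strand_length"), strand$length))
  }
  invisible(annot)
}

#' Classify backbone cleavage sites as overhang or inter-tetrad
#'
#' Site k is the phosphodiester linkage between residues k and k + 1
#' (k = 1..L-1). A site is in the overhang region iff at least one of its
#' flanking residues lies outside the tetrad core; sites flanked by two
#' tetrad residues cleave between tetrads.
#'
#' @param strand An [rna_strand()] or sequence string.
#' @param annot A [tetrad_annotation()].
#' @return A tibble with columns `site` (1..L-1) and `region`
#'   (`"overhang"` or `"inter_tetrad"`).
#' @examples
#' cleavage_sites(rna_strand("UAGGGU"), tetrad_annotation(6, 3:6, c("G","G","G","U")))
#' @export
cleavage_sites <- function(strand, annot) {
  strand <- as_strand(strand)
  check_annotation(strand, annot)
  sites <- seq_len(strand$length - 1L)
  in_tetrad <- sites %in% annot$position & (sites + 1L) %in% annot$position
  tibble::tibble(site = sites,
                 region = ifelse(in_tetrad, "inter_tetrad", "overhang"))
}

#' Enumerate CAD backbone fragments
#'
#' Generates the neutral a/c/w/y fragments of an RNA strand under the
#' standard oligonucleotide (McLuckey) nomenclature, built by composition
#' arithmetic for a 5'-OH/3'-OH strand: the 5'-side prefix of i residues
#' with (i-1) linkages defines b_i; c_i = b_i + HPO3 and a_i = b_i - H2O;
#' the 3'-side suffix of j residues defines y_j, and w_j = y_j + HPO3.
#' c/y pairs and a/w pairs are complementary across one cleavage site.
#' y1 (neutral nucleoside for 3'-OH RNA) is enumerated but flagged
#' undetectable, since it carries no phosphate to hold a charge.
#'
#' @param strand An [rna_strand()] or sequence string.
#' @param annot Optional [tetrad_annotation()]; if given, each fragment is
#'   labelled with the region of its cleavage site.
#' @param series Subset of `c("a", "c", "w", "y")`.
#' @return A tibble with columns `series`, `index`, `site`, `formula`,
#'   `mass` (neutral monoisotopic Da), `region` (or `NA`), `detectable`.
#' @examples
#' enumerate_fragments("UAGGGU", series = c("c", "y"))
#' @export
enumerate_fragments <- function(strand, annot = NULL,
                                series = c("a", "c", "w", "y")) {
  strand <- as_strand(strand)
  series <- match.arg(series, several.ok = TRUE)
  if (length(series) == 0) abort("at least one fragment series required")
  res <- strsplit(strand$sequence, "")[[1]]
  L <- strand$length
  if (L < 2) abort("fragments require a strand of length >= 2")
  regions <- if (is.null(annot)) NULL else cleavage_sites(strand, annot)

  one <- function(ser, i) {
    if (ser %in% c("a", "c")) {
      comp <- strand_composition(res[seq_len(i)])
      comp <- if (ser == "c") comp + comp_hpo3() else comp - comp_h2o()
      site <- i
    } else {
      comp <- strand_composition(res[(L - i + 1L):L])
      if (ser == "w") comp <- comp + comp_hpo3()
      site <- L - i
    }
    tibble::tibble(series = ser, index = i, site = site,
                   formula = format(comp), mass = mono_mass(comp))
  }

  out <- tidyr::expand_grid(series = series, index = seq_len(L - 1L)) |>
    purrr::pmap(function(series, index) one(series, index)) |>
    dplyr::bind_rows() |>
    dplyr::mutate(detectable = !(.data$series == "y" & .data$index == 1L))
  if (!is.null(regions)) {
    out <- dplyr::left_join(out, regions, by = "site")
  } else {
    out$region <- NA_character_
  }
  dplyr::select(out, "series", "index", "site", "formula", "mass",
                "region", "detectable") |>
    dplyr::arrange(.data$series, .data$index)
}

#' Neutral-loss product ions
#'
#' m/z of products formed when a precursor species loses neutral molecules:
#' NH3 (only possible when ammonium adducts supply the transferable
#' proton), nucleobases (guanine, adenine), or a terminal U nucleotide.
#'
#' @param species One row of a [species_table()] (or a list with `mz`,
#'   `n`, `cation`, `x`).
#' @param loss One of `"NH3"`, `"guanine"`, `"adenine"`, `"U_nucleotide"`.
#' @param count Number of neutrals lost (>= 1).
#' @return A tibble with columns `loss`, `count`, `loss_mass`, `mz`.
#' @examples
#' q <- species_table("UAGGGU", order = 4, cation = "NH4", x = 3, n = 5)
#' neutral_loss_products(q, "NH3", 1)
#' @export
neutral_loss_products <- function(species,
                                  loss = c("NH3", "guanine", "adenine",
                                           "U_nucleotide"),
                                  count = 1L) {
  loss <- match.arg(loss)
  stopifnot(count >= 1)
  sp <- as.list(species[1, , drop = FALSE])
  if (loss == "NH3") {
    if (!identical(sp$cation, "NH4")) {
      abort("NH3 loss requires ammonium adducts: no proton donor on this species")
    }
    if (count > sp$x) {
      abort(sprintf("cannot lose %d NH3 from a species with only %d NH4+ adducts",
                    as.integer(count), as.integer(sp$x)))
    }
  }
  loss_comp <- switch(loss,
                      NH3 = comp_nh3(),
                      guanine = comp_guanine(),
                      adenine = comp_adenine(),
                      U_nucleotide = parse_formula("C9H12N2O6") + comp_hpo3())
  m <- mono_mass(loss_comp)
  tibble::tibble(loss = loss, count = as.integer(count), loss_mass = m,
                 mz = sp$mz - count * m / sp$n)
}
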