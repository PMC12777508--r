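#' Build an RNA strand from its sequence
#'
#' Assembles the elemental composition and monoisotopic mass of an
#' unmodified RNA oligonucleotide with 5'-OH and 3'-OH termini, read
#' 5' to 3'. An L-mer is the sum of its L nucleoside compositions plus
#' (L - 1) internal phosphodiester linkages, each contributing HPO3 and
#' removing H2O.
#'
#' @param sequence String over the alphabet A, C, G, U, 5' to 3'.
#' @return An `rna_strand` object: a list with `sequence`, `length`,
#'   `composition` (an [elemental_composition()]) and `mono_mass` (Da).
#' @examples
#' rna_strand("UAGGGU")
#' @export
rna_strand <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(trimws(sequence))
  if (nchar(sequence) < 1L) abort("sequence must contain at least one residue")
  res <- strsplit(sequence, "")[[1]]
  ok <- res %in% the$nucleosides$residue
  if (!all(ok)) {
    pos <- which(!ok)[1]
    abort(sprintf("unknown residue '%s' at position %d (alphabet: A, C, G, U)",
                  res[pos], pos))
  }
  comp <- strand_composition(res)
  structure(
    list(sequence = sequence, length = length(res),
         composition = comp, mono_mass = mono_mass(comp)),
    class = "rna_strand"
  )
}

# composition of a run of residues joined by (n-1) phosphodiester linkages,
# 5'-OH/3'-OH ends (used for whole strands and for fragment prefixes/suffixes)
strand_composition <- function(residues) {
  formulas <- setNames(the$nucleosides$formula, the$nucleosides$residue)
  comp <- parse_formula(formulas[[residues[1]]])
  if (length(residues) > 1) {
    for (r in residues[-1]) comp <- comp + parse_formula(formulas[[r]])
    n_link <- length(residues) - 1L
    comp <- comp + n_link * comp_hpo3() - n_link * comp_h2o()
  }
  comp
}

#' @export
print.rna_strand <- function(x, ...) {
  cat(sprintf("<RNA strand> 5'-%s-3' (%d nt, 5'-OH/3'-OH)\n", x$sequence, x$length))
  cat(sprintf("  composition %s, monoisotopic mass %.4f Da\n",
              format(x$composition), x$mono_mass))
  invisible(x)
}

as_strand <- function(x) {
  if (inherits(x, "rna_strand")) x else rna_strand(x)
}
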