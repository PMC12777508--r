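#' Elemental compositions
#'
#' An elemental composition is a named integer vector (element symbol ->
#' count) with class `elemental_composition`. Compositions add and subtract
#' element-wise; subtracting below zero is an error, because a fragment or
#' neutral loss can never contain atoms its parent lacks. Scalar
#' multiplication scales every count, which is how multimeric assemblies
#' (dimer, tetramer) are built from one strand.
#'
#' @param ... Element counts given as named arguments, e.g.
#'   `elemental_composition(C = 9, H = 12, N = 2, O = 6)`, or a single
#'   character formula such as `"C9H12N2O6"`.
#' @return An `elemental_composition` object.
#' @examples
#' h2o <- elemental_composition(H = 2, O = 1)
#' uridine <- elemental_composition("C9H12N2O6")
#' uridine - h2o
#' @export
elemental_composition <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.character(args[[1]]) && is.null(names(args))) {
    return(parse_formula(args[[1]]))
  }
  counts <- unlist(args)
  if (is.null(names(counts)) || any(names(counts) == "")) {
    abort("element counts must be named, e.g. elemental_composition(C = 9)")
  }
  counts <- vapply(counts, as.integer, integer(1))
  if (any(counts < 0)) abort("element counts must be non-negative")
  new_composition(counts)
}

new_composition <- function(counts) {
  known <- unique(the$isotopes$symbol)
  bad <- setdiff(names(counts), known)
  if (length(bad) > 0) {
    abort(paste0("no isotope data for element(s): ", paste(bad, collapse = ", ")))
  }
  counts <- counts[counts > 0]
  # canonical CHNOPS-style ordering, C and H first as in molecular formulae
  ord <- c("C", "H", "N", "O", "P", "K", "Na")
  counts <- counts[order(match(names(counts), ord))]
  structure(as.integer(counts), names = names(counts),
            class = "elemental_composition")
}

#' Parse a molecular formula string
#'
#' @param formula A string like `"C58H71N24O41P5"`.
#' @return An `elemental_composition`.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)(\\d*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)(\\d*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    abort(paste0("cannot parse formula: ", formula))
  }
  sym <- sub("\\d+$", "", parts)
  num <- sub("^[A-Za-z]+", "", parts)
  counts <- ifelse(num == "", 1L, as.integer(num))
  counts <- tapply(counts, sym, sum)
  new_composition(setNames(as.integer(counts), names(counts)))
}

#' @export
format.elemental_composition <- function(x, ...) {
  if (length(x) == 0) return("(empty)")
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<elemental composition> ", format(x),
      sprintf("  (monoisotopic %.4f Da)\n", mono_mass(x)), sep = "")
  invisible(x)
}

#' @export
Ops.elemental_composition <- function(e1, e2) {
  if (.Generic == "+") return(comp_combine(e1, e2, +1L))
  if (.Generic == "-") return(comp_combine(e1, e2, -1L))
  if (.Generic == "*") {
    if (inherits(e1, "elemental_composition") && is.numeric(e2)) {
      comp <- e1; k <- e2
    } else if (inherits(e2, "elemental_composition") && is.numeric(e1)) {
      comp <- e2; k <- e1
    } else {
      abort("composition '*' needs one composition and one integer")
    }
    k <- as.integer(k)
    if (length(k) != 1L || k < 0L) abort("multiplier must be a single non-negative integer")
    return(new_composition(setNames(unclass(comp) * k, names(comp))))
  }
  if (.Generic == "==") {
    return(isTRUE(all.equal(sort_counts(e1), sort_counts(e2))))
  }
  abort(paste0("operation '", .Generic, "' not defined for compositions"))
}

sort_counts <- function(x) {
  v <- setNames(as.integer(x), names(x))
  v[order(names(v))]
}

comp_combine <- function(e1, e2, sign) {
  stopifnot(inherits(e1, "elemental_composition"),
            inherits(e2, "elemental_composition"))
  els <- union(names(e1), names(e2))
  v1 <- setNames(integer(length(els)), els); v1[names(e1)] <- unclass(e1)
  v2 <- setNames(integer(length(els)), els); v2[names(e2)] <- unclass(e2)
  out <- v1 + sign * v2
  if (any(out < 0)) {
    abort(paste0("composition subtraction below zero for: ",
                 paste(els[out < 0], collapse = ", ")))
  }
  new_composition(out)
}

#' Monoisotopic mass
#'
#' Sum of the lightest-isotope atomic masses over all atoms, in Da.
#'
#' @param x An `elemental_composition` or `rna_strand`.
#' @param ... Unused.
#' @return Mass in Da.
#' @export
mono_mass <- function(x, ...) UseMethod("mono_mass")

#' @export
mono_mass.elemental_composition <- function(x, ...) {
  sum(unclass(x) * the$mono_mass[names(x)])
}

#' @export
mono_mass.rna_strand <- function(x, ...) x$mono_mass

# fixed small-molecule compositions used throughout
comp_h2o  <- function() elemental_composition(H = 2, O = 1)
comp_hpo3 <- function() elemental_composition(H = 1, P = 1, O = 3)
comp_nh3  <- function() elemental_composition(N = 1, H = 3)
comp_guanine <- function() elemental_composition(C = 5, H = 5, N = 5, O = 1)
comp_adenine <- function() elemental_composition(C = 5, H = 5, N = 5)
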