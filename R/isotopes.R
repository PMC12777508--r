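#' Aggregated isotope pattern of a composition
#'
#' Computes the isotopologue distribution of an elemental composition,
#' aggregated by nucleon number (unit-mass bins, as Orbitrap-resolved
#' envelopes of intact oligonucleotide assemblies are read): per element
#' the single-atom isotope vector is raised to the atom count by repeated
#' convolution, element distributions are then convolved together, and
#' within each bin the abundance-weighted centroid mass is reported.
#'
#' @param comp An [elemental_composition()] (or formula string).
#' @param max_peaks Keep at most this many bins (most abundant leading
#'   bins; the pattern is truncated from the heavy tail), then renormalize.
#' @return An `isotope_pattern`: a tibble with columns `mass` (centroid Da)
#'   and `abundance` (sums to 1), ordered by mass; the first row is the
#'   monoisotopic peak.
#' @examples
#' isotope_pattern(elemental_composition(H = 2, O = 1))
#' @export
isotope_pattern <- function(comp, max_peaks = 20L) {
  if (is.character(comp)) comp <- parse_formula(comp)
  stopifnot(inherits(comp, "elemental_composition"))
  if (length(comp) == 0) abort("composition is empty")
  stopifnot(max_peaks >= 1)

  pat <- NULL
  for (el in names(comp)) {
    single <- element_pattern(el)
    el_pat <- pattern_power(single, unclass(comp)[[el]])
    pat <- if (is.null(pat)) el_pat else pattern_convolve(pat, el_pat)
    pat <- pattern_trim(pat, keep = max_peaks + 25L)  # headroom before final cut
  }
  pat <- pattern_trim(pat, keep = max_peaks)
  pat$abundance <- pat$abundance / sum(pat$abundance)
  out <- tibble::tibble(mass = pat$mass, abundance = pat$abundance)
  class(out) <- c("isotope_pattern", class(out))
  out
}

# single-atom pattern: abundance and mass-moment vectors indexed by nucleon
# offset from the lightest isotope
element_pattern <- function(symbol) {
  iso <- the$isotopes[the$isotopes$symbol == symbol, ]
  if (nrow(iso) == 0) abort(paste0("no isotope data for element: ", symbol))
  offset <- round(iso$mass - min(iso$mass))
  len <- max(offset) + 1L
  a <- numeric(len); s <- numeric(len)
  for (i in seq_len(nrow(iso))) {
    k <- offset[i] + 1L
    a[k] <- a[k] + iso$abundance[i]
    s[k] <- s[k] + iso$abundance[i] * iso$mass[i]
  }
  list(a = a, s = s)
}

# convolve two binned patterns; s carries the abundance-weighted mass sum so
# the centroid of each bin falls out as s/a
pattern_convolve <- function(p, q) {
  la <- length(p$a); lb <- length(q$a)
  a <- numeric(la + lb - 1L)
  s <- numeric(la + lb - 1L)
  # centroid masses (zero-abundance bins contribute nothing)
  mp <- ifelse(p$a > 0, p$s / p$a, 0)
  mq <- ifelse(q$a > 0, q$s / q$a, 0)
  for (i in seq_len(la)) {
    if (p$a[i] == 0) next
    j <- seq_len(lb)
    k <- i + j - 1L
    w <- p$a[i] * q$a
    a[k] <- a[k] + w
    s[k] <- s[k] + w * (mp[i] + mq)
  }
  list(a = a, s = s)
}

# pattern of k identical atoms by square-and-multiply convolution
pattern_power <- function(p, k) {
  stopifnot(k >= 1)
  out <- NULL
  base <- p
  while (k > 0) {
    if (k %% 2 == 1) out <- if (is.null(out)) base else pattern_convolve(out, base)
    k <- k %/% 2
    if (k > 0) base <- pattern_convolve(base, base)
  }
  out
}

pattern_trim <- function(p, keep) {
  nz <- which(p$a > 1e-15)
  if (length(nz) == 0) abort("isotope pattern vanished")
  idx <- nz[seq_len(min(length(nz), keep))]
  list(a = p$a[idx], s = p$s[idx],
       mass = (p$s / p$a)[idx], abundance = p$a[idx])
}

#' Convolve two isotope patterns
#'
#' The pattern of a sum of compositions equals the convolution of the
#' individual patterns; exposed for testing and for assembling multimer
#' envelopes from the strand pattern.
#'
#' @param p,q `isotope_pattern` tibbles.
#' @param max_peaks Bins kept after convolution.
#' @return An `isotope_pattern` tibble.
#' @export
convolve_patterns <- function(p, q, max_peaks = 20L) {
  as_binned <- function(x) {
    off <- round(x$mass - x$mass[1])
    len <- max(off) + 1L
    a <- numeric(len); s <- numeric(len)
    a[off + 1L] <- x$abundance
    s[off + 1L] <- x$abundance * x$mass
    list(a = a, s = s)
  }
  out <- pattern_trim(pattern_convolve(as_binned(p), as_binned(q)), max_peaks)
  res <- tibble::tibble(mass = out$mass,
                        abundance = out$abundance / sum(out$abundance))
  class(res) <- c("isotope_pattern", class(res))
  res
}
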