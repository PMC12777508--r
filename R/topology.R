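#' Combinatorial model of a tetramolecular quadruplex
#'
#' Four strands arranged as a cycle (strand k pairs with strand k+1 mod 4
#' in every tetrad plane), a 5' to 3' stack of tetrads each of kind G or U,
#' and monovalent cations occupying inter-tetrad slots (slot i sits between
#' tetrads i and i+1 and contacts all 8 bases of its two flanking tetrads).
#' Hoogsteen-type pairing gives 2 hydrogen bonds per G-G tetrad edge and 1
#' per U-U edge, so an intact G-tetrad holds 8 H-bonds and a U-tetrad 4.
#'
#' The 6-mer UAGGGU forms a stack of three G-tetrads plus a 3'-terminal
#' U-tetrad with three channel cations (`tetrads = c("G","G","G","U")`,
#' `cation_slots = 1:3`); UUAGGG forms three G-tetrads with two cations
#' (`tetrads = c("G","G","G")`, `cation_slots = 1:2`, the default).
#'
#' @param tetrads Character vector of tetrad kinds, 5' to 3' stack order.
#' @param cation_slots Distinct integers in 1..(n_tetrads - 1).
#' @return A `quadruplex_model` object.
#' @examples
#' quadruplex_model()                              # 3 G-tetrads, 2 cations
#' quadruplex_model(c("G", "G", "G", "U"), 1:3)    # U-tetrad, 3rd cation
#' @export
quadruplex_model <- function(tetrads = c("G", "G", "G"), cation_slots = 1:2) {
  stopifnot(length(tetrads) >= 1, all(tetrads %in% c("G", "U")))
  cation_slots <- as.integer(cation_slots)
  if (length(cation_slots) > 0) {
    if (any(cation_slots < 1 | cation_slots > length(tetrads) - 1L)) {
      abort("cation slots must lie between consecutive tetrads (1..n_tetrads-1)")
    }
    if (anyDuplicated(cation_slots)) abort("cation slots must be distinct")
  }
  structure(list(n_strands = 4L, tetrads = tetrads,
                 cation_slots = sort(cation_slots)),
            class = "quadruplex_model")
}

#' @export
print.quadruplex_model <- function(x, ...) {
  cat(sprintf("<quadruplex model> 4 strands, tetrad stack 5'->3': %s; %d cation(s) in slot(s) %s\n",
              paste(x$tetrads, collapse = "-"), length(x$cation_slots),
              if (length(x$cation_slots)) paste(x$cation_slots, collapse = ",") else "-"))
  invisible(x)
}

#' All nontrivial partitions of the four strands
#'
#' The 7 ways to split strands \{1,2,3,4\} into two non-empty parts:
#' four asymmetric 3+1 splits, two symmetric 2+2 splits of adjacent strands
#' (each dimer keeps two tetrad edges), and the one diagonal 2+2 split of
#' opposite strands (each dimer keeps no edge, physically implausible and
#' flagged as such).
#'
#' @return A tibble with columns `id`, `kind`, `part1`, `part2`
#'   (list-columns of strand indices), `physical`.
#' @export
strand_partitions <- function() {
  tibble::tibble(
    id = c("3+1 (strand 1)", "3+1 (strand 2)", "3+1 (strand 3)", "3+1 (strand 4)",
           "2+2 adjacent (12|34)", "2+2 adjacent (23|41)", "2+2 opposite (13|24)"),
    kind = c(rep("asymmetric_3_1", 4), rep("symmetric_2_2_adjacent", 2),
             "symmetric_2_2_opposite"),
    part1 = list(1L, 2L, 3L, 4L, c(1L, 2L), c(2L, 3L), c(1L, 3L)),
    part2 = list(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L),
                 c(3L, 4L), c(4L, 1L), c(2L, 4L)),
    physical = c(rep(TRUE, 6), FALSE)
  )
}

check_partition <- function(part1, part2) {
  part1 <- as.integer(part1); part2 <- as.integer(part2)
  if (length(part1) == 0 || length(part2) == 0) {
    abort("both partition parts must be non-empty")
  }
  if (!setequal(c(part1, part2), 1:4) || length(c(part1, part2)) != 4) {
    abort("partition parts must be disjoint and cover strands 1..4")
  }
  list(part1 = part1, part2 = part2)
}

# edges of the 4-cycle, as strand index pairs
tetrad_edges <- function() list(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L))

#' Hydrogen bonds broken by a strand-separation pathway
#'
#' Counts, per tetrad, the hydrogen bonds on cycle edges that cross the
#' partition (2 per severed G-G edge, 1 per U-U edge). Any 3+1 or adjacent
#' 2+2 split severs exactly two edges per tetrad — 4 H-bonds in each
#' G-tetrad and 2 in a U-tetrad — which is why asymmetric and symmetric
#' dissociation cost the same number of H-bonds.
#'
#' @param model A [quadruplex_model()].
#' @param part1,part2 Strand index sets forming the partition.
#' @return A tibble with columns `tetrad`, `kind`, `edges_cut`,
#'   `hbonds_broken`, plus a `total` attribute with the stack-wide sum.
#' @examples
#' m <- quadruplex_model(c("G", "G", "G", "U"), 1:3)
#' hb <- hbonds_broken(m, 1, 2:4)
#' attr(hb, "total")  # 14
#' @export
hbonds_broken <- function(model, part1, part2) {
  stopifnot(inherits(model, "quadruplex_model"))
  p <- check_partition(part1, part2)
  crossing <- vapply(tetrad_edges(), function(e) {
    xor(e[1] %in% p$part1, e[2] %in% p$part1)
  }, logical(1))
  edges_cut <- sum(crossing)
  per_edge <- c(G = 2L, U = 1L)
  out <- tibble::tibble(
    tetrad = seq_along(model$tetrads),
    kind = model$tetrads,
    edges_cut = edges_cut,
    hbonds_broken = unname(edges_cut * per_edge[model$tetrads])
  )
  attr(out, "total") <- sum(out$hbonds_broken)
  out
}

#' Cation-base contacts across a dissociation pathway
#'
#' Each channel cation contacts all 8 bases of its two flanking tetrads.
#' This tallies the distinct bases (tetrad, strand pairs) contacted by any
#' cation, and how many of those contacts survive when the cations leave
#' with one part of a strand partition: a retained contact is one whose
#' base lies on a strand in the cation-carrying part. For the
#' three-G-tetrad, two-cation quadruplex this yields the 12 / 9 / 6
#' sequence for intact / asymmetric (cations with the trimer) / adjacent
#' symmetric (cations with one dimer) pathways.
#'
#' @param model A [quadruplex_model()].
#' @param part1,part2 Optional partition; when omitted only the intact
#'   contact count is reported.
#' @return A one-row tibble with columns `total`, and (when a partition is
#'   given) `retained_part1`, `retained_part2`, `larger_part` (1, 2, or
#'   `NA` on a tie), `retained` (contacts kept when cations follow the
#'   larger part; on a tie the common value if equal, else `NA`).
#' @export
cation_contacts <- function(model, part1 = NULL, part2 = NULL) {
  stopifnot(inherits(model, "quadruplex_model"))
  # distinct contacted bases: union over cations of flanking-tetrad bases
  flank <- unique(unlist(lapply(model$cation_slots, function(s) c(s, s + 1L))))
  total <- length(flank) * model$n_strands
  if (is.null(part1) && is.null(part2)) {
    return(tibble::tibble(total = total))
  }
  p <- check_partition(part1, part2)
  r1 <- length(flank) * length(p$part1)
  r2 <- length(flank) * length(p$part2)
  larger <- if (length(p$part1) > length(p$part2)) 1L
            else if (length(p$part2) > length(p$part1)) 2L else NA_integer_
  retained <- if (!is.na(larger)) c(r1, r2)[larger]
              else if (r1 == r2) r1 else NA_integer_
  tibble::tibble(total = total, retained_part1 = r1, retained_part2 = r2,
                 larger_part = larger, retained = retained)
}

#' Rank strand-separation pathways
#'
#' Scores every nontrivial partition of the four strands by the number of
#' cation-base contacts retained (more is better: those interactions need
#' not be paid for) and by hydrogen bonds broken (fewer is better), in that
#' priority. For any model with at least one channel cation the asymmetric
#' 3+1 split ranks first, rationalising the dominance of Q -> T + M over
#' symmetric dissociation into dimers.
#'
#' @param model A [quadruplex_model()].
#' @return A tibble of partitions sorted best-first, with columns `rank`,
#'   `id`, `kind`, `hbonds_broken`, `contacts_retained`, `physical`,
#'   `tied_with_next`.
#' @examples
#' rank_pathways(quadruplex_model(c("G", "G", "G"), 1:2))
#' @export
rank_pathways <- function(model) {
  stopifnot(inherits(model, "quadruplex_model"))
  parts <- strand_partitions()
  scored <- parts |>
    dplyr::mutate(
      hbonds_broken = purrr::map2_dbl(.data$part1, .data$part2, function(a, b) {
        attr(hbonds_broken(model, a, b), "total")
      }),
      contacts_retained = purrr::map2_dbl(.data$part1, .data$part2, function(a, b) {
        cc <- cation_contacts(model, a, b)
        if (is.na(cc$retained)) max(cc$retained_part1, cc$retained_part2)
        else cc$retained
      })
    ) |>
    dplyr::arrange(dplyr::desc(.data$contacts_retained), .data$hbonds_broken) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "id", "kind", "hbonds_broken", "contacts_retained",
                  "physical")
  scored$tied_with_next <- c(
    scored$contacts_retained[-1] == scored$contacts_retained[-nrow(scored)] &
      scored$hbonds_broken[-1] == scored$hbonds_broken[-nrow(scored)],
    FALSE
  )
  scored
}
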