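# brute-force oracle: count H-bonds on cut edges and cation contacts by
# explicit enumeration of (tetrad, strand) bases
oracle_hbonds <- function(model, part1) {
  edges <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  per_edge <- c(G = 2, U = 1)
  total <- 0
  for (tet in model$tetrads) {
    for (e in edges) {
      if (xor(e[1] %in% part1, e[2] %in% part1)) total <- total + per_edge[[tet]]
    }
  }
  total
}

oracle_contacts <- function(model, keep_strands) {
  bases <- expand.grid(tetrad = seq_along(model$tetrads), strand = 1:4)
  flank <- unique(unlist(lapply(model$cation_slots, function(s) c(s, s + 1))))
  contacted <- bases[bases$tetrad %in% flank, ]
  if (is.null(keep_strands)) return(nrow(contacted))
  nrow(contacted[contacted$strand %in% keep_strands, ])
}

test_that("H-bond counts per tetrad match the 4-per-G / 2-per-U rule", {
  hb_asym <- hbonds_broken(model1(), 1, 2:4)
  expect_equal(hb_asym$hbonds_broken, c(4, 4, 4, 2))
  expect_equal(attr(hb_asym, "total"), 14)
  hb_sym <- hbonds_broken(model1(), c(1, 2), c(3, 4))
  expect_equal(hb_sym$hbonds_broken, c(4, 4, 4, 2))  # same cost as asymmetric
  expect_error(hbonds_broken(model1(), 1:4, integer(0)), "non-empty")
})

test_that("H-bond counting is symmetric under swapping partition parts", {
  parts <- strand_partitions()
  for (i in seq_len(nrow(parts))) {
    a <- attr(hbonds_broken(model1(), parts$part1[[i]], parts$part2[[i]]), "total")
    b <- attr(hbonds_broken(model1(), parts$part2[[i]], parts$part1[[i]]), "total")
    expect_equal(a, b)
  }
})

test_that("cation contacts reproduce the 12 / 9 / 6 sequence of the 2-cation model", {
  m <- model2()
  expect_equal(cation_contacts(m)$total, 12)
  asym <- cation_contacts(m, 1, 2:4)
  expect_equal(asym$retained, 9)       # cations travel with the trimer
  sym <- cation_contacts(m, c(1, 2), c(3, 4))
  expect_equal(sym$retained_part1, 6)  # either dimer keeps only 6
  expect_equal(sym$retained_part2, 6)
})

test_that("retained plus severed contacts equal the intact total, every partition", {
  for (model in list(model1(), model2())) {
    parts <- strand_partitions()
    total <- cation_contacts(model)$total
    for (i in seq_len(nrow(parts))) {
      cc <- cation_contacts(model, parts$part1[[i]], parts$part2[[i]])
      expect_equal(cc$retained_part1 + cc$retained_part2, total)
    }
  }
})

test_that("counting agrees with the brute-force oracle over all 7 partitions", {
  for (model in list(model1(), model2())) {
    parts <- strand_partitions()
    for (i in seq_len(nrow(parts))) {
      p1 <- parts$part1[[i]]; p2 <- parts$part2[[i]]
      expect_equal(attr(hbonds_broken(model, p1, p2), "total"),
                   unname(oracle_hbonds(model, p1)))
      cc <- cation_contacts(model, p1, p2)
      expect_equal(cc$total, oracle_contacts(model, NULL))
      expect_equal(cc$retained_part1, oracle_contacts(model, p1))
      expect_equal(cc$retained_part2, oracle_contacts(model, p2))
    }
  }
})

test_that("asymmetric dissociation ranks as the lowest-energy pathway", {
  for (model in list(model1(), model2())) {
    rk <- rank_pathways(model)
    expect_equal(rk$kind[1], "asymmetric_3_1")
    top_sym <- min(which(rk$kind != "asymmetric_3_1"))
    expect_true(all(rk$kind[seq_len(top_sym - 1)] == "asymmetric_3_1"))
    expect_gt(rk$contacts_retained[1], rk$contacts_retained[top_sym])
  }
})

test_that("without cations the ranking degenerates to H-bond ties", {
  m <- quadruplex_model(c("G", "G", "G"), integer(0))
  rk <- rank_pathways(m)
  expect_equal(unique(rk$contacts_retained), 0)
  expect_true(all(rk$hbonds_broken[rk$kind != "symmetric_2_2_opposite"] == 12))
  expect_true(any(rk$tied_with_next))
})

test_that("model validation rejects bad cation slots", {
  expect_error(quadruplex_model(c("G", "G"), 2), "between consecutive")
  expect_error(quadruplex_model(c("G", "G", "G"), c(1, 1)), "distinct")
})
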