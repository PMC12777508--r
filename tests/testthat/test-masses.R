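test_that("composition algebra is element-wise and rejects negative counts", {
  u <- elemental_composition("C9H12N2O6")
  h2o <- elemental_composition(H = 2, O = 1)
  expect_equal(format(u + h2o), "C9H14N2O7")
  expect_equal(format(u - h2o), "C9H10N2O5")
  expect_equal(format(2 * h2o), "H4O2")
  expect_error(h2o - u, "below zero")
  expect_error(elemental_composition(Xx = 1), "isotope data")
})

test_that("strand composition and mass match the published 6-mer values", {
  s <- rna1()
  expect_equal(format(s$composition), "C58H71N24O41P5")
  expect_equal(s$mono_mass, 1914.290, tolerance = 0.002 / 1914.29)
  # single residue: uridine nucleoside, no linkage
  u <- rna_strand("U")
  expect_equal(format(u$composition), "C9H12N2O6")
  expect_equal(u$mono_mass, 244.0695, tolerance = 1e-6)
})

test_that("strand composition is permutation-invariant in the residue multiset", {
  expect_equal(format(rna1()$composition), format(rna2()$composition))
  expect_equal(rna1()$mono_mass, rna2()$mono_mass)
})

test_that("invalid sequences are rejected with the offending position", {
  expect_error(rna_strand("UAXGGU"), "position 3")
  expect_error(rna_strand(""), "at least one residue")
})

test_that("m/z reproduces the full published quadruplex grid to 0.002 Th", {
  grid <- published_mz_grid()
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    mz <- mz_species(rna1(), order = 4, cation = row$cation, x = row$x,
                     n = row$n)
    expect_equal(mz, row$mz, tolerance = 0.002 / row$mz,
                 label = sprintf("(Q+%d%s)%d-", row$x, row$cation, row$n))
  }
})

test_that("charge balance n = h - x holds across the published grid", {
  grid <- published_mz_grid()
  expect_true(all(grid$n == grid$h - grid$x))
  # and the constructor enforces it
  expect_error(mz_species(rna1(), 4, "K", x = 3, n = 4, h = 6),
               "charge balance")
})

test_that("m/z decreases strictly with net charge at fixed cation count", {
  tab <- species_table(rna1(), order = 4, cation = "K", x = 1:3, n = 4:8)
  tab |>
    dplyr::group_by(x) |>
    dplyr::arrange(n, .by_group = TRUE) |>
    dplyr::summarise(mono = all(diff(mz) < 0)) |>
    dplyr::pull(mono) |>
    all() |>
    expect_true()
})

test_that("uncharged species have no m/z", {
  expect_error(mz_species(rna1(), 1, "none", 0, n = 0), "no m/z")
})

test_that("bare deprotonated monomer m/z follows from the neutral mass", {
  m <- rna1()$mono_mass
  expect_equal(mz_species(rna1(), 1, "none", 0, n = 2),
               (m - 2 * 1.007276466) / 2, tolerance = 1e-9)
  expect_equal(mz_species(rna1(), 1, "none", 0, n = 2), 956.138,
               tolerance = 0.002 / 956)
})

test_that("isotope patterns are normalized with the monoisotopic peak first", {
  p <- isotope_pattern(elemental_composition(H = 2, O = 1))
  expect_equal(sum(p$abundance), 1, tolerance = 1e-9)
  expect_equal(p$mass[1], 18.0106, tolerance = 1e-4)
  expect_gt(p$abundance[1], 0.99)
  big <- isotope_pattern(rna1()$composition, max_peaks = 15)
  expect_equal(sum(big$abundance), 1, tolerance = 1e-9)
  expect_true(all(diff(big$mass) > 0))
})

test_that("a single carbon atom reproduces the tabulated 13C/12C ratio", {
  iso <- element_isotopes()
  c13 <- iso[iso$symbol == "C", ]
  p <- isotope_pattern(elemental_composition(C = 1))
  expect_equal(nrow(p), 2)
  expect_equal(p$abundance[2] / p$abundance[1],
               c13$abundance[2] / c13$abundance[1], tolerance = 1e-9)
})

test_that("pattern of a sum of compositions equals the convolution of patterns", {
  a <- elemental_composition("C9H12N2O6")
  b <- elemental_composition("C10H13N5O5")
  direct <- isotope_pattern(a + b, max_peaks = 8)
  conv <- convolve_patterns(isotope_pattern(a, 12), isotope_pattern(b, 12),
                            max_peaks = 8)
  expect_equal(conv$abundance, direct$abundance, tolerance = 1e-6)
  expect_equal(conv$mass, direct$mass, tolerance = 1e-4)
  # associativity on three small molecules
  c3 <- elemental_composition(H = 2, O = 1)
  lhs <- convolve_patterns(convolve_patterns(isotope_pattern(a, 12),
                                             isotope_pattern(b, 12), 12),
                           isotope_pattern(c3, 12), max_peaks = 8)
  rhs <- convolve_patterns(isotope_pattern(a, 12),
                           convolve_patterns(isotope_pattern(b, 12),
                                             isotope_pattern(c3, 12), 12),
                           max_peaks = 8)
  expect_equal(lhs$abundance, rhs$abundance, tolerance = 1e-9)
})
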