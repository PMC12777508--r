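test_that("peaks match candidates within tolerance, with ppm tie broken to lower charge", {
  cand <- species_table(rna1(), order = 4, cation = "K", x = 3, n = 4:8)
  pk <- tibble::tibble(mz = c(1941.749, 1942.749), intensity = c(100, 50))
  asg <- assign_peaks(pk, cand, tol_ppm = 10)
  expect_true(asg$assigned[1])
  expect_equal(asg$label[1], "(Q+3K)4-")
  expect_false(asg$assigned[2])  # 1 Th off is far outside 10 ppm
  # two artificial candidates equidistant in ppm
  cand2 <- tibble::tibble(label = c("hi_n", "lo_n"), class = "assembly",
                          order = c(4L, 1L), cation = "none", x = 0L,
                          h = c(6L, 3L), n = c(6L, 3L), nh3 = 0L,
                          mz = c(1000.001, 999.999))
  asg2 <- assign_peaks(tibble::tibble(mz = 1000, intensity = 1), cand2,
                       tol_ppm = 10)
  expect_equal(asg2$label, "lo_n")
})

test_that("a single-species spectrum quantifies to 100%", {
  cand <- species_table(rna1(), order = 4, cation = "K", x = 3, n = 4:8)
  pk <- tibble::tibble(mz = cand$mz, intensity = c(10, 40, 60, 30, 10))
  sp <- species_percentages(assign_peaks(pk, cand))
  expect_equal(nrow(sp), 1)
  expect_equal(sp$species, "Q")
  expect_equal(sp$species_pct, 100)
})

test_that("NH3-loss satellites and extra adducts fold into the quadruplex total", {
  cand <- species_table(rna1(), order = 4, cation = "NH4", x = 3, n = 5,
                        nh3_losses = 0:2)
  pk <- tibble::tibble(mz = cand$mz, intensity = c(70, 20, 10))
  sp <- species_percentages(assign_peaks(pk, cand))
  expect_equal(sp$species, "Q")
  expect_equal(sp$intensity, 100)
  cand_k <- species_table(rna1(), order = 4, cation = "K", x = 3:4, n = 5)
  pk_k <- tibble::tibble(mz = cand_k$mz, intensity = c(80, 20))
  sp_k <- species_percentages(assign_peaks(pk_k, cand_k))
  expect_equal(sp_k$species, "Q")
  expect_equal(sp_k$species_pct, 100)
})

test_that("molecule percentages weight species by strand stoichiometry", {
  mp <- molecule_percentages(
    tibble::tibble(species = c("Q", "M", "D"), species_pct = c(62, 28, 10)))
  expect_equal(mp$molecule_pct[mp$species == "Q"], 83.8, tolerance = 0.001)
  mp2 <- molecule_percentages(
    tibble::tibble(species = c("Q", "M", "D"), species_pct = c(57, 43, 0)))
  expect_equal(mp2$molecule_pct[mp2$species == "Q"], 84.1, tolerance = 0.001)
  mp3 <- molecule_percentages(tibble::tibble(species = "M", species_pct = 100))
  expect_equal(mp3$molecule_pct, 100)
  expect_error(molecule_percentages(tibble::tibble(species = "M",
                                                   species_pct = 0)),
               "nonzero")
})

test_that("molecule percentages are invariant to uniform intensity rescaling", {
  sp <- tibble::tibble(species = c("Q", "M", "D"), species_pct = c(62, 28, 10))
  scaled <- dplyr::mutate(sp, species_pct = species_pct * 7)
  expect_equal(molecule_percentages(sp)$molecule_pct,
               molecule_percentages(scaled)$molecule_pct)
})

test_that("simulated ESI spectra round-trip the generating proportions", {
  sim <- simulate_esi_spectrum(seed = 7)
  cand <- expand_isotopes(sim$candidates, rna1(), max_peaks = 5)
  sp <- species_percentages(assign_peaks(sim$peaks, cand))
  got <- setNames(sp$species_pct, sp$species)
  expect_equal(got[["Q"]], 62, tolerance = 1 / 62)
  expect_equal(got[["M"]], 28, tolerance = 1 / 28)
  expect_equal(got[["D"]], 10, tolerance = 1 / 10)
  mp <- molecule_percentages(sp)
  expect_equal(mp$molecule_pct[mp$species == "Q"], 84, tolerance = 1 / 84)
  expect_equal(sum(sp$species_pct), 100, tolerance = 1e-3)
  expect_equal(sum(mp$molecule_pct), 100, tolerance = 1e-3)
})

test_that("quantification of an empty assignment errors", {
  cand <- species_table(rna1(), order = 4, cation = "K", x = 3, n = 4)
  asg <- assign_peaks(tibble::tibble(mz = 500, intensity = 1), cand)
  expect_error(species_percentages(asg), "no assigned")
})
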