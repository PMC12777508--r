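test_that("laboratory-frame energy is voltage times net charge", {
  expect_equal(lab_frame_energy(30, 5), 150)
  expect_equal(lab_frame_energy(0, 7), 0)
  expect_equal(lab_frame_energy(60, 8), 480)
  expect_error(lab_frame_energy(-1, 5), ">= 0")
})

test_that("noiseless logistic trajectories give exact closed-form E50", {
  f <- fit_e50(logistic_curve(p0 = 100, e_mid = 150, w = 10))
  expect_equal(f$e50, 150, tolerance = 1e-4)
  # pre-depleted precursor: absolute-50% crossing precedes the midpoint
  f80 <- fit_e50(logistic_curve(p0 = 80, e_mid = 150, w = 10))
  expect_equal(f80$e50, 150 + 10 * log(80 / 50 - 1), tolerance = 1e-4)
  expect_equal(f80$e50, 144.892, tolerance = 1e-4)
  # half-of-initial convention recovers the midpoint itself
  expect_equal(f80$e50_relative, 150, tolerance = 1e-3)
})

test_that("fit and interpolation E50 agree on noiseless logistic data", {
  for (w in c(8, 15, 25)) {
    f <- fit_e50(logistic_curve(p0 = 100, e_mid = 170, w = w))
    expect_equal(f$e50, f$e50_interp, tolerance = 0.02)
  }
})

test_that("an uncrossed Q trajectory is reported as not bracketed", {
  cv <- logistic_curve(p0 = 100, e_mid = 600, w = 10,
                       energies = seq(0, 200, by = 20))
  expect_error(fit_e50(cv), "not bracketed")
})

test_that("breakdown curves from simulated CAD series recover the truth", {
  sim <- simulate_cad_series(e_mid = 150, width = 15, seed = 11)
  bd <- build_breakdown(sim$series, rna1(), annot1())
  tab <- tibble::as_tibble(bd)
  # percentages sum to 100 at every energy
  sums <- dplyr::summarise(dplyr::group_by(tab, energy), s = sum(pct))
  expect_true(all(abs(sums$s - 100) < 0.1))
  # Q trajectory decreases monotonically (up to small noise)
  q <- dplyr::arrange(dplyr::filter(tab, species == "Q"), energy)
  expect_true(all(diff(q$pct) < 1))
  f <- fit_e50(bd)
  expect_equal(f$e50, sim$truth$e50, tolerance = 5 / 150)
})

test_that("clean zero-energy point keeps the precursor at 100%", {
  sim <- simulate_cad_series(voltages = c(0, 10, 20, 30, 40, 50, 60),
                             frag_max = 0, noise_cv = 0, jitter_ppm = 0,
                             seed = 1)
  bd <- build_breakdown(sim$series, rna1(), annot1())
  q0 <- dplyr::filter(tibble::as_tibble(bd), energy == 0, species == "Q")
  expect_equal(q0$pct, 100, tolerance = 1e-6)
})

test_that("a pre-depleted precursor is reported via initial_q_pct", {
  sim <- simulate_cad_series(initial_q = 0.8, seed = 21)
  bd <- build_breakdown(sim$series, rna1(), annot1())
  expect_equal(attr(bd, "initial_q_pct"), 80, tolerance = 0.05)
  f <- fit_e50(bd)
  expect_lt(f$e50, f$e50_relative)  # absolute-50% crossing comes earlier
})

test_that("stability comparison reports the +20% difference and monotonicity", {
  cmp <- compare_stabilities(list(180, 150), c("A", "B"))
  expect_equal(cmp$pct_diff, 20)
  expect_equal(cmp$ratio, 1.2)
  cmp0 <- compare_stabilities(list(150, 150))
  expect_equal(cmp0$pct_diff, 0)
  cmp_n <- compare_stabilities(as.list(c(160, 140, 120, 90, 70)), n = 4:8)
  expect_true(attr(cmp_n, "monotone_decreasing_in_n"))
  cmp_bad <- compare_stabilities(as.list(c(160, 170, 120, 90, 70)), n = 4:8)
  expect_false(attr(cmp_bad, "monotone_decreasing_in_n"))
})

test_that("seeded noisy logistic recovery lands within 5 eV", {
  e <- seq(50, 300, by = 10)
  q_true <- 100 / (1 + exp((e - 150) / 10))
  withr::with_seed(42, {
    q <- pmin(pmax(q_true + stats::rnorm(length(e), 0, 2), 0), 100)
  })
  cv <- as_breakdown_curve(tibble::tibble(
    energy = rep(e, 2), species = rep(c("Q", "M"), each = length(e)),
    pct = c(q, 100 - q)))
  expect_equal(fit_e50(cv)$e50, 150, tolerance = 5 / 150)
})
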