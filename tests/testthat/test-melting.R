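test_that("single-transition fits recover the midpoint within 0.5 degC", {
  for (sd in 1:4) {
    sim <- simulate_melting(seed = sd)  # Tm 60, 10-90% span ~15 degC
    fit <- fit_melting(sim$curve, 1)
    expect_equal(fit$transitions$t_mid, 60, tolerance = 0.5 / 60)
    expect_equal(fit$transitions$delta_t_10_90, 15, tolerance = 0.15)
  }
})

test_that("broad and narrow transitions are distinguishable at realistic noise", {
  narrow <- fit_melting(simulate_melting(seed = 2)$curve, 1)
  broad <- fit_melting(simulate_melting(
    transitions = tibble::tibble(amplitude = 0.08, t_mid = 40, width = 5.7),
    seed = 2)$curve, 1)
  expect_equal(broad$transitions$t_mid, 40, tolerance = 1 / 40)
  expect_equal(broad$transitions$delta_t_10_90, 25, tolerance = 0.15)
  expect_gt(broad$transitions$delta_t_10_90,
            narrow$transitions$delta_t_10_90 + 5)
})

test_that("two-transition curves recover both midpoints within 1 degC", {
  sim <- simulate_melting(
    transitions = tibble::tibble(amplitude = c(0.05, 0.03),
                                 t_mid = c(40, 70), width = c(5.7, 3.4)),
    seed = 6)
  fit <- fit_melting(sim$curve, 2)
  tms <- sort(fit$transitions$t_mid)
  expect_equal(tms[1], 40, tolerance = 1 / 40)
  expect_equal(tms[2], 70, tolerance = 1 / 70)
})

test_that("model selection picks the generating number of sigmoids", {
  sel1 <- select_model(simulate_melting(seed = 2)$curve)
  expect_equal(sel1$n_sigmoids, 1L)
  sel2 <- select_model(simulate_melting(
    transitions = tibble::tibble(amplitude = c(0.05, 0.03),
                                 t_mid = c(40, 70), width = c(5.7, 3.4)),
    seed = 6)$curve)
  expect_equal(sel2$n_sigmoids, 2L)
})

test_that("pure noise selects one sigmoid and flags it degenerate", {
  sim <- simulate_melting(
    transitions = tibble::tibble(amplitude = 0, t_mid = 60, width = 3.4),
    seed = 9)
  sel <- select_model(sim$curve)
  expect_equal(sel$n_sigmoids, 1L)
  expect_true(any(sel$fits[[1]]$transitions$degenerate))
})

test_that("fit residuals for the generating model are unbiased and noise-sized", {
  sim <- simulate_melting(seed = 3)
  fit <- fit_melting(sim$curve, 1)
  r <- residuals(fit$fit)
  expect_lt(abs(mean(r)), 3 * sim$truth$noise_sd / sqrt(length(r)))
  expect_equal(fit$sigma, sim$truth$noise_sd, tolerance = 0.2)
  # noiseless data reproduces itself
  clean <- simulate_melting(noise_sd = 0, seed = 1)
  fit0 <- fit_melting(clean$curve, 1)
  expect_lt(fit0$sigma, 1e-8)
})

test_that("the analytic derivative peaks at the midpoint", {
  fit <- fit_melting(simulate_melting(seed = 4)$curve, 1)
  d <- derivative_profile(fit)
  peak_t <- d$profile$temperature[which.max(d$profile$dA_dT)]
  expect_equal(peak_t, fit$transitions$t_mid, tolerance = 0.01)
  expect_equal(d$extrema$temperature, fit$transitions$t_mid)
  # raw-data numerical derivative tracks the analytic one within noise
  raw <- derivative_profile(fit$data)
  ana <- derivative_profile(fit, n = nrow(fit$data))
  expect_lt(stats::median(abs(raw$profile$dA_dT - ana$profile$dA_dT)), 0.01)
})

test_that("a pure linear baseline has constant derivative", {
  sim <- simulate_melting(
    transitions = tibble::tibble(amplitude = 0, t_mid = 60, width = 3.4),
    noise_sd = 0, seed = 1)
  d <- derivative_profile(sim$curve)
  expect_equal(max(d$profile$dA_dT) - min(d$profile$dA_dT), 0, tolerance = 1e-9)
  expect_equal(d$profile$dA_dT[1], 5e-4, tolerance = 1e-9)
})

test_that("cooling branches are refused for midpoint fitting", {
  sim <- simulate_melting(cooling = TRUE, seed = 8)
  cool_only <- dplyr::filter(sim$curve, direction == "cooling")
  expect_error(fit_melting(cool_only), "hysteretic")
  # with both branches present only the heating branch is fitted
  fit <- fit_melting(sim$curve, 1)
  expect_equal(fit$transitions$t_mid, 60, tolerance = 0.5 / 60)
})
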