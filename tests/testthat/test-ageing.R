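test_that("area-difference enthalpy relaxation recovers known constructions", {
  # identical curves -> 0
  cv <- step_cp_curve()
  expect_equal(enthalpy_relaxation(cv, cv, 340, 400), 0)

  # constant Cp difference 0.1 across the whole 10 K integration span -> 1.0 J/g
  Tv <- seq(300, 430, by = 0.25)
  base <- dsc_curve((Tv - 300) * 6, Tv, rep(1.2, length(Tv)),
                    "specific_heat", nominal_rate = 10)
  bump <- ifelse(Tv >= 365 & Tv <= 385, 0.1, 0)
  aged <- dsc_curve((Tv - 300) * 6, Tv, 1.2 + bump,
                    "specific_heat", nominal_rate = 10)
  expect_equal(enthalpy_relaxation(aged, base, 370, 380), 1.0,
               tolerance = 1e-9)

  # Gaussian overshoot of prescribed area
  p <- phenomenological_pair(375.35, 0.47, overshoot_area = 5.13,
                             peak_width = 3, grid = seq(320, 430, 0.1))
  got <- enthalpy_relaxation(p$aged, p$unaged, 340, 405)
  expect_equal(got, 5.13, tolerance = 0.01 * 5.13)
})

test_that("heat-flow and Cp forms of the area difference agree", {
  p <- phenomenological_pair(375.35, 0.47, overshoot_area = 2.7,
                             peak_width = 2.5, grid = seq(320, 430, 0.1))
  via_cp <- enthalpy_relaxation(p$aged, p$unaged, 340, 400)
  via_hf <- enthalpy_relaxation(to_heat_flow(p$aged), to_heat_flow(p$unaged),
                                340, 400)
  expect_equal(via_hf, via_cp, tolerance = 1e-9)
})

test_that("enthalpy relaxation is invariant to a common baseline", {
  p <- phenomenological_pair(375.35, 0.47, overshoot_area = 3.3,
                             peak_width = 2, grid = seq(320, 430, 0.2))
  ref <- enthalpy_relaxation(p$aged, p$unaged, 340, 400)
  shift <- function(cv) { cv$value <- cv$value + 0.4 + 0.002 * cv$temperature; cv }
  expect_equal(enthalpy_relaxation(shift(p$aged), shift(p$unaged), 340, 400),
               ref, tolerance = 1e-9)
})

test_that("curve pairs with mismatched rates are rejected", {
  p <- phenomenological_pair(375.35, 0.47, 1, 2, seq(330, 420, 0.5))
  slow <- p$aged; slow$nominal_rate <- 5
  expect_error(enthalpy_relaxation(slow, p$unaged, 340, 400),
               class = "glassage_rate_mismatch_error")
  expect_error(enthalpy_relaxation(p$aged, p$unaged, 400, 340),
               class = "glassage_validation_error")
})

test_that("equilibrium enthalpy relaxation follows delta_cp (Tg - Ta)", {
  expect_equal(equilibrium_relaxation(0.47, Tg = 375.35, Ta = 358.15),
               0.47 * 17.2, tolerance = 1e-12)
  b <- flat_baseline(1.2, 1.67)
  expect_equal(equilibrium_relaxation(b, 375.35, 338.15, "integral"),
               equilibrium_relaxation(b, 375.35, 338.15, "scalar"))
  expect_equal(equilibrium_relaxation(0.47, 375.35, 375.35), 0)
  expect_error(equilibrium_relaxation(0.47, 375.35, 380),
               class = "glassage_domain_error")
  # sloped baselines: integral mode is the exact trapezoid of a linear step
  b2 <- cp_baseline(c(1.0, 0.001), c(1.2, 0.0025), c(310, 350), c(390, 420))
  Ta <- 340; Tg <- 380
  exact <- pracma::trapz(seq(Ta, Tg, length.out = 1e4),
                         delta_cp(b2, seq(Ta, Tg, length.out = 1e4)))
  expect_equal(equilibrium_relaxation(b2, Tg, Ta, "integral"), exact,
               tolerance = 1e-9)
})

test_that("series construction validates, sorts and averages replicates", {
  s <- relaxation_series(358.15, c(7200, 3600, 3600), c(3, 2, 2.4))
  expect_equal(s$data$t_a, c(3600, 7200))
  expect_equal(s$data$dHr[1], 2.2)  # replicate mean
  expect_equal(s$data$sd[1], 0.3 / sqrt(2), tolerance = 1e-12)

  expect_error(relaxation_series(358.15, c(0, 3600), c(-1, 2)),
               class = "glassage_validation_error")
  expect_error(build_series(data.frame(Ta = c(358, 348, 358),
                                       t_a = c(1, 2, 3) * 3600,
                                       dHr = c(1, 2, 3))),
               class = "glassage_validation_error")
  expect_error(build_series(data.frame(Ta = 358, t_a = c(1, 2) * 3600,
                                       dHr = c(1, 2))),
               class = "glassage_validation_error")
})

test_that("series CSV round trip preserves the measurements", {
  s <- simulate_kww_series(358.15, ageing_hours * 3600, 28 * 3600, 0.327,
                           7.92, noise_sd = 0.3, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(s, path)
  back <- read_series_csv(path)
  expect_equal(back$Ta, s$Ta, tolerance = 1e-9)
  expect_equal(back$data$dHr, s$data$dHr, tolerance = 1e-9)
  expect_equal(back$data$t_a, s$data$t_a, tolerance = 1e-6)
})

test_that("simulated ageing series grow monotonically and stay below equilibrium", {
  Ta <- 358.15
  unaged_sim <- simulate_tnm(ageing_program(Ta, 0, T_high = 440, T_low = 310),
                             tnm_default)
  unaged <- tnm_segment_curve(unaged_sim, 3)
  b <- tnm_default$cp_baseline
  gt <- detect_glass_transition(unaged, b)
  dHr <- sapply(c(0.5, 2, 8, 32) * 3600, function(ta) {
    sim <- simulate_tnm(ageing_program(Ta, ta, T_high = 440, T_low = 310),
                        tnm_default)
    aged <- tnm_segment_curve(sim, 4)
    enthalpy_relaxation(aged, unaged, gt$T_mid - 40, gt$T_mid + 25)
  })
  expect_true(all(diff(dHr) > 0))
  eq <- equilibrium_relaxation(b, gt$T_mid, Ta, "integral")
  expect_true(all(dHr <= eq * 1.05))
})
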