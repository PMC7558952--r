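test_that("Cp baseline fitting recovers exact and noisy linear inputs", {
  cv <- linear_cp_curve(intercept = 1.0, slope = 0.001)
  expect_warning(b <- fit_cp_baselines(cv, c(310, 350), c(390, 420)),
                 "degenerate")  # one global line: zero step, still recovered
  expect_equal(b$solid, c(1.0, 0.001), tolerance = 1e-9)
  expect_equal(b$liquid, c(1.0, 0.001), tolerance = 1e-9)
  expect_lt(max(b$rms), 1e-10)

  # noisy linear input: slope recovered within 3 standard errors
  set.seed(7)
  Tv <- seq(310, 350, length.out = 200)
  noisy <- dsc_curve((Tv - 310) * 6, Tv, 1.0 + 0.001 * Tv + rnorm(200, 0, 0.005),
                     "specific_heat", nominal_rate = 10)
  # liquid window holds an exact line a step above the solid one
  Tl <- seq(390, 420, length.out = 50)
  full <- dsc_curve(c(noisy$time, 1000 + (Tl - 390) * 6),
                    c(Tv, Tl), c(noisy$value, 1.4 + 0.001 * Tl),
                    "specific_heat", nominal_rate = 10)
  bf <- fit_cp_baselines(full, c(310, 350), c(390, 420))
  se <- summary(lm(y ~ x, data.frame(x = Tv, y = noisy$value)))$coefficients[2, 2]
  expect_lt(abs(bf$solid[2] - 0.001), 3 * se)
})

test_that("baseline windows are validated", {
  cv <- linear_cp_curve()
  expect_error(fit_cp_baselines(cv, c(310, 395), c(390, 420)),
               class = "glassage_window_error")
  expect_error(fit_cp_baselines(cv, c(305, 306), c(390, 420)),
               class = "glassage_window_error")
})

test_that("delta_cp evaluates the liquid-solid step", {
  b <- flat_baseline(1.2, 1.67)
  expect_equal(delta_cp(b, 330), 0.47)
  expect_equal(delta_cp(b, 410), 0.47)
  b2 <- cp_baseline(c(0.8, 0.002), c(1.23, 0.002), c(310, 350), c(390, 420))
  expect_equal(delta_cp(b2, 300), 0.43)
  expect_equal(delta_cp(b2, 420), 0.43)
  # identical lines: degenerate zero step, flagged but evaluable
  expect_warning(b0 <- cp_baseline(c(1.2, 0), c(1.2, 0),
                                   c(310, 350), c(390, 420)), "degenerate")
  expect_equal(delta_cp(b0, 370), 0)
  # crossing lines are rejected outright
  expect_error(cp_baseline(c(1.2, 0.002), c(1.4, -0.002),
                           c(310, 350), c(390, 420)),
               class = "glassage_validation_error")
})

test_that("glass transition midpoint and step height are recovered from an ideal step", {
  cv <- step_cp_curve(Tg = 375.35, dcp = 0.47, lo = 1.2)
  b <- flat_baseline(1.2, 1.67)
  gt <- detect_glass_transition(cv, b)
  expect_equal(gt$T_mid, 375.35, tolerance = 0.01)
  expect_equal(gt$delta_cp_at_Tg, 0.47)
  expect_true(gt$T_onset < gt$T_mid && gt$T_mid < gt$T_end)
})

test_that("transition detection is invariant to a common Cp offset", {
  gt0 <- detect_glass_transition(step_cp_curve(), flat_baseline())
  gt1 <- detect_glass_transition(step_cp_curve(offset = 0.35),
                                 flat_baseline(offset = 0.35))
  expect_equal(gt1$T_mid, gt0$T_mid, tolerance = 1e-9)
  expect_equal(gt1$T_onset, gt0$T_onset, tolerance = 1e-6)
})

test_that("TNM heating scan places the midpoint near the nominal Tg", {
  sim <- simulate_tnm(rate_sweep_program(10, 10, T_high = 440, T_low = 310),
                      tnm_default)
  cv <- tnm_segment_curve(sim, 2)
  gt <- detect_glass_transition(cv, tnm_default$cp_baseline)
  # the default glass has tau = 100 s at 375.35 K; a 10 K/min scan should
  # put the midpoint near that temperature
  expect_lt(abs(gt$T_mid - 375.35), 2)
  # scan hysteresis: the heating midpoint lies above the frozen-in Tf
  Tf_glass <- sim$Tf[max(which(sim$segment == 1))]
  expect_gt(gt$T_mid, Tf_glass)
  expect_lt(gt$T_mid - Tf_glass, 4)
})

test_that("enthalpy integration matches closed forms and a fine Riemann sum", {
  cv <- dsc_curve(c(0, 30, 60), c(300, 305, 310), rep(2, 3),
                  "specific_heat", nominal_rate = 10)
  ec <- integrate_enthalpy(cv, T_ref = 300, H_ref = 0)
  expect_equal(tail(ec$H, 1), 20)

  # Cp = a T on [T1, T2] vs a (T2^2 - T1^2)/2
  a <- 0.004; Tv <- seq(300, 400, length.out = 1e4)
  lin <- dsc_curve((Tv - 300) * 6, Tv, a * Tv, "specific_heat",
                   nominal_rate = 10)
  ecl <- integrate_enthalpy(lin, 300, 0)
  expect_equal(tail(ecl$H, 1), a * (400^2 - 300^2) / 2, tolerance = 1e-9)

  # Riemann-sum oracle on a curved integrand
  Tv2 <- seq(300, 400, length.out = 2001)
  cp2 <- 1 + 0.5 * sin(Tv2 / 20)
  cur <- dsc_curve((Tv2 - 300) * 6, Tv2, cp2, "specific_heat",
                   nominal_rate = 10)
  ec2 <- integrate_enthalpy(cur, 300, 0)
  Tf2 <- seq(300, 400, length.out = 2e5)
  riemann <- sum((1 + 0.5 * sin(Tf2 / 20))[-1] * diff(Tf2))
  expect_equal(tail(ec2$H, 1), riemann, tolerance = 1e-6)

  expect_true(all(diff(ec2$H) >= 0))  # H non-decreasing for Cp >= 0
  expect_error(integrate_enthalpy(cv, 299, 0),
               class = "glassage_reference_error")
})

test_that("fictive temperature from constructed enthalpy lines", {
  # glass line H = 0.5 (T - 300); liquid line H = 1.0 (T - 300) - 37 -> Tf = 374
  Tv <- seq(300, 360, length.out = 100)
  ec <- structure(list(temperature = Tv, H = 0.5 * (Tv - 300),
                       reference = c(T_ref = 300, H_ref = 0)),
                  class = "enthalpy_curve")
  liq <- list(intercept = -300 - 37, slope = 1.0)
  ft <- fictive_temperature(ec, liq, glass_window = c(300, 360))
  expect_equal(ft$Tf, 374, tolerance = 1e-9)

  par <- list(intercept = -10, slope = 0.5)
  expect_error(fictive_temperature(ec, par, c(300, 360)),
               class = "glassage_no_intersection_error")
})

test_that("equal-area fictive temperature matches the midpoint on a symmetric step", {
  cv <- step_cp_curve(Tg = 375.35, dcp = 0.47, lo = 1.2, width = 1.2)
  b <- flat_baseline(1.2, 1.67)
  ft <- fictive_temperature_equal_area(cv, b)
  expect_equal(ft$Tf, 375.35, tolerance = 0.05)
})

test_that("overshoot area lowers the equal-area fictive temperature monotonically", {
  b <- flat_baseline(1.2, 1.67)
  grid <- seq(300, 430, length.out = 2600)
  tfs <- sapply(c(0, 1, 2.5, 5), function(area) {
    p <- phenomenological_pair(375.35, 0.47, overshoot_area = area,
                               peak_width = 2.5, grid = grid,
                               solid = c(1.2, 0))
    fictive_temperature_equal_area(p$aged, b)$Tf
  })
  expect_true(all(diff(tfs) < 0))
})

test_that("intersection and equal-area methods agree on simulated glasses", {
  for (ta_h in c(0, 8)) {
    sim <- simulate_tnm(ageing_program(Ta = 358.15, t_a = ta_h * 3600,
                                       T_high = 440, T_low = 310),
                        tnm_default)
    cv <- tnm_segment_curve(sim, length(sim$program$segments))
    b <- tnm_default$cp_baseline
    ec <- integrate_enthalpy(cv, T_ref = 330, H_ref = 0)
    liq <- fit_enthalpy_line(ec, c(395, 420))
    ft_i <- fictive_temperature(ec, liq, glass_window = c(315, 345))
    ft_e <- fictive_temperature_equal_area(cv, b)
    expect_lt(abs(ft_i$Tf - ft_e$Tf), 0.5)
  }
})
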