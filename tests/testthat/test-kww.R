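test_that("KWW prediction and recovery obey their closed-form limits", {
  expect_equal(kww_predict(0, 3600, 0.5, 5), 0)
  for (b in c(0.25, 0.5, 1)) {
    expect_equal(kww_predict(3600, 3600, b, 5), 5 * (1 - exp(-1)))
    expect_equal(kww_recovery(3600, 3600, b), exp(-1))  # beta-free at t = tau
  }
  expect_equal(kww_predict(1e12, 3600, 0.5, 5), 5, tolerance = 1e-9)
  expect_equal(kww_recovery(0, 3600, 0.5), 1)

  # complement identity: dHr + dHr_inf * phi == dHr_inf exactly
  t <- c(0, 10^(2:7))
  expect_equal(kww_predict(t, 5e4, 0.33, 7.9) + 7.9 * kww_recovery(t, 5e4, 0.33),
               rep(7.9, length(t)))
  # monotone decay
  expect_true(all(diff(kww_recovery(10^(1:8), 5e4, 0.33)) < 0))

  expect_error(kww_recovery(10, -1, 0.5), class = "glassage_parameter_error")
  expect_error(kww_recovery(10, 10, 1.2), class = "glassage_parameter_error")
  expect_error(kww_predict(10, 10, 0.5, -2), class = "glassage_parameter_error")
})

test_that("recovery parameter reproduces the reported 32 h values", {
  expect_equal(round(kww_recovery(32 * 3600, 189 * 86400, 0.277), 2), 0.78)
  expect_equal(round(kww_recovery(32 * 3600, 6 * 86400, 0.306), 2), 0.53)
})

test_that("experimental recovery from a series is the enthalpy complement", {
  s <- relaxation_series(358.15, c(0, 3600, 7200), c(0, 4.93, 7.92))
  r <- recovery_from_series(s, 7.92)
  expect_equal(r$phi, c(1, 1 - 4.93 / 7.92, 0))
  expect_equal(round(r$phi[2], 2), 0.38)
  expect_warning(recovery_from_series(
    relaxation_series(358.15, c(1, 2) * 3600, c(1, 9)), 7.92), "clipped")
})

test_that("noiseless fits recover generating parameters across a grid", {
  for (tau_h in c(10, 100, 1000)) for (beta in c(0.25, 0.5, 0.75)) {
    tau <- tau_h * 3600
    t <- tau * c(0.05, 0.15, 0.4, 1, 2.5, 6, 15)
    s <- relaxation_series(358.15, t, kww_predict(t, tau, beta, 6.5))
    f <- fit_kww(s)
    expect_equal(unname(coef(f)["tau"]), tau, tolerance = 1e-6)
    expect_equal(unname(coef(f)["beta"]), beta, tolerance = 1e-6)
    expect_equal(unname(coef(f)["dHr_inf"]), 6.5, tolerance = 1e-6)
  }
})

test_that("fits honour a fixed equilibrium plateau", {
  tau <- 20 * 3600; beta <- 0.4; A <- 8.2
  t <- ageing_hours * 3600
  s <- relaxation_series(358.15, t, kww_predict(t, tau, beta, A),
                         dHr_inf_fixed = A)
  f <- fit_kww(s)
  expect_true(f$fixed["dHr_inf"])
  expect_equal(unname(coef(f)["dHr_inf"]), A)
  expect_equal(unname(coef(f)["tau"]), tau, tolerance = 1e-6)
  # three points suffice when the plateau is fixed
  s3 <- relaxation_series(358.15, t[c(2, 4, 6)],
                          kww_predict(t[c(2, 4, 6)], tau, beta, A))
  expect_error(fit_kww(s3), class = "glassage_fit_error")
  expect_equal(unname(coef(fit_kww(s3, dHr_inf = A))["beta"]), beta,
               tolerance = 1e-4)
})

test_that("fit methods behave like a standard modelling object", {
  s <- simulate_kww_series(358.15, ageing_hours * 3600, 28 * 3600, 0.327,
                           7.92, noise_sd = 0.2, seed = 3)
  f <- fit_kww(s)
  expect_s3_class(f, "kww_fit")
  expect_named(coef(f), c("tau", "beta", "dHr_inf"))
  expect_equal(dim(vcov(f)), c(3L, 3L))
  expect_equal(fitted(f) + residuals(f), s$data$dHr, tolerance = 1e-12)
  expect_equal(predict(f, 28 * 3600),
               unname(kww_predict(28 * 3600, coef(f)["tau"], coef(f)["beta"],
                                  coef(f)["dHr_inf"])))
  expect_output(print(f), "tau")
  sm <- summary(f)
  expect_true(all(is.finite(sm$coefficients$std_error)))
  # simulate() is reproducible under a seed
  s1 <- simulate(f, nsim = 2, seed = 9)
  s2 <- simulate(f, nsim = 2, seed = 9)
  expect_equal(s1[[2]]$data$dHr, s2[[2]]$data$dHr)
})

test_that("noisy fits recover tau within Monte-Carlo bounds", {
  truth <- table1_kww$`85`
  taus <- vapply(1:200, function(i) {
    s <- simulate_kww_series(358.15, ageing_hours * 3600, truth$tau,
                             truth$beta, truth$dHr_inf, noise_sd = 0.3,
                             seed = 1000 + i)
    f <- tryCatch(fit_kww(s, n_starts = 3), error = function(e) NULL)
    if (is.null(f)) NA_real_ else unname(coef(f)["tau"])
  }, 0)
  expect_lt(mean(is.na(taus)), 0.05)
  expect_lt(abs(median(taus, na.rm = TRUE) / truth$tau - 1), 0.25)
})

test_that("fictive temperature maps linearly from recovered enthalpy", {
  s <- relaxation_series(358.15, c(3600, 7200, 10800), c(0, 2.35, 0.47 * 17.2))
  tf <- fictive_vs_time(s, Tg = 375.35, dcp = 0.47)
  expect_equal(tf$Tf, c(375.35, 370.35, 358.15))
  expect_error(fictive_vs_time(s, 375.35, 0), class = "glassage_parameter_error")
})
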