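# shared fixtures: all synthetic, generated in code

# linear-Cp heating curve sampled at `rate` K/min
linear_cp_curve <- function(Tlo = 300, Thi = 430, n = 600,
                            intercept = 1.0, slope = 0.003, rate = 10) {
  Tv <- seq(Tlo, Thi, length.out = n)
  dsc_curve(time = (Tv - Tlo) / (rate / 60), temperature = Tv,
            value = intercept + slope * Tv, signal_kind = "specific_heat",
            nominal_rate = rate)
}

# sigmoid Cp step between constant baselines, optionally shifted by `offset`
step_cp_curve <- function(Tg = 375.35, dcp = 0.47, lo = 1.2,
                          width = 1.5, Tlo = 300, Thi = 430, n = 2000,
                          offset = 0, rate = 10) {
  Tv <- seq(Tlo, Thi, length.out = n)
  cp <- lo + dcp * plogis((Tv - Tg) / width) + offset
  dsc_curve(time = (Tv - Tlo) / (rate / 60), temperature = Tv, value = cp,
            signal_kind = "specific_heat", nominal_rate = rate)
}

flat_baseline <- function(lo = 1.2, hi = 1.67, offset = 0) {
  cp_baseline(solid = c(lo + offset, 0), liquid = c(hi + offset, 0),
              solid_window = c(310, 350), liquid_window = c(390, 420))
}

# default simulated glass, shared across TNM tests
tnm_default <- default_tnm_parameters()

table1_kww <- list(
  `65` = list(tau = 189 * 86400, beta = 0.277, dHr_inf = 16.88),
  `75` = list(tau = 6 * 86400, beta = 0.306, dHr_inf = 12.45),
  `85` = list(tau = 28 * 3600, beta = 0.327, dHr_inf = 7.92))

ageing_hours <- c(0.5, 1, 2, 4, 8, 16, 24, 32)
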