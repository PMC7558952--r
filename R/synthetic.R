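#' Tool-Narayanaswamy-Moynihan simulator parameters
#'
#' The TNM model describes structural relaxation with a relaxation time
#' depending on both temperature and fictive temperature,
#' \deqn{\ln\tau(T, T_f) = \ln A + \frac{x\,\Delta h^*}{R T} +
#'       \frac{(1-x)\,\Delta h^*}{R T_f},}
#' with nonlinearity `x` in (0, 1], apparent activation enthalpy `dh_star`
#' (J mol^-1) and a KWW stretching exponent `beta` for the response to each
#' temperature step.
#'
#' @param lnA log pre-exponential time (ln seconds).
#' @param dh_star apparent activation enthalpy (J mol^-1).
#' @param x nonlinearity parameter in (0, 1].
#' @param beta nonexponentiality parameter in (0, 1].
#' @param cp_baseline a [cp_baseline()] providing the solid line and the
#'   step delta_cp(T) used to convert the fictive-temperature derivative to
#'   a measurable Cp.
#' @param Tf_init initial fictive temperature (K); `NA` means "start
#'   equilibrated at the program's first temperature".
#' @return an object of class `tnm_parameters`.
#' @export
tnm_parameters <- function(lnA, dh_star, x, beta, cp_baseline,
                           Tf_init = NA_real_) {
  if (x <= 0 || x > 1 || beta <= 0 || beta > 1)
    stop_glassage("x and beta must lie in (0, 1]", "glassage_parameter_error")
  if (dh_star <= 0)
    stop_glassage("dh_star must be positive", "glassage_parameter_error")
  stopifnot(inherits(cp_baseline, "cp_baseline"))
  structure(list(lnA = lnA, dh_star = dh_star, x = x, beta = beta,
                 cp_baseline = cp_baseline, Tf_init = Tf_init),
            class = "tnm_parameters")
}

#' Default glass-former parameter set
#'
#' A documented parameter set emulating a small-molecule pharmaceutical
#' glass with Tg near 375 K (102 degC) at 10 K min^-1 and a heat-capacity
#' step of 0.47 J g^-1 K^-1: `dh_star` = 500 kJ mol^-1, `x` = 0.5,
#' `beta` = 0.5, and `lnA` chosen so that the equilibrium relaxation time at
#' 375.35 K is 100 s (the conventional tau(Tg) for a 10 K min^-1 scan).
#'
#' @param Tg_target temperature (K) at which tau(T, T) = `tau_at_Tg`.
#' @param tau_at_Tg equilibrium relaxation time at `Tg_target` (s).
#' @param dh_star,x,beta see [tnm_parameters()].
#' @param cp_baseline reference lines; defaults to parallel lines with a
#'   constant 0.47 J g^-1 K^-1 step.
#' @return a [tnm_parameters()] object.
#' @examples
#' default_tnm_parameters()
#' @export
default_tnm_parameters <- function(Tg_target = 375.35, tau_at_Tg = 100,
                                   dh_star = 500e3, x = 0.5, beta = 0.5,
                                   cp_baseline = NULL) {
  baseline <- cp_baseline %||% glassage::cp_baseline(
    solid = c(1.2, 0), liquid = c(1.67, 0),
    solid_window = c(310, 350), liquid_window = c(390, 420))
  lnA <- log(tau_at_Tg) - dh_star / (.R_GAS * Tg_target)
  tnm_parameters(lnA = lnA, dh_star = dh_star, x = x, beta = beta,
                 cp_baseline = baseline)
}

#' @export
print.tnm_parameters <- function(x, ...) {
  cat(sprintf(
    "TNM parameters: lnA = %.2f, dh* = %.3g kJ/mol, x = %.3g, beta = %.3g\n",
    x$lnA, x$dh_star / 1000, x$x, x$beta))
  invisible(x)
}

#' TNM relaxation time
#'
#' @param params a [tnm_parameters()].
#' @param T temperature (K).
#' @param Tf fictive temperature (K); defaults to `T` (equilibrium).
#' @return relaxation time in seconds (vectorised over `T`/`Tf`).
#' @export
tnm_relaxation_time <- function(params, T, Tf = T) {
  exp(params$lnA + params$x * params$dh_star / (.R_GAS * T) +
        (1 - params$x) * params$dh_star / (.R_GAS * Tf))
}

#' Simulate a DSC experiment with the TNM model
#'
#' Discretises the thermal program into small steps and evolves the fictive
#' temperature by the TNM-KWW superposition
#' \deqn{T_f(t_n) = T_0 + \sum_j \Delta T_j\,
#'   \Big[1 - \exp\{-(\textstyle\sum_{k=j}^{n}\Delta t_k/\tau_k)^\beta\}\Big],}
#' where each tau_k is evaluated at that step's temperature and the previous
#' step's fictive temperature. The measurable specific heat on a ramp is
#' `Cp(T) = Cp_solid(T) + delta_cp(T) * dTf/dT`.
#'
#' Ramps are stepped so that each step changes temperature by at most
#' `dT_max`; holds are stepped at `dt`. With `subdivide = FALSE` a ramp step
#' larger than `dT_max` raises a resolution error instead.
#'
#' @param program a [thermal_program()].
#' @param params a [tnm_parameters()].
#' @param dt base time step (s) for isothermal holds.
#' @param dT_max maximum per-step temperature change on ramps (K).
#' @param subdivide automatically subdivide ramps to honour `dT_max`.
#' @return an object of class `tnm_simulation`: vectors `time` (s),
#'   `temperature` (K), `Tf` (K), `segment` (index into
#'   `program$segments`), plus `params` and `program`.
#' @examples
#' sim <- simulate_tnm(rate_sweep_program(10, 10, T_high = 420, T_low = 330),
#'                     default_tnm_parameters())
#' tail(sim$Tf, 1)
#' @export
simulate_tnm <- function(program, params, dt = 60, dT_max = 0.5,
                         subdivide = TRUE) {
  stopifnot(inherits(program, "thermal_program"),
            inherits(params, "tnm_parameters"))
  # build the step grid: temperature at the END of each step + its duration
  Tstep <- list(); dtstep <- list(); segid <- list()
  for (k in seq_along(program$segments)) {
    s <- program$segments[[k]]
    dur_s <- s$duration * 60
    if (s$kind == "isothermal") {
      if (dur_s <= 0) next
      n <- max(1L, ceiling(dur_s / dt))
      Tstep[[length(Tstep) + 1L]] <- rep(s$T_start, n)
      dtstep[[length(dtstep) + 1L]] <- rep(dur_s / n, n)
    } else {
      span <- abs(s$T_end - s$T_start)
      rate_s <- abs(s$rate) / 60
      n_dt <- ceiling(dur_s / dt)
      if (!subdivide && span / n_dt > dT_max + 1e-12)
        stop_glassage(sprintf(
          "segment %d: step of %.3g K exceeds dT_max = %g K", k,
          span / n_dt, dT_max), "glassage_resolution_error")
      n <- max(n_dt, ceiling(span / dT_max))
      Tstep[[length(Tstep) + 1L]] <-
        seq(s$T_start, s$T_end, length.out = n + 1L)[-1L]
      dtstep[[length(dtstep) + 1L]] <- rep(span / n / rate_s, n)
    }
    segid[[length(segid) + 1L]] <- rep(k, length(Tstep[[length(Tstep)]]))
  }
  Tv <- unlist(Tstep); dtv <- unlist(dtstep); seg <- unlist(segid)
  n <- length(Tv)
  T0 <- program$segments[[1]]$T_start
  Tf0 <- if (is.finite(params$Tf_init)) params$Tf_init else T0
  dT <- diff(c(T0, Tv))
  beta <- params$beta

  Tf <- numeric(n)
  # reduced-time bookkeeping: S[k] = cumulative sum of dt/tau up to step k;
  # only steps with a temperature jump contribute terms to the superposition
  Scum <- 0
  Sj <- numeric(n); dTr <- numeric(n); nr <- 0L
  Tfprev <- Tf0
  offset <- Tf0 - T0  # non-equilibrium start folds into the j = 0 term
  for (k in seq_len(n)) {
    tau_k <- tnm_relaxation_time(params, Tv[k], Tfprev)
    if (dT[k] != 0) {
      nr <- nr + 1L
      Sj[nr] <- Scum
      dTr[nr] <- dT[k]
    }
    Scum <- Scum + dtv[k] / tau_k
    if (nr > 0L) {
      xi <- Scum - Sj[seq_len(nr)]
      Tf[k] <- T0 + offset * exp(-Scum^beta) +
        sum(dTr[seq_len(nr)] * (1 - exp(-xi^beta)))
    } else {
      Tf[k] <- T0 + offset * exp(-Scum^beta)
    }
    Tfprev <- Tf[k]
  }
  structure(list(time = cumsum(dtv), temperature = Tv, Tf = Tf,
                 segment = seg, params = params, program = program),
            class = "tnm_simulation")
}

#' @export
print.tnm_simulation <- function(x, ...) {
  cat(sprintf(
    "TNM simulation: %d steps over %d segments, final Tf = %.2f K\n",
    length(x$time), length(x$program$segments), tail(x$Tf, 1)))
  invisible(x)
}

#' @export
plot.tnm_simulation <- function(x, ...) {
  plot(x$temperature, x$Tf, type = "l", xlab = "Temperature (K)",
       ylab = "Fictive temperature (K)", ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' Extract one ramp of a simulation as a specific-heat curve
#'
#' Converts the fictive-temperature trajectory of a ramp segment to the
#' measurable specific heat `Cp = Cp_solid + delta_cp * dTf/dT`.
#'
#' @param sim a [simulate_tnm()] result.
#' @param segment index of a ramp segment in the simulated program.
#' @return a specific-heat [dsc_curve()].
#' @export
tnm_segment_curve <- function(sim, segment) {
  stopifnot(inherits(sim, "tnm_simulation"))
  s <- sim$program$segments[[segment]]
  if (s$kind != "ramp")
    stop_glassage("Cp extraction requires a ramp segment",
                  "glassage_validation_error")
  sel <- which(sim$segment == segment)
  if (length(sel) < 3L)
    stop_glassage("segment has too few simulated steps",
                  "glassage_validation_error")
  Tv <- sim$temperature[sel]
  dTfdT <- pracma::gradient(sim$Tf[sel], Tv)
  b <- sim$params$cp_baseline
  cp <- baseline_cp(b, Tv, "solid") + delta_cp(b, Tv) * dTfdT
  dsc_curve(time = sim$time[sel], temperature = Tv, value = cp,
            signal_kind = "specific_heat",
            sample_id = sprintf("tnm_segment_%d", segment),
            nominal_rate = s$rate)
}

#' Aged/unaged curve pair with an exactly known overshoot area
#'
#' Phenomenological fixture generator: the unaged scan is a smooth sigmoid
#' Cp step of height `dcp` at `Tg` between linear baselines; the aged scan
#' adds a Gaussian enthalpy-recovery peak of exactly `overshoot_area`
#' centred just above `Tg`. The pair gives bit-exact ground truth for the
#' area-difference computation in [enthalpy_relaxation()].
#'
#' @param Tg step midpoint (K).
#' @param dcp step height (J g^-1 K^-1).
#' @param overshoot_area Gaussian peak area (J g^-1), non-negative.
#' @param peak_width Gaussian standard deviation (K).
#' @param grid temperature grid (K), must cover the peak to +/- 6 sd.
#' @param peak_offset peak centre above `Tg` (K).
#' @param step_width sigmoid width (K).
#' @param solid baseline `c(intercept, slope)`.
#' @param rate nominal heating rate recorded on the curves (K min^-1).
#' @return list with `unaged` and `aged` [dsc_curve()]s.
#' @examples
#' p <- phenomenological_pair(375.35, 0.47, overshoot_area = 5.13,
#'                            peak_width = 3, grid = seq(330, 420, 0.1))
#' enthalpy_relaxation(p$aged, p$unaged, 340, 400)
#' @export
phenomenological_pair <- function(Tg, dcp, overshoot_area, peak_width,
                                  grid, peak_offset = 5, step_width = 2,
                                  solid = c(1.0, 0.003), rate = 10) {
  if (overshoot_area < 0)
    stop_glassage("overshoot area must be non-negative",
                  "glassage_validation_error")
  centre <- Tg + peak_offset
  if (overshoot_area > 0 &&
      (centre - 6 * peak_width < min(grid) ||
       centre + 6 * peak_width > max(grid)))
    stop_glassage("Gaussian peak truncated by the temperature grid",
                  "glassage_geometry_error")
  base <- solid[1] + solid[2] * grid + dcp * plogis((grid - Tg) / step_width)
  peak <- if (overshoot_area > 0)
    overshoot_area * exp(-(grid - centre)^2 / (2 * peak_width^2)) /
      (peak_width * sqrt(2 * pi)) else 0
  time <- (grid - grid[1]) / (abs(rate) / 60)
  mk <- function(v, id) dsc_curve(time, grid, v, "specific_heat",
                                  sample_id = id, nominal_rate = rate)
  list(unaged = mk(base, "unaged"), aged = mk(base + peak, "aged"))
}

#' Simulate a noisy KWW relaxation series
#'
#' Generates `dHr_i = kww_predict(t_i) + eps_i` with Gaussian noise of
#' standard deviation `noise_sd` (the 0.3 J g^-1 default matches typical
#' DSC repeatability), reproducibly from `seed`.
#'
#' @param Ta ageing temperature (K).
#' @param times ageing times (s).
#' @inheritParams kww_predict
#' @param noise_sd measurement noise standard deviation (J g^-1).
#' @param seed RNG seed.
#' @return a [relaxation_series()] (noise-floor clipped at -0.3 J g^-1).
#' @export
simulate_kww_series <- function(Ta, times, tau, beta, dHr_inf,
                                noise_sd = 0.3, seed = 1) {
  if (noise_sd < 0)
    stop_glassage("noise_sd must be non-negative", "glassage_validation_error")
  mu <- kww_predict(times, tau, beta, dHr_inf)
  set.seed(seed)
  y <- mu + if (noise_sd > 0) rnorm(length(times), 0, noise_sd) else 0
  relaxation_series(Ta, times, pmax(y, -0.3),
                    sd = max(noise_sd, 0.3))
}
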