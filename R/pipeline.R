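#' Study configuration
#'
#' Collects the knobs of an end-to-end ageing/fragility study of a simulated
#' (or supplied) glass. Defaults encode the reference study design: ageing
#' at 65/75/85 degC for 0.5-32 h after 10 K min^-1 cooling, a fragility
#' sweep over 0.2-10 K min^-1 (cooling) and 0.5-20 K min^-1 (heating), and
#' the default TNM glass of [default_tnm_parameters()].
#'
#' @param ageing_temperatures ageing temperatures (K).
#' @param ageing_times ageing times (s).
#' @param cooling_rates,heating_rates fragility sweep rates (K min^-1).
#' @param heating_sweep `"matched"` (cool at the heating rate before each
#'   heating leg) or `"fixed_cool"` (constant `fixed_cool_rate` pre-cool).
#' @param fixed_cool_rate pre-cool rate for `heating_sweep = "fixed_cool"`.
#' @param solid_window,liquid_window baseline windows (K).
#' @param integration_offsets `c(below, above)`: Eq.-area integration limits
#'   relative to Tg, i.e. `T1 = Tg - below`, `T2 = Tg + above` (K).
#' @param scan_rate standard scan rate (K min^-1).
#' @param T_high,T_low program temperature limits (K).
#' @param tnm a [tnm_parameters()] object.
#' @param kww optional list mapping ageing temperature (K, as character or
#'   numeric names) to `list(tau, beta, dHr_inf)` for the `"series"` data
#'   source.
#' @param source `"thermograms"` (full area-difference path through the TNM
#'   simulator) or `"series"` (pre-tabulated or KWW-generated series).
#' @param noise_sd measurement noise for generated series (J g^-1).
#' @param dHr_inf_mode `"free"`, `"scalar"` or `"integral"`: whether the KWW
#'   plateau is fitted or fixed from the equilibrium relaxation.
#' @param dt,dT_max simulator resolution, see [simulate_tnm()].
#' @param seed RNG seed.
#' @return a list of class `study_config`.
#' @export
study_config <- function(ageing_temperatures = celsius_to_kelvin(c(65, 75, 85)),
                         ageing_times = c(0.5, 1, 2, 4, 8, 16, 24, 32) * 3600,
                         cooling_rates = c(0.2, 0.5, 1, 2, 5, 10),
                         heating_rates = c(0.5, 1, 2, 5, 10, 20),
                         heating_sweep = c("matched", "fixed_cool"),
                         fixed_cool_rate = 20,
                         solid_window = c(310, 350),
                         liquid_window = c(390, 420),
                         integration_offsets = c(40, 25),
                         scan_rate = 10,
                         T_high = 440, T_low = 310,
                         tnm = default_tnm_parameters(),
                         kww = NULL,
                         source = c("thermograms", "series"),
                         noise_sd = 0,
                         dHr_inf_mode = c("free", "scalar", "integral"),
                         dt = 60, dT_max = 0.5, seed = 1) {
  cfg <- list(ageing_temperatures = ageing_temperatures,
              ageing_times = ageing_times,
              cooling_rates = cooling_rates, heating_rates = heating_rates,
              heating_sweep = match.arg(heating_sweep),
              fixed_cool_rate = fixed_cool_rate,
              solid_window = solid_window, liquid_window = liquid_window,
              integration_offsets = integration_offsets,
              scan_rate = scan_rate, T_high = T_high, T_low = T_low,
              tnm = tnm, kww = kww, source = match.arg(source),
              noise_sd = noise_sd, dHr_inf_mode = match.arg(dHr_inf_mode),
              dt = dt, dT_max = dT_max, seed = seed)
  if (length(cfg$ageing_temperatures) == 0L || length(cfg$ageing_times) == 0L)
    stop_glassage("ageing temperatures and times must be non-empty",
                  "glassage_validation_error")
  if (any(cfg$ageing_temperatures >= liquid_window[1]))
    stop_glassage("ageing temperatures must lie below the liquid window",
                  "glassage_validation_error")
  class(cfg) <- "study_config"
  cfg
}

#' Read a study configuration from YAML
#'
#' Scalar fields use the instrument units of [study_config()] except that
#' temperatures may be given in Celsius via `*_C` keys and ageing times in
#' hours via `ageing_times_h`. TNM parameters may be overridden under a
#' `tnm:` mapping (`dh_star`, `x`, `beta`, `Tg_target`, `tau_at_Tg`).
#'
#' @param path YAML file path.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$ageing_temperatures_C))
    args$ageing_temperatures <- celsius_to_kelvin(unlist(y$ageing_temperatures_C))
  if (!is.null(y$ageing_times_h))
    args$ageing_times <- unlist(y$ageing_times_h) * 3600
  for (nm in c("cooling_rates", "heating_rates", "heating_sweep",
               "fixed_cool_rate", "solid_window", "liquid_window",
               "integration_offsets", "scan_rate", "T_high", "T_low",
               "source", "noise_sd", "dHr_inf_mode", "dt", "dT_max", "seed"))
    if (!is.null(y[[nm]])) args[[nm]] <- unlist(y[[nm]])
  if (!is.null(y$tnm))
    args$tnm <- do.call(default_tnm_parameters,
                        y$tnm[intersect(names(y$tnm),
                                        c("Tg_target", "tau_at_Tg", "dh_star",
                                          "x", "beta"))])
  if (!is.null(y$kww)) args$kww <- y$kww
  do.call(study_config, args)
}

.kww_for_Ta <- function(cfg, Ta) {
  if (is.null(cfg$kww)) return(NULL)
  keys <- as.numeric(names(cfg$kww))  # kelvin or Celsius accepted
  hit <- which(abs(keys - Ta) < 0.51 | abs(keys - kelvin_to_celsius(Ta)) < 0.51)
  if (length(hit) != 1L) return(NULL)
  cfg$kww[[hit]]
}

#' Run the isothermal ageing study
#'
#' For each ageing temperature: obtain an enthalpy-relaxation series (from
#' TNM-simulated aged/unaged thermogram pairs via the area-difference
#' integral, or directly from KWW-generated values), fit the KWW model,
#' compute recovery parameters, the fictive-temperature trajectory and the
#' equilibrium enthalpy relaxation in both modes, and assemble a report.
#' Failures at one temperature are recorded and do not abort the others.
#'
#' @param config a [study_config()].
#' @return a list of class `ageing_study` with one entry per ageing
#'   temperature plus shared reference quantities (`Tg`, `delta_cp`).
#' @export
run_ageing_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  b <- cfg$tnm$cp_baseline
  # reference unaged heating scan for Tg and the area-difference path
  unaged_sim <- simulate_tnm(ageing_program(
    Ta = cfg$ageing_temperatures[1], t_a = 0, T_high = cfg$T_high,
    T_low = cfg$T_low, rate = cfg$scan_rate), cfg$tnm,
    dt = cfg$dt, dT_max = cfg$dT_max)
  heat_seg <- length(unaged_sim$program$segments)
  unaged_curve <- tnm_segment_curve(unaged_sim, heat_seg)
  gt <- detect_glass_transition(unaged_curve, b)
  Tg <- gt$T_mid
  dcp <- gt$delta_cp_at_Tg
  T1 <- Tg - cfg$integration_offsets[1]
  T2 <- Tg + cfg$integration_offsets[2]

  per_Ta <- lapply(cfg$ageing_temperatures, function(Ta) {
    tryCatch({
      if (cfg$source == "series") {
        kp <- .kww_for_Ta(cfg, Ta)
        if (is.null(kp))
          stop_glassage(sprintf("no KWW parameters configured for Ta = %g K", Ta),
                        "glassage_validation_error")
        series <- simulate_kww_series(Ta, cfg$ageing_times, kp$tau, kp$beta,
                                      kp$dHr_inf, noise_sd = cfg$noise_sd,
                                      seed = cfg$seed + round(Ta))
      } else {
        dHr <- vapply(cfg$ageing_times, function(ta) {
          sim <- simulate_tnm(ageing_program(Ta = Ta, t_a = ta,
                                             T_high = cfg$T_high,
                                             T_low = cfg$T_low,
                                             rate = cfg$scan_rate),
                              cfg$tnm, dt = cfg$dt, dT_max = cfg$dT_max)
          aged <- tnm_segment_curve(sim, length(sim$program$segments))
          enthalpy_relaxation(aged, unaged_curve, T1, T2)
        }, 0)
        series <- relaxation_series(Ta, cfg$ageing_times, pmax(dHr, -0.3))
      }
      if (all(series$data$dHr == 0)) {
        warning(sprintf("all dHr zero at Ta = %g K; KWW fit skipped", Ta))
        return(list(Ta = Ta, series = series, fit = NULL))
      }
      eq_scalar <- equilibrium_relaxation(dcp, Tg, Ta, "scalar")
      eq_integral <- equilibrium_relaxation(b, Tg, Ta, "integral")
      fix <- switch(cfg$dHr_inf_mode, free = NULL, scalar = eq_scalar,
                    integral = eq_integral)
      fit <- fit_kww(series, dHr_inf = fix)
      phi <- recovery_from_series(series, coef(fit)["dHr_inf"])
      tf <- fictive_vs_time(series, Tg, dcp)
      list(Ta = Ta, series = series, fit = fit, recovery = phi,
           fictive = tf,
           equilibrium = c(scalar = eq_scalar, integral = eq_integral))
    }, error = function(e) list(Ta = Ta, error = conditionMessage(e)))
  })
  names(per_Ta) <- sprintf("Ta_%.0fC", kelvin_to_celsius(cfg$ageing_temperatures))
  structure(list(Tg = Tg, delta_cp = dcp,
                 integration_limits = c(T1 = T1, T2 = T2),
                 results = per_Ta, config = cfg),
            class = "ageing_study")
}

#' @export
print.ageing_study <- function(x, ...) {
  cat(sprintf("Ageing study: Tg = %.2f K, delta Cp = %.3f J/(g K)\n",
              x$Tg, x$delta_cp))
  for (r in x$results) {
    if (!is.null(r$error)) {
      cat(sprintf("  Ta = %.1f K: FAILED (%s)\n", r$Ta, r$error))
    } else if (is.null(r$fit)) {
      cat(sprintf("  Ta = %.1f K: no relaxation observed\n", r$Ta))
    } else {
      p <- coef(r$fit)
      cat(sprintf(
        "  Ta = %.1f K: tau = %.3g h, beta = %.3f, dHr_inf = %.2f J/g\n",
        r$Ta, p["tau"] / 3600, p["beta"], p["dHr_inf"]))
    }
  }
  invisible(x)
}

#' Run the fragility rate-sweep study
#'
#' Simulates cooling sweeps (limiting fictive temperature per rate) and
#' heating sweeps (midpoint Tg per rate), regresses ln q against 1/T for
#' each mode, and reports activation energy, fragility index and class.
#'
#' @param config a [study_config()].
#' @return a list of class `fragility_study` with `cooling` and `heating`
#'   [fragility()] fits.
#' @export
run_fragility_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  if (length(cfg$cooling_rates) < 2L || length(cfg$heating_rates) < 2L)
    stop_glassage("need several rates per sweep", "glassage_validation_error")
  b <- cfg$tnm$cp_baseline

  Tf_cool <- vapply(cfg$cooling_rates, function(q) {
    sim <- simulate_tnm(rate_sweep_program(q, NULL, T_high = cfg$T_high,
                                           T_low = cfg$T_low),
                        cfg$tnm, dt = cfg$dt, dT_max = cfg$dT_max)
    tail(sim$Tf, 1)
  }, 0)
  cool <- fragility(cfg$cooling_rates, Tf_cool, mode = "cooling")

  Tg_heat <- vapply(cfg$heating_rates, function(q) {
    pre <- if (cfg$heating_sweep == "matched") q else cfg$fixed_cool_rate
    sim <- simulate_tnm(rate_sweep_program(pre, q, T_high = cfg$T_high,
                                           T_low = cfg$T_low),
                        cfg$tnm, dt = cfg$dt, dT_max = cfg$dT_max)
    detect_glass_transition(tnm_segment_curve(sim, 2), b)$T_mid
  }, 0)
  heat <- fragility(cfg$heating_rates, Tg_heat, mode = "heating")

  structure(list(cooling = cool, heating = heat, config = cfg),
            class = "fragility_study")
}

#' @export
print.fragility_study <- function(x, ...) {
  print(x$heating); print(x$cooling)
  cat(sprintf("  heating/cooling m ratio: %.3f\n",
              x$heating$m / x$cooling$m))
  invisible(x)
}

#' Serialise a study to a JSON report
#'
#' Deterministic (no timestamps) JSON suitable for regression-testing a
#' pipeline run; numbers are written at full precision.
#'
#' @param study an `ageing_study` or `fragility_study`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(study, path) {
  rep <- if (inherits(study, "ageing_study")) {
    list(kind = "ageing_study", Tg_K = study$Tg, delta_cp = study$delta_cp,
         integration_limits_K = as.list(study$integration_limits),
         results = lapply(study$results, function(r) {
           if (!is.null(r$error)) return(list(Ta_K = r$Ta, error = r$error))
           out <- list(Ta_K = r$Ta,
                       series = list(t_a_s = r$series$data$t_a,
                                     dHr_J_per_g = r$series$data$dHr))
           if (!is.null(r$fit)) {
             p <- coef(r$fit)
             out$kww <- list(tau_s = unname(p["tau"]),
                             beta = unname(p["beta"]),
                             dHr_inf_J_per_g = unname(p["dHr_inf"]),
                             rss = r$fit$rss, converged = r$fit$converged)
             out$recovery <- list(t_a_s = r$recovery$t_a, phi = r$recovery$phi)
             out$fictive <- list(t_a_s = r$fictive$t_a, Tf_K = r$fictive$Tf)
             out$equilibrium_J_per_g <- as.list(r$equilibrium)
           }
           out
         }),
         seed = study$config$seed)
  } else if (inherits(study, "fragility_study")) {
    one <- function(f) list(Ea_J_per_mol = f$Ea, m = f$m, label = f$label,
                            Tg_ref_K = f$Tg_ref, r_squared = f$r_squared,
                            rates_K_per_min = f$data$rate,
                            T_char_K = f$data$T_char)
    list(kind = "fragility_study", heating = one(study$heating),
         cooling = one(study$cooling), seed = study$config$seed)
  } else stop_glassage("unknown study type", "glassage_validation_error")
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
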