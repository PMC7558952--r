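#' Integrate specific heat into total enthalpy
#'
#' Cumulative trapezoidal integration of Cp(T) over temperature, anchored so
#' that `H(T_ref) = H_ref`. The result is returned on an ascending
#' temperature grid regardless of scan direction.
#'
#' @param curve a specific-heat [dsc_curve()] with monotone temperature.
#' @param T_ref anchor temperature (K), inside the curve range.
#' @param H_ref enthalpy at the anchor (J g^-1).
#' @return an object of class `enthalpy_curve` with fields `temperature`,
#'   `H` and `reference`.
#' @examples
#' cv <- dsc_curve(c(0, 30, 60), c(300, 305, 310), rep(2, 3),
#'                 "specific_heat", nominal_rate = 10)
#' ec <- integrate_enthalpy(cv, T_ref = 300, H_ref = 0)
#' tail(ec$H, 1)  # 20 J/g
#' @export
integrate_enthalpy <- function(curve, T_ref, H_ref = 0) {
  stopifnot(inherits(curve, "dsc_curve"))
  if (curve$signal_kind != "specific_heat")
    stop_glassage("enthalpy integration requires a specific-heat curve",
                  "glassage_validation_error")
  Tv <- curve$temperature
  dT <- diff(Tv)
  if (!(all(dT > 0) || all(dT < 0)))
    stop_glassage("curve temperature must be monotone", "glassage_validation_error")
  if (dT[1] < 0) {
    Tv <- rev(Tv); Cp <- rev(curve$value)
  } else Cp <- curve$value
  if (T_ref < Tv[1] || T_ref > tail(Tv, 1))
    stop_glassage("reference temperature outside curve range",
                  "glassage_reference_error")
  H <- pracma::cumtrapz(Tv, Cp)[, 1]
  H0 <- approx(Tv, H, xout = T_ref)$y
  structure(list(temperature = Tv, H = H - H0 + H_ref,
                 reference = c(T_ref = T_ref, H_ref = H_ref)),
            class = "enthalpy_curve")
}

#' @export
print.enthalpy_curve <- function(x, ...) {
  cat(sprintf(
    "Enthalpy curve: %d samples, %.2f-%.2f K, anchored H(%.2f K) = %.3g J/g\n",
    length(x$H), x$temperature[1], tail(x$temperature, 1),
    x$reference["T_ref"], x$reference["H_ref"]))
  invisible(x)
}

#' Fit a straight enthalpy line in a temperature window
#'
#' Least-squares line through an enthalpy curve inside `window`; used for the
#' glassy-state line and for extrapolating the liquid-state enthalpy below
#' the transition.
#'
#' @param ec an [integrate_enthalpy()] result.
#' @param window temperature window `c(lo, hi)` (K).
#' @return list with `intercept` (J g^-1 at 0 K), `slope` (J g^-1 K^-1) and
#'   residual `rms`.
#' @export
fit_enthalpy_line <- function(ec, window) {
  stopifnot(inherits(ec, "enthalpy_curve"))
  sel <- ec$temperature >= window[1] & ec$temperature <= window[2]
  if (sum(sel) < 2L)
    stop_glassage("enthalpy-line window contains fewer than 2 samples",
                  "glassage_window_error")
  f <- lm(y ~ x, data = data.frame(x = ec$temperature[sel], y = ec$H[sel]))
  co <- unname(coef(f))
  list(intercept = co[1], slope = co[2],
       rms = sqrt(mean(residuals(f)^2)))
}

#' Fictive temperature by enthalpy-line intersection
#'
#' The fictive temperature of a glass is the temperature at which its
#' extrapolated glassy-state enthalpy line meets the extrapolated
#' liquid-state enthalpy line. The glassy line is fitted through the
#' integrated enthalpy of the sample inside `glass_window`; the liquid line
#' is supplied (typically from [fit_enthalpy_line()] above the transition on
#' the same or a reference curve).
#'
#' @param H_glass an [integrate_enthalpy()] result for the glass.
#' @param liquid_line a list with `intercept` and `slope` describing the
#'   liquid enthalpy line (same enthalpy reference as `H_glass`).
#' @param glass_window temperature window (K) below the transition used to
#'   fit the glassy line.
#' @return an object of class `fictive_temp` with fields `Tf`, `method` and
#'   `diagnostics`.
#' @export
fictive_temperature <- function(H_glass, liquid_line, glass_window) {
  gl <- fit_enthalpy_line(H_glass, glass_window)
  dslope <- liquid_line$slope - gl$slope
  if (abs(dslope) < 1e-10)
    stop_glassage("glass and liquid enthalpy lines are parallel",
                  "glassage_no_intersection_error")
  Tf <- (gl$intercept - liquid_line$intercept) / dslope
  structure(list(Tf = Tf, method = "enthalpy_intersection",
                 diagnostics = list(glass_line = gl,
                                    liquid_line = liquid_line)),
            class = "fictive_temp")
}

#' Fictive temperature by the equal-area construction
#'
#' Moynihan's construction: Tf solves
#' \deqn{\int_{T_f}^{T^*} \Delta C_p(T)\,dT =
#'       \int_{T'}^{T^*} (C_p(T) - C_{p,solid}(T))\,dT,}
#' with T' below and T* above the transition. Equivalent to the
#' enthalpy-line intersection when the reference lines are exact.
#'
#' @param curve a specific-heat [dsc_curve()] spanning the transition.
#' @param baseline a [cp_baseline()].
#' @param T_prime,T_star integration limits (K); default to the inner edges
#'   of the baseline windows.
#' @return an object of class `fictive_temp`.
#' @export
fictive_temperature_equal_area <- function(curve, baseline,
                                           T_prime = NULL, T_star = NULL) {
  stopifnot(inherits(curve, "dsc_curve"), inherits(baseline, "cp_baseline"))
  if (curve$signal_kind != "specific_heat")
    stop_glassage("equal-area construction requires a specific-heat curve",
                  "glassage_validation_error")
  T_prime <- T_prime %||% baseline$solid_window[2]
  T_star <- T_star %||% baseline$liquid_window[1]
  Tv <- curve$temperature
  ord <- order(Tv)
  Tv <- Tv[ord]; Cp <- curve$value[ord]
  if (T_prime < Tv[1] || T_star > tail(Tv, 1))
    stop_glassage("integration limits outside curve range",
                  "glassage_reference_error")
  sel <- Tv >= T_prime & Tv <= T_star
  Ts <- c(T_prime, Tv[sel], T_star)
  Cs <- c(approx(Tv, Cp, T_prime)$y, Cp[sel], approx(Tv, Cp, T_star)$y)
  keep <- !duplicated(Ts)
  Ts <- Ts[keep]; Cs <- Cs[keep]
  rhs <- pracma::trapz(Ts, Cs - baseline_cp(baseline, Ts, "solid"))
  # integral of the linear delta-Cp from Tf to T_star, closed form
  dc <- function(T) delta_cp(baseline, T)
  lhs <- function(Tf) (dc(Tf) + dc(T_star)) / 2 * (T_star - Tf)
  f <- function(Tf) lhs(Tf) - rhs
  if (f(T_prime) * f(T_star) > 0)
    stop_glassage("equal-area condition has no root in the scan window",
                  "glassage_no_intersection_error")
  Tf <- uniroot(f, c(T_prime, T_star), tol = 1e-8)$root
  structure(list(Tf = Tf, method = "equal_area",
                 diagnostics = list(excess_area = rhs,
                                    limits = c(T_prime = T_prime,
                                               T_star = T_star))),
            class = "fictive_temp")
}

#' @export
print.fictive_temp <- function(x, ...) {
  cat(sprintf("Fictive temperature: %.2f K (%.2f degC), method: %s\n",
              x$Tf, kelvin_to_celsius(x$Tf), x$method))
  invisible(x)
}
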