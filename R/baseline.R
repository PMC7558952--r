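#' Solid and liquid heat-capacity reference lines
#'
#' Linear Cp reference lines for the glassy solid and the (supercooled)
#' liquid, fitted in user-chosen temperature windows on either side of the
#' glass transition. The heat-capacity step is
#' `delta_cp(b, T) = liquid(T) - solid(T)` and must be positive between the
#' windows.
#'
#' @param solid,liquid numeric `c(intercept, slope)` of Cp in J g^-1 K^-1
#'   (intercept at T = 0 K) for the two phases.
#' @param solid_window,liquid_window temperature windows (K) the lines refer
#'   to; `c(lo, hi)`.
#' @param rms residual root-mean-square of each fit (diagnostic).
#' @return an object of class `cp_baseline`.
#' @examples
#' b <- cp_baseline(solid = c(1.0, 0.003), liquid = c(1.47, 0.003),
#'                  solid_window = c(310, 350), liquid_window = c(390, 420))
#' delta_cp(b, 375)
#' @export
cp_baseline <- function(solid, liquid, solid_window, liquid_window,
                        rms = c(solid = NA_real_, liquid = NA_real_)) {
  stopifnot(length(solid) == 2L, length(liquid) == 2L,
            solid_window[1] < solid_window[2],
            liquid_window[1] < liquid_window[2])
  if (solid_window[2] > liquid_window[1])
    stop_glassage("solid and liquid windows must not overlap",
                  "glassage_window_error")
  b <- structure(list(solid = unname(solid), liquid = unname(liquid),
                      solid_window = solid_window,
                      liquid_window = liquid_window, rms = rms),
                 class = "cp_baseline")
  gap <- seq(solid_window[2], liquid_window[1], length.out = 32)
  dcp <- delta_cp(b, gap)
  if (any(dcp < -1e-12))
    stop_glassage("liquid line must lie above solid line across the transition",
                  "glassage_validation_error")
  if (min(dcp) <= 0)
    warning("degenerate baseline: zero heat-capacity step across the transition")
  b
}

#' @export
print.cp_baseline <- function(x, ...) {
  cat(sprintf("Cp baselines (J/(g K)):\n  solid : %.4g + %.4g T  on [%g, %g] K\n  liquid: %.4g + %.4g T  on [%g, %g] K\n",
              x$solid[1], x$solid[2], x$solid_window[1], x$solid_window[2],
              x$liquid[1], x$liquid[2], x$liquid_window[1], x$liquid_window[2]))
  cat(sprintf("  delta Cp at window midpoint: %.4g\n",
              delta_cp(x, mean(c(x$solid_window[2], x$liquid_window[1])))))
  invisible(x)
}

#' Evaluate a baseline line
#'
#' @param baseline a [cp_baseline()].
#' @param T temperature (K), vectorised.
#' @param phase `"solid"` or `"liquid"`.
#' @return Cp of the reference line at `T` (J g^-1 K^-1).
#' @export
baseline_cp <- function(baseline, T, phase = c("solid", "liquid")) {
  phase <- match.arg(phase)
  p <- baseline[[phase]]
  p[1] + p[2] * T
}

#' Heat-capacity step between liquid and solid reference lines
#'
#' @inheritParams baseline_cp
#' @return `liquid(T) - solid(T)` in J g^-1 K^-1.
#' @export
delta_cp <- function(baseline, T) {
  baseline_cp(baseline, T, "liquid") - baseline_cp(baseline, T, "solid")
}

#' Fit Cp reference lines from a thermogram
#'
#' Ordinary least-squares lines through the specific-heat samples inside the
#' solid and liquid windows.
#'
#' @param curve a specific-heat [dsc_curve()] spanning both windows.
#' @param solid_window,liquid_window temperature windows (K), each containing
#'   at least 5 samples and excluding the transition region.
#' @return a [cp_baseline()] with per-window residual RMS.
#' @export
fit_cp_baselines <- function(curve, solid_window = c(310, 350),
                             liquid_window = c(390, 420)) {
  stopifnot(inherits(curve, "dsc_curve"))
  if (curve$signal_kind != "specific_heat")
    stop_glassage("baseline fitting requires a specific-heat curve",
                  "glassage_validation_error")
  if (solid_window[2] > liquid_window[1])
    stop_glassage("solid and liquid windows must not overlap",
                  "glassage_window_error")
  fit1 <- function(win, label) {
    sel <- curve$temperature >= win[1] & curve$temperature <= win[2]
    if (sum(sel) < 5L)
      stop_glassage(sprintf("%s window contains fewer than 5 samples", label),
                    "glassage_window_error")
    f <- lm(y ~ x, data = data.frame(x = curve$temperature[sel],
                                     y = curve$value[sel]))
    list(coefs = unname(coef(f)), rms = sqrt(mean(residuals(f)^2)))
  }
  s <- fit1(solid_window, "solid")
  l <- fit1(liquid_window, "liquid")
  cp_baseline(solid = s$coefs, liquid = l$coefs,
              solid_window = solid_window, liquid_window = liquid_window,
              rms = c(solid = s$rms, liquid = l$rms))
}

#' Locate the glass transition on a Cp curve
#'
#' The midpoint temperature is where Cp crosses the half-step line
#' `solid(T) + delta_cp(T)/2` (the common DSC midpoint convention); onset and
#' end are the intersections of the tangent at the steepest Cp slope with the
#' solid and liquid reference lines. When the half-step line is crossed more
#' than once (e.g. an enthalpy-recovery overshoot), the crossing nearest the
#' steepest slope is used and a warning is raised.
#'
#' @param curve a specific-heat [dsc_curve()] spanning the transition.
#' @param baseline a [cp_baseline()].
#' @return an object of class `glass_transition` with fields `T_onset`,
#'   `T_mid`, `T_end`, `delta_cp_at_Tg` and `mode` (heating/cooling from the
#'   curve's nominal rate).
#' @export
detect_glass_transition <- function(curve, baseline) {
  stopifnot(inherits(curve, "dsc_curve"), inherits(baseline, "cp_baseline"))
  if (curve$signal_kind != "specific_heat")
    stop_glassage("transition detection requires a specific-heat curve",
                  "glassage_validation_error")
  Tv <- curve$temperature
  ord <- order(Tv)
  Tv <- Tv[ord]; Cp <- curve$value[ord]
  lo <- baseline$solid_window[2]; hi <- baseline$liquid_window[1]
  sel <- which(Tv >= lo & Tv <= hi)
  if (length(sel) < 5L)
    stop_glassage("curve does not span the transition region",
                  "glassage_transition_error")
  Ts <- Tv[sel]; Cs <- Cp[sel]
  half <- baseline_cp(baseline, Ts, "solid") + delta_cp(baseline, Ts) / 2
  d <- Cs - half
  cross <- which(d[-length(d)] * d[-1] <= 0 & d[-length(d)] != d[-1])
  if (length(cross) == 0L)
    stop_glassage("no half-step crossing found", "glassage_transition_error")
  slope <- diff(Cs) / diff(Ts)
  ks <- which.max(slope)
  if (length(cross) > 1L)
    warning("multiple half-step crossings; using the one nearest the steepest slope")
  k <- cross[which.min(abs(cross - ks))]
  T_mid <- Ts[k] - d[k] * (Ts[k + 1] - Ts[k]) / (d[k + 1] - d[k])
  # tangent at the steepest slope
  T_t <- (Ts[ks] + Ts[ks + 1]) / 2
  C_t <- (Cs[ks] + Cs[ks + 1]) / 2
  m_t <- slope[ks]
  line_x <- function(p) {  # intersection of tangent with line p1 + p2 T
    if (abs(m_t - p[2]) < 1e-12)
      stop_glassage("tangent parallel to baseline", "glassage_transition_error")
    (p[1] + p[2] * T_t - C_t + m_t * T_t - p[2] * T_t) / (m_t - p[2])
  }
  T_onset <- line_x(baseline$solid)
  T_end <- line_x(baseline$liquid)
  mode <- if (is.finite(curve$nominal_rate) && curve$nominal_rate < 0)
    "cooling" else "heating"
  structure(list(T_onset = T_onset, T_mid = T_mid, T_end = T_end,
                 delta_cp_at_Tg = delta_cp(baseline, T_mid), mode = mode),
            class = "glass_transition")
}

#' @export
print.glass_transition <- function(x, ...) {
  cat(sprintf(
    "Glass transition (%s): onset %.2f K, midpoint %.2f K, end %.2f K\n",
    x$mode, x$T_onset, x$T_mid, x$T_end))
  cat(sprintf("  delta Cp at Tg: %.3f J/(g K)\n", x$delta_cp_at_Tg))
  invisible(x)
}
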