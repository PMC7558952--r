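#' Enthalpy-relaxation measurement series
#'
#' A `relaxation_series` collects enthalpy-relaxation measurements
#' (ageing time, recovered enthalpy) at one ageing temperature. Replicate
#' ageing times are averaged; missing per-point standard deviations default
#' to the typical DSC repeatability of 0.3 J g^-1.
#'
#' @param Ta ageing temperature (K).
#' @param t_a ageing times (s), non-negative.
#' @param dHr enthalpy relaxation at each time (J g^-1).
#' @param sd per-point standard deviation (J g^-1); scalar or vector,
#'   `NULL` for the 0.3 J g^-1 default.
#' @param dHr_inf_fixed optional fixed equilibrium enthalpy relaxation
#'   (J g^-1) used by [fit_kww()] when the plateau is not fitted.
#' @return an object of class `relaxation_series` (sorted by `t_a`).
#' @examples
#' relaxation_series(Ta = 358.15, t_a = c(1, 4, 16) * 3600,
#'                   dHr = c(2.1, 4.0, 5.8))
#' @export
relaxation_series <- function(Ta, t_a, dHr, sd = NULL, dHr_inf_fixed = NULL) {
  n <- length(t_a)
  if (length(dHr) != n)
    stop_glassage("t_a and dHr must have equal length", "glassage_validation_error")
  if (any(t_a < 0))
    stop_glassage("ageing times must be non-negative", "glassage_validation_error")
  if (any(dHr < -0.3))
    stop_glassage("dHr below -0.3 J/g is outside measurement-noise bounds",
                  "glassage_validation_error")
  sd <- if (is.null(sd)) rep(0.3, n) else rep(sd, length.out = n)
  d <- data.frame(t_a = t_a, dHr = dHr, sd = sd)
  if (anyDuplicated(d$t_a)) {
    # average replicates; pool sd as the rms of the replicate sds
    agg <- do.call(rbind, lapply(split(d, d$t_a), function(g)
      data.frame(t_a = g$t_a[1], dHr = mean(g$dHr),
                 sd = sqrt(mean(g$sd^2) / nrow(g)))))
    d <- agg
  }
  d <- d[order(d$t_a), , drop = FALSE]
  rownames(d) <- NULL
  structure(list(Ta = Ta, data = d, dHr_inf_fixed = dHr_inf_fixed),
            class = "relaxation_series")
}

#' @export
print.relaxation_series <- function(x, ...) {
  cat(sprintf(
    "Relaxation series at Ta = %.2f K (%.1f degC): %d ageing times, %.3g-%.3g h\n",
    x$Ta, kelvin_to_celsius(x$Ta), nrow(x$data),
    min(x$data$t_a) / 3600, max(x$data$t_a) / 3600))
  if (!is.null(x$dHr_inf_fixed))
    cat(sprintf("  fixed equilibrium relaxation: %.3g J/g\n", x$dHr_inf_fixed))
  print(transform(x$data, t_a_h = t_a / 3600)[, c("t_a_h", "dHr", "sd")])
  invisible(x)
}

#' Assemble a relaxation series from tabulated records
#'
#' @param records a data frame with columns `Ta` (K), `t_a` (s), `dHr`
#'   (J g^-1) and optionally `sd`; all rows must share one `Ta`.
#' @param dHr_inf_fixed optional fixed plateau (J g^-1).
#' @return a [relaxation_series()].
#' @export
build_series <- function(records, dHr_inf_fixed = NULL) {
  stopifnot(is.data.frame(records),
            all(c("Ta", "t_a", "dHr") %in% names(records)))
  if (length(unique(records$Ta)) != 1L)
    stop_glassage("records mix more than one ageing temperature",
                  "glassage_validation_error")
  if (nrow(records) < 3L)
    stop_glassage("need at least 3 records per ageing temperature",
                  "glassage_validation_error")
  relaxation_series(records$Ta[1], records$t_a, records$dHr,
                    sd = records$sd, dHr_inf_fixed = dHr_inf_fixed)
}

#' Read and write relaxation-series tables
#'
#' CSV convention: columns `Ta_C`, `t_a_h`, `dHr_J_per_g` and optional
#' `sd_J_per_g` (Celsius and hours at the file boundary, kelvin and seconds
#' internally).
#'
#' @param path file path.
#' @return `read_series_csv()` returns a [relaxation_series()].
#' @export
read_series_csv <- function(path) {
  tab <- read.csv(path)
  need <- c("Ta_C", "t_a_h", "dHr_J_per_g")
  if (!all(need %in% names(tab)))
    stop_glassage(sprintf("series CSV must contain columns %s",
                          paste(need, collapse = ", ")),
                  "glassage_format_error")
  build_series(data.frame(Ta = celsius_to_kelvin(tab$Ta_C),
                          t_a = tab$t_a_h * 3600,
                          dHr = tab$dHr_J_per_g,
                          sd = if ("sd_J_per_g" %in% names(tab))
                            tab$sd_J_per_g else NA))
}

#' @rdname read_series_csv
#' @param series a [relaxation_series()].
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "relaxation_series"))
  tab <- data.frame(Ta_C = kelvin_to_celsius(series$Ta),
                    t_a_h = series$data$t_a / 3600,
                    dHr_J_per_g = series$data$dHr,
                    sd_J_per_g = series$data$sd)
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Enthalpy relaxation from an aged/unaged curve pair
#'
#' The recovered enthalpy is the area between the aged and unaged scans
#' across the glass transition,
#' \deqn{\Delta H_r = \frac{1}{q}\int_{T_1}^{T_2}
#'   (\Phi_{aged} - \Phi_{unaged})\,dT
#'   = \int_{T_1}^{T_2} (C_{p,aged} - C_{p,unaged})\,dT.}
#' Heat-flow inputs are converted with [to_specific_heat()] first, so the
#' two forms are numerically identical. Both curves are linearly
#' interpolated onto the union of their temperature samples inside
#' `[T1, T2]` (exact for piecewise-linear inputs) before trapezoidal
#' integration.
#'
#' @param aged,unaged [dsc_curve()]s covering `[T1, T2]`, heating at the
#'   same nominal rate.
#' @param T1,T2 integration limits (K), chosen to bracket the transition.
#' @return enthalpy relaxation in J g^-1.
#' @export
enthalpy_relaxation <- function(aged, unaged, T1, T2) {
  stopifnot(inherits(aged, "dsc_curve"), inherits(unaged, "dsc_curve"))
  if (T1 >= T2)
    stop_glassage("T1 must be below T2", "glassage_validation_error")
  ra <- aged$nominal_rate; ru <- unaged$nominal_rate
  if (is.finite(ra) && is.finite(ru) && abs(ra - ru) > 1e-9)
    stop_glassage("aged and unaged curves have different nominal rates",
                  "glassage_rate_mismatch_error")
  a <- to_specific_heat(aged)
  u <- to_specific_heat(unaged)
  rng <- function(cv) range(cv$temperature)
  if (T1 < max(rng(a)[1], rng(u)[1]) || T2 > min(rng(a)[2], rng(u)[2]))
    stop_glassage("both curves must cover [T1, T2]", "glassage_validation_error")
  grid <- sort(unique(c(T1, T2,
                        a$temperature[a$temperature > T1 & a$temperature < T2],
                        u$temperature[u$temperature > T1 & u$temperature < T2])))
  ya <- approx(a$temperature, a$value, xout = grid)$y
  yu <- approx(u$temperature, u$value, xout = grid)$y
  pracma::trapz(grid, ya - yu)
}

#' Equilibrium enthalpy relaxation
#'
#' The maximum recoverable enthalpy for a glass aged at `Ta`:
#' `scalar` mode evaluates `delta_cp * (Tg - Ta)` (with the step taken at
#' `Tg` when a baseline is supplied); `integral` mode integrates the
#' temperature-dependent step, `int_Ta^Tg delta_cp(T) dT`.
#'
#' @param x a [cp_baseline()] or a scalar heat-capacity step (J g^-1 K^-1).
#' @param Tg glass transition temperature (K).
#' @param Ta ageing temperature (K), below `Tg`.
#' @param mode `"scalar"` or `"integral"`.
#' @return equilibrium enthalpy relaxation in J g^-1.
#' @examples
#' equilibrium_relaxation(0.47, Tg = 375.35, Ta = 358.15)
#' @export
equilibrium_relaxation <- function(x, Tg, Ta, mode = c("scalar", "integral")) {
  mode <- match.arg(mode)
  if (Ta > Tg)
    stop_glassage("ageing temperature must not exceed Tg", "glassage_domain_error")
  if (inherits(x, "cp_baseline")) {
    if (mode == "scalar") return(delta_cp(x, Tg) * (Tg - Ta))
    # linear integrand: exact trapezoid
    return((delta_cp(x, Ta) + delta_cp(x, Tg)) / 2 * (Tg - Ta))
  }
  stopifnot(is.numeric(x), length(x) == 1L)
  x * (Tg - Ta)  # constant step: both modes coincide
}
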