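#' Apparent activation energy from a rate sweep
#'
#' Regression of ln(q) on 1/T_char over a sweep of scan rates, where T_char
#' is the glass transition temperature (heating sweeps) or the limiting
#' fictive temperature (cooling sweeps). The apparent activation energy of
#' structural relaxation at the transition is
#' \deqn{E_a = -R\,\frac{d\,\ln q}{d(1/T)},}
#' with R the gas constant.
#'
#' @param rate scan-rate magnitudes (K min^-1), at least 3 distinct values.
#' @param T_char characteristic temperature per rate (K).
#' @param mode `"heating"` or `"cooling"`; a sweep must be single-mode.
#' @return list with `Ea` (J mol^-1), `slope` (K), `intercept`,
#'   `r_squared` and `mode`.
#' @examples
#' Tc <- c(373, 374.5, 376, 377.5)
#' q <- exp(20 - 495000 / 8.314 / Tc + 495000 / 8.314 / 375)
#' fit_activation_energy(q, Tc)$Ea
#' @export
fit_activation_energy <- function(rate, T_char, mode = c("heating", "cooling")) {
  mode <- match.arg(mode)
  if (length(rate) != length(T_char))
    stop_glassage("rate and T_char must have equal length",
                  "glassage_validation_error")
  if (length(unique(rate)) < 3L)
    stop_glassage("need at least 3 distinct rates", "glassage_validation_error")
  if (any(rate <= 0))
    stop_glassage("rates must be positive magnitudes", "glassage_validation_error")
  x <- 1 / T_char
  if (diff(range(x)) < 1e-12)
    stop_glassage("no spread in 1/T_char; regression ill-conditioned",
                  "glassage_conditioning_error")
  ly <- log(rate)
  f <- lm(ly ~ x, data = data.frame(x = x, ly = ly))
  slope <- unname(coef(f)[2])
  r2 <- 1 - sum(residuals(f)^2) / sum((ly - mean(ly))^2)
  list(Ea = -.R_GAS * slope, slope = slope,
       intercept = unname(coef(f)[1]), r_squared = r2, mode = mode)
}

#' Angell kinetic fragility index
#'
#' `m = Ea / (2.303 R Tg_ref)`: the steepness of the relaxation-time
#' Arrhenius plot at the glass transition, scaled so that a purely
#' Arrhenius ("strong") liquid has m around 16.
#'
#' @param Ea apparent activation energy (J mol^-1).
#' @param Tg_ref reference glass transition temperature (K), conventionally
#'   the value at the standard 10 K min^-1 scan.
#' @return dimensionless fragility index.
#' @examples
#' fragility_m(495.8e3, 375.35)  # ~69
#' @export
fragility_m <- function(Ea, Tg_ref) {
  if (Tg_ref <= 0)
    stop_glassage("Tg_ref must be positive", "glassage_validation_error")
  Ea / (2.303 * .R_GAS * Tg_ref)
}

#' Classify a glass former by its fragility index
#'
#' Conventional bands: strong below m = 40, fragile above m = 100,
#' moderately fragile between (typical pharmaceutical glasses fall at
#' m = 60-120).
#'
#' @param m fragility index, positive.
#' @return `"strong"`, `"moderately_fragile"` or `"fragile"`.
#' @examples
#' classify_fragility(69)
#' @export
classify_fragility <- function(m) {
  if (m <= 0)
    stop_glassage("fragility index must be positive", "glassage_validation_error")
  if (m < 40) "strong" else if (m < 100) "moderately_fragile" else "fragile"
}

#' Fragility analysis of a rate sweep
#'
#' Convenience wrapper combining [fit_activation_energy()],
#' [fragility_m()] and [classify_fragility()].
#'
#' @inheritParams fit_activation_energy
#' @param Tg_ref reference temperature (K); defaults to `T_char` at the
#'   rate closest to 10 K min^-1.
#' @return an object of class `fragility_fit`.
#' @export
fragility <- function(rate, T_char, mode = c("heating", "cooling"),
                      Tg_ref = NULL) {
  mode <- match.arg(mode)
  fit <- fit_activation_energy(rate, T_char, mode)
  Tg_ref <- Tg_ref %||% T_char[which.min(abs(rate - 10))]
  m <- fragility_m(fit$Ea, Tg_ref)
  structure(c(fit, list(m = m, Tg_ref = Tg_ref,
                        label = classify_fragility(m),
                        data = data.frame(rate = rate, T_char = T_char))),
            class = "fragility_fit")
}

#' @export
print.fragility_fit <- function(x, ...) {
  cat(sprintf("Fragility from %s sweep (%d rates, %.3g-%.3g K/min)\n",
              x$mode, nrow(x$data), min(x$data$rate), max(x$data$rate)))
  cat(sprintf("  Ea = %.1f kJ/mol  (r^2 = %.4f)\n", x$Ea / 1000, x$r_squared))
  cat(sprintf("  m  = %.1f at Tg_ref = %.2f K  ->  %s\n",
              x$m, x$Tg_ref, x$label))
  invisible(x)
}

#' Read a rate-sweep table
#'
#' CSV convention: columns `rate_K_per_min`, `T_char_C`, `mode`.
#'
#' @param path file path.
#' @return data frame with columns `rate`, `T_char` (K), `mode`.
#' @export
read_sweep_csv <- function(path) {
  tab <- read.csv(path)
  need <- c("rate_K_per_min", "T_char_C", "mode")
  if (!all(need %in% names(tab)))
    stop_glassage(sprintf("sweep CSV must contain columns %s",
                          paste(need, collapse = ", ")),
                  "glassage_format_error")
  data.frame(rate = tab$rate_K_per_min,
             T_char = celsius_to_kelvin(tab$T_char_C),
             mode = tab$mode)
}
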