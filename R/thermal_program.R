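#' Thermal program segments
#'
#' A thermal program is an ordered sequence of segments, each either a
#' temperature ramp at constant rate or an isothermal hold. `ramp_segment()`
#' and `isothermal_segment()` build single segments; `thermal_program()`
#' assembles and validates a program. Temperatures are kelvin, rates are
#' signed K min^-1, durations are minutes (instrument conventions; the
#' simulator converts to seconds internally).
#'
#' @param T_start,T_end segment start/end temperature (K).
#' @param rate signed ramp rate (K min^-1); negative for cooling.
#' @param T hold temperature (K).
#' @param duration hold duration (min).
#' @return an object of class `thermal_segment`.
#' @examples
#' prog <- thermal_program(
#'   ramp_segment(463.15, 358.15, rate = -10),
#'   isothermal_segment(358.15, duration = 32 * 60),
#'   ramp_segment(358.15, 298.15, rate = -10),
#'   ramp_segment(298.15, 463.15, rate = 10)
#' )
#' prog
#' @export
ramp_segment <- function(T_start, T_end, rate) {
  if (!is.finite(rate) || rate == 0)
    stop_glassage("ramp segment requires non-zero rate", "glassage_validation_error")
  if (sign(T_end - T_start) != sign(rate))
    stop_glassage("ramp rate sign inconsistent with temperature change",
                  "glassage_validation_error")
  duration <- (T_end - T_start) / rate
  structure(list(kind = "ramp", T_start = T_start, T_end = T_end,
                 rate = rate, duration = duration),
            class = "thermal_segment")
}

#' @rdname ramp_segment
#' @export
isothermal_segment <- function(T, duration) {
  if (duration < 0)
    stop_glassage("hold duration must be non-negative", "glassage_validation_error")
  structure(list(kind = "isothermal", T_start = T, T_end = T,
                 rate = 0, duration = duration),
            class = "thermal_segment")
}

#' @rdname ramp_segment
#' @param ... `thermal_segment` objects (or a single list of them).
#' @export
thermal_program <- function(...) {
  segs <- list(...)
  if (length(segs) == 1L && !inherits(segs[[1]], "thermal_segment"))
    segs <- segs[[1]]
  if (length(segs) == 0L)
    stop_glassage("empty thermal program", "glassage_validation_error")
  for (s in segs)
    if (!inherits(s, "thermal_segment"))
      stop_glassage("all elements must be thermal segments", "glassage_validation_error")
  if (length(segs) > 1L) {
    for (k in seq_len(length(segs) - 1L)) {
      if (abs(segs[[k]]$T_end - segs[[k + 1L]]$T_start) > 1e-9)
        stop_glassage(sprintf(
          "temperature discontinuity between segments %d and %d", k, k + 1L),
          "glassage_validation_error")
    }
  }
  structure(list(segments = segs), class = "thermal_program")
}

#' @export
print.thermal_segment <- function(x, ...) {
  if (x$kind == "ramp")
    cat(sprintf("ramp  %.2f -> %.2f K at %+.3g K/min (%.3g min)\n",
                x$T_start, x$T_end, x$rate, x$duration))
  else
    cat(sprintf("hold  %.2f K for %.3g min\n", x$T_start, x$duration))
  invisible(x)
}

#' @export
print.thermal_program <- function(x, ...) {
  cat(sprintf("Thermal program with %d segment(s):\n", length(x$segments)))
  for (s in x$segments) print(s)
  invisible(x)
}

#' Standard ageing and rate-sweep protocols
#'
#' `ageing_program()` encodes the usual DSC physical-ageing protocol: cool
#' from above the glass transition to the ageing temperature, hold, cool to a
#' low scan limit, then reheat past the transition. `rate_sweep_program()`
#' encodes one cool/heat cycle for a fragility sweep.
#'
#' @param Ta ageing temperature (K).
#' @param t_a ageing (hold) time in seconds.
#' @param T_high upper program temperature (K), above the transition.
#' @param T_low lower program temperature (K), below the transition.
#' @param rate scan rate magnitude (K min^-1) for cooling and reheating.
#' @return a `thermal_program`.
#' @examples
#' ageing_program(Ta = 358.15, t_a = 8 * 3600)
#' @export
ageing_program <- function(Ta, t_a, T_high = 463.15, T_low = 298.15, rate = 10) {
  segs <- list(ramp_segment(T_high, Ta, -abs(rate)))
  if (t_a > 0)
    segs <- c(segs, list(isothermal_segment(Ta, t_a / 60)))
  segs <- c(segs, list(ramp_segment(Ta, T_low, -abs(rate)),
                       ramp_segment(T_low, T_high, abs(rate))))
  thermal_program(segs)
}

#' @rdname ageing_program
#' @param cool_rate,heat_rate rate magnitudes (K min^-1) for the cooling and
#'   heating legs of a sweep cycle.
#' @export
rate_sweep_program <- function(cool_rate, heat_rate = NULL,
                               T_high = 463.15, T_low = 298.15) {
  segs <- list(ramp_segment(T_high, T_low, -abs(cool_rate)))
  if (!is.null(heat_rate))
    segs <- c(segs, list(ramp_segment(T_low, T_high, abs(heat_rate))))
  thermal_program(segs)
}
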