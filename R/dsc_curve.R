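#' DSC thermogram container
#'
#' A `dsc_curve` holds one thermogram segment in canonical units: time in
#' seconds, temperature in kelvin, and signal as either heat flow per gram
#' (W g^-1, endothermic up) or specific heat capacity (J g^-1 K^-1).
#'
#' @param time numeric vector, seconds, strictly increasing.
#' @param temperature numeric vector, kelvin.
#' @param value signal vector in the units implied by `signal_kind`.
#' @param signal_kind `"specific_heat"` or `"heat_flow_per_gram"`.
#' @param sample_id sample label.
#' @param mass_mg sample mass in mg (optional; needed to convert absolute
#'   heat flow at read time).
#' @param nominal_rate nominal scan rate, signed K min^-1 (0 for isothermal).
#' @param Ta,t_a optional ageing metadata: ageing temperature (K) and
#'   ageing time (s).
#' @return an object of class `dsc_curve`.
#' @examples
#' dsc_curve(time = c(0, 60, 120), temperature = c(300, 310, 320),
#'           value = c(1.2, 1.25, 1.3), signal_kind = "specific_heat",
#'           nominal_rate = 10)
#' @export
dsc_curve <- function(time, temperature, value,
                      signal_kind = c("specific_heat", "heat_flow_per_gram"),
                      sample_id = "sample", mass_mg = NA_real_,
                      nominal_rate = NA_real_, Ta = NA_real_, t_a = NA_real_) {
  signal_kind <- match.arg(signal_kind)
  n <- length(time)
  if (n < 2L || length(temperature) != n || length(value) != n)
    stop_glassage("time, temperature and value must have equal length >= 2",
                  "glassage_validation_error")
  if (anyNA(time) || anyNA(temperature) || anyNA(value))
    stop_glassage("NA values in thermogram arrays", "glassage_validation_error")
  if (any(diff(time) <= 0))
    stop_glassage("time must be strictly increasing", "glassage_validation_error")
  structure(list(sample_id = sample_id, mass_mg = mass_mg,
                 signal_kind = signal_kind, time = as.numeric(time),
                 temperature = as.numeric(temperature),
                 value = as.numeric(value),
                 nominal_rate = nominal_rate, Ta = Ta, t_a = t_a),
            class = "dsc_curve")
}

#' @export
print.dsc_curve <- function(x, ...) {
  unit <- if (x$signal_kind == "specific_heat") "J/(g K)" else "W/g"
  cat(sprintf("DSC curve '%s': %d samples, %.2f-%.2f K, signal %s [%s]",
              x$sample_id, length(x$time), min(x$temperature),
              max(x$temperature), x$signal_kind, unit))
  if (is.finite(x$nominal_rate)) cat(sprintf(", %+.3g K/min", x$nominal_rate))
  if (is.finite(x$Ta)) cat(sprintf(", aged %.3g h at %.2f K", x$t_a / 3600, x$Ta))
  cat("\n")
  invisible(x)
}

#' @export
plot.dsc_curve <- function(x, ...) {
  ylab <- if (x$signal_kind == "specific_heat")
    expression(C[p] ~ (J ~ g^-1 ~ K^-1)) else expression(Phi ~ (W ~ g^-1))
  plot(x$temperature, x$value, type = "l", xlab = "Temperature (K)",
       ylab = ylab, ...)
  invisible(x)
}

#' CSV dialect for thermogram files
#'
#' Column mapping and unit declarations for delimited thermogram tables.
#' The bundled default reads the plain export convention used throughout
#' this package: columns `time_s`, `temperature_C` (or `temperature_K`),
#' and one of `heat_flow_mW`, `heat_flow_W_per_g`, `cp_J_per_gK`.
#' Heat flow is endothermic-up; a dialect for an exothermic-up instrument
#' sets `endo_up = FALSE` and the sign is flipped on read.
#'
#' @param time,temperature_C,temperature_K,heat_flow_mW,heat_flow_W_per_g,cp_J_per_gK
#'   column names in the file (set unused ones to `NULL`).
#' @param sep field separator.
#' @param endo_up logical; is the stored heat flow endothermic-up?
#' @return a list of class `dsc_dialect`.
#' @export
dsc_dialect <- function(time = "time_s",
                        temperature_C = "temperature_C",
                        temperature_K = "temperature_K",
                        heat_flow_mW = "heat_flow_mW",
                        heat_flow_W_per_g = "heat_flow_W_per_g",
                        cp_J_per_gK = "cp_J_per_gK",
                        sep = ",", endo_up = TRUE) {
  structure(list(time = time, temperature_C = temperature_C,
                 temperature_K = temperature_K, heat_flow_mW = heat_flow_mW,
                 heat_flow_W_per_g = heat_flow_W_per_g,
                 cp_J_per_gK = cp_J_per_gK, sep = sep, endo_up = endo_up),
            class = "dsc_dialect")
}

#' Read and write thermogram tables
#'
#' `read_dsc_curve()` reads a delimited text thermogram into canonical units
#' (K, s, per-gram signal). Absolute heat flow (mW) is divided by the sample
#' mass (mW / mg = W g^-1). `write_dsc_curve()` writes the canonical CSV
#' form (`time_s`, `temperature_K`, `cp_J_per_gK` or `heat_flow_W_per_g`),
#' which `read_dsc_curve()` reads back losslessly.
#'
#' @param path file path.
#' @param dialect a [dsc_dialect()].
#' @param mass_mg sample mass (mg); required when the file stores absolute
#'   heat flow.
#' @param sample_id,nominal_rate,Ta,t_a metadata passed to [dsc_curve()].
#' @return `read_dsc_curve()` returns a [dsc_curve()]; `write_dsc_curve()`
#'   returns `path` invisibly.
#' @export
read_dsc_curve <- function(path, dialect = dsc_dialect(), mass_mg = NA_real_,
                           sample_id = basename(path), nominal_rate = NA_real_,
                           Ta = NA_real_, t_a = NA_real_) {
  tab <- read.csv(path, sep = dialect$sep, check.names = FALSE)
  pick <- function(nm) if (!is.null(nm) && nm %in% names(tab)) tab[[nm]] else NULL
  time <- pick(dialect$time)
  if (is.null(time))
    stop_glassage(sprintf("missing time column '%s'", dialect$time),
                  "glassage_format_error")
  temp <- pick(dialect$temperature_K)
  if (is.null(temp)) {
    tc <- pick(dialect$temperature_C)
    if (is.null(tc))
      stop_glassage("missing temperature column", "glassage_format_error")
    temp <- celsius_to_kelvin(tc)
  }
  sgn <- if (isTRUE(dialect$endo_up)) 1 else -1
  if (!is.null(v <- pick(dialect$cp_J_per_gK))) {
    kind <- "specific_heat"; val <- v
  } else if (!is.null(v <- pick(dialect$heat_flow_W_per_g))) {
    kind <- "heat_flow_per_gram"; val <- sgn * v
  } else if (!is.null(v <- pick(dialect$heat_flow_mW))) {
    if (!is.finite(mass_mg) || mass_mg <= 0)
      stop_glassage("absolute heat flow (mW) requires a positive sample mass",
                    "glassage_format_error")
    kind <- "heat_flow_per_gram"; val <- sgn * v / mass_mg
  } else {
    stop_glassage("no recognised signal column", "glassage_format_error")
  }
  dsc_curve(time = time, temperature = temp, value = val, signal_kind = kind,
            sample_id = sample_id, mass_mg = mass_mg,
            nominal_rate = nominal_rate, Ta = Ta, t_a = t_a)
}

#' @rdname read_dsc_curve
#' @param curve a [dsc_curve()].
#' @export
write_dsc_curve <- function(curve, path) {
  stopifnot(inherits(curve, "dsc_curve"))
  col <- if (curve$signal_kind == "specific_heat") "cp_J_per_gK" else
    "heat_flow_W_per_g"
  tab <- data.frame(time_s = curve$time, temperature_K = curve$temperature,
                    v = curve$value)
  names(tab)[3] <- col
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert between heat flow and specific heat capacity
#'
#' On a constant-rate ramp, specific heat follows from per-gram heat flow as
#' Cp = Phi / |q| with q the scan rate in K s^-1; `to_heat_flow()` is the
#' exact inverse.
#'
#' @param curve a [dsc_curve()] recorded on a ramp (`nominal_rate != 0`).
#' @param rate optional rate override, signed K min^-1.
#' @return a [dsc_curve()] with the other `signal_kind`.
#' @examples
#' cv <- dsc_curve(c(0, 60), c(300, 310), c(0.1, 0.1),
#'                 "heat_flow_per_gram", nominal_rate = 10)
#' to_specific_heat(cv)$value  # 0.6 J/(g K)
#' @export
to_specific_heat <- function(curve, rate = NULL) {
  stopifnot(inherits(curve, "dsc_curve"))
  if (curve$signal_kind == "specific_heat") return(curve)
  q <- .rate_K_per_s(curve, rate)
  out <- curve
  out$value <- curve$value / q
  out$signal_kind <- "specific_heat"
  out
}

#' @rdname to_specific_heat
#' @export
to_heat_flow <- function(curve, rate = NULL) {
  stopifnot(inherits(curve, "dsc_curve"))
  if (curve$signal_kind == "heat_flow_per_gram") return(curve)
  q <- .rate_K_per_s(curve, rate)
  out <- curve
  out$value <- curve$value * q
  out$signal_kind <- "heat_flow_per_gram"
  out
}

.rate_K_per_s <- function(curve, rate) {
  r <- rate %||% curve$nominal_rate
  if (!is.finite(r) || r == 0)
    stop_glassage("conversion requires a non-zero scan rate",
                  "glassage_rate_error")
  abs(r) / 60
}

#' Split a thermogram record into protocol steps
#'
#' Assigns each sample of a continuous record to the segment of a thermal
#' program by elapsed time, and checks that the observed temperatures match
#' the programmed span within a tolerance (instrument lag).
#'
#' @param curve a [dsc_curve()] whose time axis starts at the program start.
#' @param program a [thermal_program()].
#' @param tol allowed temperature mismatch (K) between samples and their
#'   segment's programmed span.
#' @return a list with one element per segment containing `segment` and
#'   `curve` (a [dsc_curve()] of that segment's samples; `NULL` if a segment
#'   received fewer than 2 samples).
#' @export
segment_curve <- function(curve, program, tol = 2) {
  stopifnot(inherits(curve, "dsc_curve"), inherits(program, "thermal_program"))
  durs <- vapply(program$segments, function(s) s$duration * 60, 0)
  bounds <- cumsum(c(0, durs))
  t0 <- curve$time[1]
  if (tail(curve$time, 1) - t0 > tail(bounds, 1) + 1e-6)
    stop_glassage("record extends beyond the thermal program",
                  "glassage_segmentation_error")
  rel <- curve$time - t0
  idx <- findInterval(rel, bounds, rightmost.closed = TRUE,
                      left.open = TRUE)
  idx[rel <= bounds[1] + 1e-12] <- 1L
  out <- vector("list", length(program$segments))
  for (k in seq_along(program$segments)) {
    seg <- program$segments[[k]]
    sel <- which(idx == k)
    if (length(sel) < 2L) {
      out[[k]] <- list(segment = seg, curve = NULL)
      next
    }
    Tk <- curve$temperature[sel]
    lo <- min(seg$T_start, seg$T_end) - tol
    hi <- max(seg$T_start, seg$T_end) + tol
    if (any(Tk < lo | Tk > hi))
      stop_glassage(sprintf(
        "segment %d: observed temperatures outside programmed span (> %g K)",
        k, tol), "glassage_segmentation_error")
    out[[k]] <- list(segment = seg,
                     curve = dsc_curve(curve$time[sel], Tk, curve$value[sel],
                                       signal_kind = curve$signal_kind,
                                       sample_id = curve$sample_id,
                                       mass_mg = curve$mass_mg,
                                       nominal_rate = seg$rate,
                                       Ta = curve$Ta, t_a = curve$t_a))
  }
  out
}
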