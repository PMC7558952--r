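#' KWW stretched-exponential relaxation model
#'
#' The Kohlrausch-Williams-Watts description of isothermal enthalpy
#' relaxation,
#' \deqn{\Delta H_r(t) = \Delta H_r^\infty\,[1 - \exp\{-(t/\tau)^\beta\}],}
#' with relaxation time `tau`, stretching exponent `beta` in (0, 1]
#' (smaller beta = broader distribution of relaxation times) and plateau
#' `dHr_inf`, the equilibrium enthalpy relaxation. The complementary
#' recovery parameter is `phi(t) = exp(-(t/tau)^beta) = 1 - dHr/dHr_inf`.
#'
#' @param t ageing time (s), non-negative; vectorised.
#' @param tau relaxation time (s), positive.
#' @param beta stretching exponent in (0, 1].
#' @param dHr_inf equilibrium enthalpy relaxation (J g^-1), positive.
#' @return `kww_predict()` returns \eqn{\Delta H_r(t)} in J g^-1;
#'   `kww_recovery()` returns the dimensionless recovery parameter.
#' @examples
#' kww_recovery(32 * 3600, tau = 189 * 86400, beta = 0.277)  # ~0.78
#' kww_predict(28 * 3600, tau = 28 * 3600, beta = 0.327, dHr_inf = 7.92)
#' @export
kww_predict <- function(t, tau, beta, dHr_inf) {
  .check_kww_par(tau, beta)
  if (dHr_inf <= 0)
    stop_glassage("dHr_inf must be positive", "glassage_parameter_error")
  dHr_inf * (1 - kww_recovery(t, tau, beta))
}

#' @rdname kww_predict
#' @export
kww_recovery <- function(t, tau, beta) {
  .check_kww_par(tau, beta)
  if (any(t < 0))
    stop_glassage("time must be non-negative", "glassage_parameter_error")
  exp(-(t / tau)^beta)
}

.check_kww_par <- function(tau, beta) {
  if (!is.finite(tau) || tau <= 0)
    stop_glassage("tau must be positive", "glassage_parameter_error")
  if (!is.finite(beta) || beta <= 0 || beta > 1)
    stop_glassage("beta must lie in (0, 1]", "glassage_parameter_error")
}

#' Experimental recovery parameters from a measured series
#'
#' `phi_i = 1 - dHr_i / dHr_inf`, clipped into [0, 1] with a warning when a
#' measurement exceeds the supplied plateau.
#'
#' @param series a [relaxation_series()].
#' @param dHr_inf equilibrium enthalpy relaxation (J g^-1).
#' @return data frame with columns `t_a` (s) and `phi`.
#' @export
recovery_from_series <- function(series, dHr_inf) {
  stopifnot(inherits(series, "relaxation_series"))
  phi <- 1 - series$data$dHr / dHr_inf
  if (any(phi < 0)) {
    warning("observed dHr exceeds dHr_inf; recovery clipped to 0")
    phi <- pmax(phi, 0)
  }
  phi <- pmin(phi, 1)
  data.frame(t_a = series$data$t_a, phi = phi)
}

#' Fit the KWW model to an enthalpy-relaxation series
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt) in the
#' transformed parameters (log tau, logit beta, log dHr_inf), which keeps
#' the search well-conditioned when tau ranges from hours to years and
#' constrains beta to (0, 1). A deterministic multi-start over log-spaced
#' tau and several beta values guards against the flat valley that appears
#' when the data cover only the early power-law part of the decay. The
#' plateau can be fixed (from [equilibrium_relaxation()] or
#' `series$dHr_inf_fixed`) or fitted free (the default).
#'
#' @param series a [relaxation_series()] with at least 4 points (3 when the
#'   plateau is fixed).
#' @param dHr_inf optional fixed plateau (J g^-1); overrides the series'
#'   `dHr_inf_fixed`.
#' @param weights `"sd"` for 1/sd^2 weighting from the series (the default)
#'   or `"none"`.
#' @param n_starts number of extra log-spaced tau starting values.
#' @param control passed to [minpack.lm::nls.lm.control()] entries
#'   (`maxiter`, `ftol`, `ptol`).
#' @return an object of class `kww_fit` with components `par`
#'   (tau, beta, dHr_inf), `fixed`, `vcov`, `rss`, `n`, `series`,
#'   `fitted`, `residuals`, `converged`.
#' @examples
#' s <- simulate_kww_series(Ta = 358.15, times = c(0.5, 1, 2, 4, 8, 16, 24, 32) * 3600,
#'                          tau = 28 * 3600, beta = 0.327, dHr_inf = 7.92,
#'                          noise_sd = 0, seed = 1)
#' fit <- fit_kww(s)
#' coef(fit)
#' @export
fit_kww <- function(series, dHr_inf = NULL, weights = c("sd", "none"),
                    n_starts = 5,
                    control = list(maxiter = 1024, ftol = 1e-15, ptol = 1e-15)) {
  stopifnot(inherits(series, "relaxation_series"))
  weights <- match.arg(weights)
  fix_A <- dHr_inf %||% series$dHr_inf_fixed
  d <- series$data[series$data$t_a > 0, , drop = FALSE]
  n <- nrow(d)
  need <- if (is.null(fix_A)) 4L else 3L
  if (n < need)
    stop_glassage(sprintf("need at least %d positive-time points", need),
                  "glassage_fit_error")
  t <- d$t_a; y <- d$dHr
  w <- if (weights == "sd" && all(is.finite(d$sd)) && all(d$sd > 0))
    1 / d$sd^2 else rep(1, n)
  sw <- sqrt(w)

  free_A <- is.null(fix_A)
  model_tr <- function(p) {
    tau <- exp(p[1]); beta <- plogis(p[2])
    A <- if (free_A) exp(p[3]) else fix_A
    A * (1 - exp(-(t / tau)^beta))
  }
  resid_tr <- function(p) sw * (y - model_tr(p))

  # initial values: plateau 1.2 x max, tau where dHr first crosses half of it
  A0 <- if (free_A) 1.2 * max(y) else fix_A
  half <- A0 / 2
  tau0 <- if (any(y >= half)) {
    k <- which(y >= half)[1]
    if (k == 1L) t[1] else
      exp(approx(y[(k - 1):k], log(t[(k - 1):k]), xout = half)$y)
  } else max(t) * (half / max(y))^2  # crude power-law extrapolation
  tau_grid <- unique(c(tau0, exp(seq(log(min(t)), log(max(t) * 1e3),
                                     length.out = n_starts))))
  beta_grid <- c(0.3, 0.5, 0.8)

  ctrl <- minpack.lm::nls.lm.control(maxiter = control$maxiter %||% 1024,
                                     ftol = control$ftol %||% 1e-15,
                                     ptol = control$ptol %||% 1e-15)
  best <- NULL
  for (tg in tau_grid) for (bg in beta_grid) {
    p0 <- c(log(tg), qlogis(bg))
    if (free_A) p0 <- c(p0, log(A0))
    f <- tryCatch(minpack.lm::nls.lm(p0, fn = resid_tr, control = ctrl),
                  error = function(e) NULL)
    if (is.null(f)) next
    if (is.null(best) || f$deviance < best$deviance) best <- f
  }
  if (is.null(best))
    stop_glassage("KWW fit failed to converge from any start",
                  "glassage_fit_error")

  p <- best$par
  tau_hat <- exp(p[1]); beta_hat <- plogis(p[2])
  A_hat <- if (free_A) exp(p[3]) else fix_A
  par <- c(tau = tau_hat, beta = beta_hat, dHr_inf = A_hat)
  fitted_y <- kww_predict(t, tau_hat, beta_hat, A_hat)
  rss <- sum(w * (y - fitted_y)^2)

  # covariance in natural parameters from the Jacobian at the optimum
  free_names <- c("tau", "beta", if (free_A) "dHr_inf")
  J <- .kww_jacobian(t, tau_hat, beta_hat, A_hat)[, free_names, drop = FALSE]
  p_free <- length(free_names)
  V <- matrix(NA_real_, p_free, p_free,
              dimnames = list(free_names, free_names))
  if (n > p_free) {
    sigma2 <- rss / (n - p_free)
    JtWJ <- crossprod(J * sw)
    Vtry <- tryCatch(sigma2 * solve(JtWJ), error = function(e) NULL)
    if (is.null(Vtry)) {
      # near-singular Jacobian (strongly correlated parameters): fall back
      # to the Moore-Penrose pseudoinverse so diagnostics stay available
      sv <- svd(JtWJ)
      pos <- sv$d > max(sv$d) * 1e-12
      Vtry <- sigma2 * (sv$v[, pos, drop = FALSE] %*%
                          (t(sv$u[, pos, drop = FALSE]) / sv$d[pos]))
      dimnames(Vtry) <- dimnames(V)
    }
    V <- Vtry
  }

  structure(list(par = par, fixed = c(tau = FALSE, beta = FALSE,
                                      dHr_inf = !free_A),
                 vcov = V, rss = rss, n = n, series = series,
                 weights = w, fitted = fitted_y, residuals = y - fitted_y,
                 converged = best$info %in% 1:4,
                 info = best$info, message = best$message),
            class = "kww_fit")
}

# analytic partials of A(1 - exp(-(t/tau)^beta)) wrt (tau, beta, A)
.kww_jacobian <- function(t, tau, beta, A) {
  u <- (t / tau)^beta
  e <- exp(-u)
  cbind(tau = -A * e * u * beta / tau,
        beta = A * e * u * log(t / tau),
        dHr_inf = 1 - e)
}

#' @export
print.kww_fit <- function(x, digits = 4, ...) {
  cat("KWW stretched-exponential fit\n")
  tau <- x$par["tau"]
  tau_str <- if (tau >= 172800) sprintf("%.3g days", tau / 86400)
             else sprintf("%.3g h", tau / 3600)
  cat(sprintf("  tau     = %s (%.6g s)%s\n", tau_str, tau,
              if (x$fixed["tau"]) " [fixed]" else ""))
  cat(sprintf("  beta    = %.*g%s\n", digits, x$par["beta"],
              if (x$fixed["beta"]) " [fixed]" else ""))
  cat(sprintf("  dHr_inf = %.*g J/g%s\n", digits, x$par["dHr_inf"],
              if (x$fixed["dHr_inf"]) " [fixed]" else ""))
  cat(sprintf("  n = %d, weighted RSS = %.3g%s\n", x$n, x$rss,
              if (!x$converged) "  (WARNING: not converged)" else ""))
  invisible(x)
}

#' @export
summary.kww_fit <- function(object, ...) {
  free <- names(object$par)[!object$fixed]
  se <- rep(NA_real_, length(free))
  if (!anyNA(object$vcov)) se <- sqrt(pmax(diag(object$vcov), 0))
  tab <- data.frame(estimate = object$par[free], std_error = se,
                    row.names = free)
  out <- list(coefficients = tab, fixed = object$par[object$fixed],
              rss = object$rss, n = object$n, converged = object$converged)
  class(out) <- "summary.kww_fit"
  out
}

#' @export
print.summary.kww_fit <- function(x, ...) {
  cat("KWW fit summary\n")
  print(x$coefficients)
  if (length(x$fixed))
    cat("fixed:", paste(names(x$fixed), signif(x$fixed, 4),
                        sep = " = ", collapse = ", "), "\n")
  cat(sprintf("weighted RSS %.4g on %d points\n", x$rss, x$n))
  invisible(x)
}

#' @export
coef.kww_fit <- function(object, ...) object$par

#' @export
vcov.kww_fit <- function(object, ...) object$vcov

#' @export
fitted.kww_fit <- function(object, ...) object$fitted

#' @export
residuals.kww_fit <- function(object, ...) object$residuals

#' @export
deviance.kww_fit <- function(object, ...) object$rss

#' @export
predict.kww_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$series$data$t_a
       else if (is.data.frame(newdata)) newdata$t_a else newdata
  p <- unname(object$par)
  kww_predict(t, p[1], p[2], p[3])
}

#' @export
plot.kww_fit <- function(x, n_grid = 100, ...) {
  d <- x$series$data
  tg <- exp(seq(log(min(d$t_a[d$t_a > 0])), log(max(d$t_a)),
                length.out = n_grid))
  plot(d$t_a / 3600, d$dHr, log = "x", xlab = "Ageing time (h)",
       ylab = expression(Delta * H[r] ~ (J ~ g^-1)), ...)
  lines(tg / 3600, predict(x, tg))
  invisible(x)
}

#' Simulate new series from a fitted KWW model
#'
#' Draws Gaussian noise around the fitted curve at the observed ageing
#' times, using the series' per-point standard deviations.
#'
#' @param object a [fit_kww()] result.
#' @param nsim number of simulated series.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of [relaxation_series()] objects.
#' @export
simulate.kww_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$series$data
  mu <- predict(object)
  lapply(seq_len(nsim), function(i)
    relaxation_series(object$series$Ta, d$t_a,
                      pmax(mu + rnorm(nrow(d), 0, d$sd), -0.3), sd = d$sd))
}

#' Fictive temperature along an ageing series
#'
#' Linearised mapping from recovered enthalpy to fictive temperature:
#' `Tf(t) = Tg - dHr(t) / delta_cp`. At `dHr = 0` the glass has
#' `Tf = Tg`; at full relaxation, `dHr = delta_cp (Tg - Ta)`, it reaches
#' the ageing temperature.
#'
#' @param series a [relaxation_series()].
#' @param Tg glass transition temperature (K).
#' @param dcp heat-capacity step (J g^-1 K^-1), positive.
#' @return data frame with columns `t_a` (s) and `Tf` (K).
#' @export
fictive_vs_time <- function(series, Tg, dcp) {
  stopifnot(inherits(series, "relaxation_series"))
  if (dcp <= 0)
    stop_glassage("delta Cp must be positive", "glassage_parameter_error")
  data.frame(t_a = series$data$t_a, Tf = Tg - series$data$dHr / dcp)
}
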