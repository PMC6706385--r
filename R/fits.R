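#' Fit a Boltzmann function to a gating curve
#'
#' Fits \eqn{y = 1 / [1 + \exp((V_h - V)/k)]} by nonlinear least
#' squares. A single signed-k form covers both curve types: positive k
#' gives a rising (activation) curve, negative k a falling
#' (inactivation) curve, matching the sign convention in which
#' inactivation slope factors are reported negative.
#'
#' Initialization: \eqn{V_h} from the half-maximum crossing of the
#' data, \eqn{k} from the 10--90\% rise span (\eqn{span/\ln 81}), with
#' the sign taken from the observed direction; bounds
#' \eqn{|V_h| \le 200} mV, \eqn{0.1 \le |k| \le 50} mV.
#'
#' @param voltage membrane potentials (mV)
#' @param response normalized responses in [0, 1] (G/Gmax or I/Imax)
#' @param form "activation" or "inactivation" (recorded on the fit and
#'   used to orient the slope initialization)
#' @return an object of class \code{boltzmann_fit} with elements
#'   \code{vh}, \code{k}, \code{form}, \code{se} (standard errors),
#'   \code{resid_norm}, \code{data}
#' @export
fit_boltzmann <- function(voltage, response,
                          form = c("activation", "inactivation")) {
  form <- match.arg(form)
  voltage <- unname(as.numeric(voltage))
  response <- unname(as.numeric(response))
  stopifnot(length(voltage) == length(response), length(voltage) >= 6L)
  if (diff(range(response)) < 1e-3) stop("flat data: no transition to fit")
  o <- order(voltage)
  v <- voltage[o]
  y <- response[o]
  rising <- stats::cor(v, y) >= 0
  # half-maximum crossing
  yr <- (y - min(y)) / (max(y) - min(y))
  cross <- if (rising) which(yr >= 0.5)[1L] else which(yr <= 0.5)[1L]
  vh0 <- if (is.na(cross) || cross == 1L) stats::median(v) else {
    approx_v(v, yr, cross, 0.5)
  }
  # 10-90% span -> |k| = span / ln(81)
  q10v <- quant_cross(v, yr, if (rising) 0.1 else 0.9, rising)
  q90v <- quant_cross(v, yr, if (rising) 0.9 else 0.1, rising)
  k0 <- abs(q90v - q10v) / log(81)
  k0 <- min(max(k0, 0.5), 49)
  if (!rising) k0 <- -k0
  fit <- minpack.lm::nlsLM(
    y ~ 1 / (1 + exp((vh - v) / k)),
    start = list(vh = vh0, k = k0),
    lower = c(vh = -200, k = if (rising) 0.1 else -50),
    upper = c(vh = 200, k = if (rising) 50 else -0.1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
  structure(list(vh = unname(cf["vh"]), k = unname(cf["k"]), form = form,
                 se = c(vh = unname(se[1L]), k = unname(se[2L])),
                 resid_norm = sqrt(sum(stats::resid(fit)^2)),
                 data = data.frame(voltage = v, response = y)),
            class = "boltzmann_fit")
}

approx_v <- function(v, yr, i, level) {
  if (i == 1L) return(v[1L])
  v[i - 1L] + (level - yr[i - 1L]) / (yr[i] - yr[i - 1L]) * (v[i] - v[i - 1L])
}

quant_cross <- function(v, yr, level, rising = TRUE) {
  i <- if (rising) which(yr >= level)[1L] else which(yr <= level)[1L]
  if (is.na(i)) return(v[length(v)])
  approx_v(v, yr, i, level)
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann %s fit: Vh = %.2f mV (se %.2g), k = %.2f mV (se %.2g)\n",
              x$form, x$vh, x$se["vh"], x$k, x$se["k"]))
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(vh = object$vh, k = object$k)
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$data$voltage else {
    if (is.list(newdata)) newdata$voltage else newdata
  }
  1 / (1 + exp((object$vh - v) / object$k))
}

#' @export
plot.boltzmann_fit <- function(x, ...) {
  plot(x$data$voltage, x$data$response, xlab = "V (mV)",
       ylab = "normalized response", ...)
  vg <- seq(min(x$data$voltage), max(x$data$voltage), length.out = 200)
  graphics::lines(vg, predict(x, vg))
  invisible(x)
}

#' Fit recovery from inactivation
#'
#' Fits the offset-free rising mono-exponential
#' \eqn{f(t) = 1 - \exp(-t/\tau)} to fraction-recovered data (second
#' pulse peak over first pulse peak versus gap duration). The curve is
#' constrained through (0, 0), consistent with reporting a single
#' recovery time constant.
#'
#' @param gap gap durations at the recovery voltage (ms)
#' @param fraction fraction recovered, in [0, 1.05]
#' @param v_recovery recovery voltage (mV), metadata
#' @param temperature temperature (degrees C), metadata
#' @return object of class \code{recovery_fit} with \code{tau} (ms)
#' @export
fit_recovery <- function(gap, fraction, v_recovery = NA_real_,
                         temperature = NA_real_) {
  gap <- unname(as.numeric(gap))
  fraction <- unname(as.numeric(fraction))
  stopifnot(length(gap) == length(fraction), length(gap) >= 6L,
            all(gap > 0))
  if (any(fraction < 0 | fraction > 1.05)) {
    stop("fraction recovered outside [0, 1.05]")
  }
  # log-linear initialization on 1 - f
  pos <- fraction < 1
  tau0 <- if (sum(pos) >= 2L) {
    -1 / stats::coef(stats::lm(log(1 - fraction[pos]) ~ gap[pos] - 1))[[1L]]
  } else max(gap) / 5
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(gap) / 5
  fit <- tryCatch(
    minpack.lm::nlsLM(fraction ~ 1 - exp(-gap / tau),
                      start = list(tau = tau0),
                      lower = c(tau = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    tau <- unname(stats::coef(fit)["tau"])
    se <- tryCatch(sqrt(diag(stats::vcov(fit)))[[1L]],
                   error = function(e) NA_real_)
  } else {
    # one-parameter golden-section fallback for near-saturated data,
    # where the Jacobian of the nls formulation degenerates
    ssr <- function(tau) sum((fraction - (1 - exp(-gap / tau)))^2)
    tau <- stats::optimize(ssr, c(1e-4, 10 * max(gap)))$minimum
    se <- NA_real_
  }
  structure(list(tau = tau, se = se,
                 v_recovery = v_recovery, temperature = temperature,
                 data = data.frame(gap = gap, fraction = fraction)),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf("recovery fit: tau = %.3f ms (Vr = %g mV, T = %g C)\n",
              x$tau, x$v_recovery, x$temperature))
  invisible(x)
}

#' @export
coef.recovery_fit <- function(object, ...) c(tau = object$tau)

#' @export
predict.recovery_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$gap else {
    if (is.list(newdata)) newdata$gap else newdata
  }
  1 - exp(-t / object$tau)
}

#' Fit the prepulse-duration decay of resurgent current
#'
#' The normalized resurgent peak decays with lengthening of the
#' depolarizing prepulse toward a residual plateau:
#' \eqn{R(t) = (1 - f_0) \exp(-t/\tau) + f_0}, with residual fraction
#' \eqn{f_0} and time constant \eqn{\tau}.
#'
#' @param duration prepulse durations (ms)
#' @param amplitude normalized resurgent peak amplitudes
#' @return object of class \code{prepulse_decay_fit} with \code{tau}
#'   (ms) and \code{f0}; if the data are flat, \code{tau} is NA and the
#'   fit is flagged \code{degenerate}
#' @export
fit_prepulse_decay <- function(duration, amplitude) {
  duration <- unname(as.numeric(duration))
  amplitude <- unname(as.numeric(amplitude))
  stopifnot(length(duration) == length(amplitude), length(duration) >= 5L)
  if (diff(range(amplitude)) < 1e-3) {
    return(structure(list(tau = NA_real_, f0 = mean(amplitude),
                          degenerate = TRUE,
                          data = data.frame(duration = duration,
                                            amplitude = amplitude)),
                     class = "prepulse_decay_fit"))
  }
  f00 <- min(amplitude)
  amp0 <- max(amplitude) - f00
  dec <- amplitude > f00 + 0.05 * amp0
  tau0 <- if (sum(dec) >= 2L) {
    -1 / stats::coef(stats::lm(log((amplitude[dec] - f00) / amp0)
                               ~ duration[dec] - 1))[[1L]]
  } else stats::median(duration)
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- stats::median(duration)
  fit <- minpack.lm::nlsLM(
    amplitude ~ (1 - f0) * exp(-duration / tau) + f0,
    start = list(tau = tau0, f0 = max(f00, 1e-3)),
    lower = c(tau = 1e-6, f0 = 0), upper = c(tau = Inf, f0 = 1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(tau = unname(cf["tau"]), f0 = unname(cf["f0"]),
                 degenerate = FALSE,
                 data = data.frame(duration = duration,
                                   amplitude = amplitude)),
            class = "prepulse_decay_fit")
}

#' @export
print.prepulse_decay_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("prepulse decay fit: flat data, f0 = %.3f, tau unidentifiable\n",
                x$f0))
  } else {
    cat(sprintf("prepulse decay fit: tau = %.2f ms, f0 = %.3f\n", x$tau, x$f0))
  }
  invisible(x)
}

#' @export
coef.prepulse_decay_fit <- function(object, ...) {
  c(tau = object$tau, f0 = object$f0)
}

#' Regression of resurgent decay rate on voltage
#'
#' The inverse decay time constants of the resurgent current follow
#' \eqn{1/\tau(V) = A \exp(k V / 25)} (ms^-1); the fit is a linear
#' regression of \eqn{\ln(1/\tau)} on \eqn{V/25}.
#'
#' @param voltage repolarization voltages (mV)
#' @param tau decay time constants (ms), > 0
#' @return object of class \code{decay_voltage_fit} with \code{A}
#'   (ms^-1) and \code{k} (dimensionless)
#' @export
fit_decay_voltage_regression <- function(voltage, tau) {
  voltage <- unname(as.numeric(voltage))
  tau <- unname(as.numeric(tau))
  stopifnot(length(voltage) == length(tau), length(voltage) >= 3L)
  if (any(tau <= 0)) stop("decay time constants must be positive")
  lm <- stats::lm(log(1 / tau) ~ I(voltage / 25))
  cf <- stats::coef(lm)
  structure(list(A = unname(exp(cf[1L])), k = unname(cf[2L]),
                 r_squared = summary(lm)$r.squared,
                 data = data.frame(voltage = voltage, tau = tau)),
            class = "decay_voltage_fit")
}

#' @export
print.decay_voltage_fit <- function(x, ...) {
  cat(sprintf("decay-voltage regression: 1/tau = %.4g * exp(%.3f * V/25) ms^-1 (R2 %.3f)\n",
              x$A, x$k, x$r_squared))
  invisible(x)
}

#' @export
coef.decay_voltage_fit <- function(object, ...) {
  c(A = object$A, k = object$k)
}

#' @export
predict.decay_voltage_fit <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$data$voltage else {
    if (is.list(newdata)) newdata$voltage else newdata
  }
  object$A * exp(object$k * v / 25)
}
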