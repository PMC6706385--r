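#' Current-voltage analysis of an activation sweep family
#'
#' Extracts the peak inward current of every sweep, regresses peak
#' current on test voltage over the +10..+40 mV range (where the
#' channels are fully activated and the I-V relation is Ohmic), and
#' reports the sodium reversal potential V_Na as the x-intercept and
#' the maximal conductance G_max as the slope. Normalized conductance
#' is I_peak / [(V - V_Na) G_max].
#'
#' @param traces list of \code{current_trace} objects from the
#'   activation protocol (sweep values = test voltages)
#' @param fit_range voltage range (mV) of the reversal-potential
#'   regression
#' @return object of class \code{iv_analysis}: data.frame of
#'   \code{voltage}, \code{peak}, \code{g_norm} plus \code{v_na} and
#'   \code{g_max}
#' @export
analyze_iv <- function(traces, fit_range = c(10, 40)) {
  v <- vapply(traces, function(tr) attr(tr, "sweep_value"), numeric(1L))
  peak <- vapply(traces, trace_peak, numeric(1L))
  sel <- v >= fit_range[1L] & v <= fit_range[2L]
  if (sum(sel) < 3L) stop("need at least 3 sweeps in the regression range")
  lm <- stats::lm(peak[sel] ~ v[sel])
  slope <- stats::coef(lm)[[2L]]
  if (slope <= 0) stop("degenerate I-V regression: non-positive slope")
  v_na <- -stats::coef(lm)[[1L]] / slope
  g <- peak / ((v - v_na) * slope)
  structure(list(table = data.frame(voltage = v, peak = peak, g_norm = g),
                 v_na = v_na, g_max = slope),
            class = "iv_analysis")
}

#' @export
print.iv_analysis <- function(x, ...) {
  cat(sprintf("I-V analysis: %d sweeps, V_Na = %.2f mV, G_max = %.4g\n",
              nrow(x$table), x$v_na, x$g_max))
  invisible(x)
}

# signed peak current of largest magnitude (inward currents negative)
trace_peak <- function(trace, from = -Inf, to = Inf) {
  i <- trace$time >= from & trace$time <= to
  cur <- trace$current[i]
  cur[which.max(abs(cur))]
}

#' Smooth the current of a trace by a moving average
#'
#' Peak-based metrics (transient peak, resurgent peak) read single
#' samples and are therefore biased upward on noisy recordings; a short
#' boxcar average restores them. Segment boundaries are not treated
#' specially, so keep the window well below the shortest kinetic
#' feature of interest.
#'
#' @param trace a \code{current_trace}
#' @param width_ms averaging window (ms)
#' @return the trace with smoothed \code{current}
#' @export
smooth_trace <- function(trace, width_ms = 0.5) {
  dt <- attr(trace, "dt")
  w <- max(1L, round(width_ms / dt))
  if (w %% 2L == 0L) w <- w + 1L
  k <- rep(1 / w, w)
  cur <- stats::filter(trace$current, k, sides = 2L)
  # shrink the window at the edges instead of dropping samples
  na <- which(is.na(cur))
  for (i in na) {
    lo <- max(1L, i - (w %/% 2L))
    hi <- min(length(trace$current), i + (w %/% 2L))
    cur[i] <- mean(trace$current[lo:hi])
  }
  trace$current <- as.numeric(cur)
  trace
}

#' Window current from activation and inactivation fits
#'
#' The steady-state window current is approximated by the product of
#' the activation and inactivation Boltzmann curves on a voltage grid.
#' The area is computed by trapezoidal integration over the grid
#' (default 0.1 mV spacing on [-120, +20] mV) and spot values are
#' reported at -20, -40, -60 and -80 mV.
#'
#' @param act activation [fit_boltzmann()] (rising, k > 0)
#' @param inact inactivation [fit_boltzmann()] (falling, k < 0)
#' @param grid voltage grid (mV)
#' @param spots voltages at which spot products are reported
#' @return object of class \code{window_curve} with \code{grid},
#'   \code{product}, \code{area} (mV, dimensionless product integrated
#'   over voltage) and \code{spots}
#' @export
window_curve <- function(act, inact, grid = seq(-120, 20, by = 0.1),
                         spots = c(-20, -40, -60, -80)) {
  stopifnot(inherits(act, "boltzmann_fit"), inherits(inact, "boltzmann_fit"))
  prod <- predict(act, grid) * predict(inact, grid)
  area <- trapezoid(grid, prod)
  sv <- predict(act, spots) * predict(inact, spots)
  structure(list(grid = grid, product = prod, area = area,
                 spots = stats::setNames(sv, paste0(spots, "mV"))),
            class = "window_curve")
}

trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' @export
print.window_curve <- function(x, ...) {
  cat(sprintf("window curve: area = %.4g mV; spots: %s\n", x$area,
              paste(sprintf("%s %.3g", names(x$spots), x$spots),
                    collapse = ", ")))
  invisible(x)
}

#' Sustained-to-peak current ratio of a depolarizing sweep
#'
#' Ratio of the average current in the 90-95 ms window of the pulse to
#' the peak transient current of the same sweep. Both are taken as
#' magnitudes of the inward current.
#'
#' @param trace a \code{current_trace} of at least 95 ms
#' @param window time window (ms) for the sustained average
#' @return dimensionless ratio
#' @export
sustained_ratio <- function(trace, window = c(90, 95)) {
  stopifnot(max(trace$time) >= window[2L])
  peak <- trace_peak(trace)
  if (peak == 0) stop("zero peak current")
  i <- trace$time >= window[1L] & trace$time <= window[2L]
  mean(trace$current[i]) / peak
}

#' Resurgent current metrics
#'
#' For each repolarization sweep of the resurgent protocol, locates the
#' resurgent peak after the end of the depolarizing prepulse, and
#' reports: peak amplitude, peak normalized to the transient peak of
#' the reference sweep (I_resurgent/I_transient), time to peak measured
#' from the prepulse end, decay time constant from a mono-exponential
#' fit (with offset) from the peak to the end of the repolarization,
#' and resurgent charge (integrated current from prepulse end to sweep
#' end) relative to the transient charge of the reference sweep.
#'
#' The first samples after the repolarization step are dominated by the
#' instantaneous tail current through still-open channels; the search
#' for the delayed resurgent peak therefore starts after the tail has
#' collapsed (first local minimum of the current magnitude).
#'
#' @param traces list of \code{current_trace} objects from the
#'   resurgent protocol
#' @param reference a \code{current_trace} providing the transient peak
#'   and charge of the same simulated cell (conventionally the
#'   activation sweep at the I-V peak voltage, -20 mV)
#' @return object of class \code{resurgent_metrics}: data.frame with
#'   one row per repolarization voltage (\code{voltage},
#'   \code{peak}, \code{ratio}, \code{time_to_peak}, \code{tau_decay},
#'   \code{charge_ratio}, \code{monotone})
#' @export
resurgent_metrics <- function(traces, reference) {
  ref_peak <- trace_peak(reference)
  if (ref_peak == 0) stop("reference transient peak is zero")
  ref_charge <- charge_of(reference, 0, max(reference$time))
  rows <- lapply(traces, function(tr) {
    segs <- attr(tr, "segments")
    t_end_pre <- segs$duration[1L]
    v_rep <- segs$level[2L]
    i <- which(tr$time > t_end_pre)
    tt <- tr$time[i] - t_end_pre
    cur <- abs(tr$current[i])
    # skip the instantaneous tail: start at the first local minimum
    dmin <- which(diff(cur) > 0)[1L]
    start <- if (is.na(dmin)) 1L else dmin
    ipk <- start - 1L + which.max(cur[start:length(cur)])
    monotone <- is.na(dmin) || ipk <= start
    peak <- cur[ipk]
    ttp <- if (monotone) NA_real_ else tt[ipk]
    tau <- if (monotone) NA_real_ else {
      fit_exp_decay(tt[ipk:length(tt)] - tt[ipk], cur[ipk:length(cur)])
    }
    q <- charge_of(tr, t_end_pre, max(tr$time))
    data.frame(voltage = v_rep, peak = peak,
               ratio = peak / abs(ref_peak),
               time_to_peak = ttp, tau_decay = tau,
               charge_ratio = q / ref_charge, monotone = monotone)
  })
  structure(list(table = do.call(rbind, rows),
                 ref_peak = abs(ref_peak), ref_charge = ref_charge),
            class = "resurgent_metrics")
}

charge_of <- function(trace, from, to) {
  i <- trace$time >= from & trace$time <= to
  abs(trapezoid(trace$time[i], trace$current[i]))
}

# mono-exponential-with-offset decay fit; returns tau (ms)
fit_exp_decay <- function(t, y) {
  c0 <- min(y)
  a0 <- max(y[1L] - c0, 1e-12)
  dec <- y > c0 + 0.05 * a0
  tau0 <- if (sum(dec) >= 2L) {
    -1 / stats::coef(stats::lm(log((y[dec] - c0 + 1e-15) / a0) ~ t[dec] - 1))[[1L]]
  } else max(t) / 3
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(t) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-t / tau) + c,
                      start = list(a = a0, tau = tau0, c = c0),
                      lower = c(a = 0, tau = 1e-9, c = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  unname(stats::coef(fit)["tau"])
}

#' @export
print.resurgent_metrics <- function(x, ...) {
  cat("resurgent metrics:\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fraction recovered from a paired-pulse family
#'
#' Peak of the second pulse divided by the peak of the first pulse,
#' per gap duration of the recovery protocol.
#'
#' @param traces list of \code{current_trace} objects from the recovery
#'   protocol
#' @return data.frame with \code{gap} (ms) and \code{fraction}
#' @export
recovery_fractions <- function(traces) {
  rows <- lapply(traces, function(tr) {
    segs <- attr(tr, "segments")
    t1 <- segs$duration[1L]
    t2 <- t1 + segs$duration[2L]
    p1 <- trace_peak(tr, 0, t1)
    p2 <- trace_peak(tr, t2, max(tr$time))
    data.frame(gap = segs$duration[2L], fraction = abs(p2) / abs(p1))
  })
  do.call(rbind, rows)
}

#' Ratio of a mutant metric to the wild-type metric
#'
#' The mutant-over-WT quotient used to compare relative resurgent
#' currents at matched temperature, e.g. 0.12 / 0.071 = 1.69.
#'
#' @param mutant mutant value (dimensionless)
#' @param wt wild-type value, > 0
#' @return quotient
#' @export
ratio_to_wt <- function(mutant, wt) {
  if (any(wt <= 0)) stop("wild-type reference must be positive")
  mutant / wt
}
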