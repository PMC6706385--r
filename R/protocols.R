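#' Standard voltage-clamp protocols
#'
#' Builds the voltage-clamp protocols of the whole-cell characterization
#' battery as data. Each protocol is a holding potential plus a family
#' of piecewise-constant sweep templates generated by one sweep-varying
#' parameter:
#'
#' \describe{
#'   \item{activation_iv}{hold -120 mV; 100 ms test steps from -160 to
#'     +40 mV in 5 mV increments (41 sweeps); inter-sweep interval 1.5 s.}
#'   \item{inactivation}{hold -120 mV; 100 ms prepulse from -160 to
#'     +20 mV in 10 mV increments, then a 100 ms test step to +10 mV.}
#'   \item{resurgent}{hold -120 mV; +40 mV x 10 ms prepulse, then a
#'     100 ms repolarization to -20, -30, -40, -50 or -60 mV.}
#'   \item{recovery}{hold -120 mV; paired +20 mV x 10 ms pulses
#'     separated by a gap at the recovery voltage (default -80 mV),
#'     gap growing from 0.1 ms in 0.1 ms increments; every 1.5 s.}
#'   \item{prepulse_duration}{hold -120 mV; +60 mV prepulse of growing
#'     duration, then a fixed repolarization test to -40 mV.}
#' }
#'
#' @param kind protocol kind (see Details)
#' @param ... overrides; recognized names depend on kind:
#'   \code{holding}, \code{increment}, \code{v_min}, \code{v_max},
#'   \code{test_duration}, \code{levels} (resurgent), \code{v_recovery},
#'   \code{max_gap}, \code{gap_increment}, \code{gaps} (explicit gap
#'   vector, recovery), \code{pulse_level}, \code{pulse_duration},
#'   \code{prepulse_level}, \code{durations} (prepulse_duration),
#'   \code{interval}
#' @return an object of class \code{sweep_protocol}: list with
#'   \code{name}, \code{holding} (mV), \code{sweeps} (list of segment
#'   data.frames), \code{sweep_var} (name + values), \code{interval}
#'   (ms)
#' @export
make_protocol <- function(kind = c("activation_iv", "inactivation",
                                   "resurgent", "recovery",
                                   "prepulse_duration"), ...) {
  kind <- match.arg(kind)
  ov <- list(...)
  get <- function(name, default) if (!is.null(ov[[name]])) ov[[name]] else default
  holding <- get("holding", -120)
  interval <- get("interval", 1500)

  if (kind == "activation_iv") {
    inc <- get("increment", 5)
    vals <- seq(get("v_min", -160), get("v_max", 40), by = inc)
    dur <- get("test_duration", 100)
    sweeps <- lapply(vals, function(v) data.frame(level = v, duration = dur))
    var <- list(name = "test_mV", values = vals)
  } else if (kind == "inactivation") {
    inc <- get("increment", 10)
    vals <- seq(get("v_min", -160), get("v_max", 20), by = inc)
    predur <- get("prepulse_duration", 100)
    test <- get("test_level", 10)
    dur <- get("test_duration", 100)
    sweeps <- lapply(vals, function(v) {
      data.frame(level = c(v, test), duration = c(predur, dur))
    })
    var <- list(name = "prepulse_mV", values = vals)
  } else if (kind == "resurgent") {
    vals <- get("levels", c(-20, -30, -40, -50, -60))
    pre <- get("prepulse_level", 40)
    predur <- get("prepulse_duration", 10)
    dur <- get("test_duration", 100)
    sweeps <- lapply(vals, function(v) {
      data.frame(level = c(pre, v), duration = c(predur, dur))
    })
    var <- list(name = "repolarization_mV", values = vals)
  } else if (kind == "recovery") {
    vr <- get("v_recovery", -80)
    pl <- get("pulse_level", 20)
    pd <- get("pulse_duration", 10)
    gaps <- get("gaps", seq(get("gap_increment", 0.1),
                            get("max_gap", 100),
                            by = get("gap_increment", 0.1)))
    stopifnot(all(gaps > 0))
    sweeps <- lapply(gaps, function(g) {
      data.frame(level = c(pl, vr, pl), duration = c(pd, g, pd))
    })
    var <- list(name = "gap_ms", values = gaps)
    attr(var, "v_recovery") <- vr
  } else {                              # prepulse_duration
    durs <- get("durations", c(2, 5, 10, 20, 50, 100, 200, 500))
    pre <- get("prepulse_level", 60)
    test <- get("test_level", -40)
    dur <- get("test_duration", 100)
    sweeps <- lapply(durs, function(d) {
      data.frame(level = c(pre, test), duration = c(d, dur))
    })
    var <- list(name = "prepulse_ms", values = durs)
  }
  stopifnot(length(sweeps) >= 1L)
  structure(list(name = kind, holding = holding, sweeps = sweeps,
                 sweep_var = var, interval = interval),
            class = "sweep_protocol")
}

#' @export
print.sweep_protocol <- function(x, ...) {
  cat(sprintf("protocol '%s': hold %g mV, %d sweeps (%s: %g..%g), interval %g ms\n",
              x$name, x$holding, length(x$sweeps), x$sweep_var$name,
              min(x$sweep_var$values), max(x$sweep_var$values), x$interval))
  invisible(x)
}

#' Serialize a protocol to / from YAML
#'
#' Round-trips the sweep layout exactly: name, holding potential,
#' sweep-varying parameter and every segment of every sweep.
#'
#' @param protocol a [make_protocol()] object
#' @param path file path
#' @export
write_protocol <- function(protocol, path) {
  doc <- list(name = protocol$name, holding = protocol$holding,
              interval = protocol$interval,
              sweep_var = list(name = protocol$sweep_var$name,
                               values = as.list(protocol$sweep_var$values)),
              sweeps = lapply(protocol$sweeps, function(s) {
                list(level = as.list(s$level),
                     duration = as.list(s$duration))
              }))
  vr <- attr(protocol$sweep_var, "v_recovery")
  if (!is.null(vr)) doc$v_recovery <- vr
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  doc <- yaml::read_yaml(path)
  var <- list(name = doc$sweep_var$name,
              values = as.numeric(unlist(doc$sweep_var$values)))
  if (!is.null(doc$v_recovery)) attr(var, "v_recovery") <- doc$v_recovery
  structure(list(name = doc$name, holding = doc$holding,
                 sweeps = lapply(doc$sweeps, function(s) {
                   data.frame(level = as.numeric(unlist(s$level)),
                              duration = as.numeric(unlist(s$duration)))
                 }),
                 sweep_var = var, interval = doc$interval),
            class = "sweep_protocol")
}

#' Run a protocol through the gating model
#'
#' Simulates one [simulate_sweep()] per sweep of the protocol. The
#' initial occupancy of every sweep is the stationary distribution at
#' the holding potential: the inter-sweep interval (1.5 s) is far longer
#' than any relaxation time at -120 mV, so full re-equilibration between
#' sweeps is assumed.
#'
#' @param scheme a [gating_scheme()]
#' @param params a [channel_params()]
#' @param protocol a [make_protocol()] object
#' @param T temperature (degrees C)
#' @param dt sample interval (ms); default as in [simulate_sweep()]
#' @param gmax,erev conductance scale and reversal potential (mV)
#' @param store_occupancy keep occupancy time courses
#' @return list of \code{current_trace} objects, one per sweep, each
#'   carrying the sweep-varying value as attribute \code{sweep_value}
#' @export
run_battery <- function(scheme, params, protocol, T, dt = NULL,
                        gmax = 1, erev = 100, store_occupancy = FALSE) {
  stopifnot(inherits(protocol, "sweep_protocol"))
  Qh <- build_generator(scheme, params, protocol$holding, T)
  p0 <- stationary_distribution(Qh)
  traces <- vector("list", length(protocol$sweeps))
  for (i in seq_along(protocol$sweeps)) {
    tr <- simulate_sweep(scheme, params, protocol$sweeps[[i]], T,
                         p0 = p0, dt = dt, gmax = gmax, erev = erev,
                         store_occupancy = store_occupancy)
    attr(tr, "protocol") <- protocol$name
    attr(tr, "sweep_var") <- protocol$sweep_var$name
    attr(tr, "sweep_value") <- protocol$sweep_var$values[i]
    traces[[i]] <- tr
  }
  names(traces) <- as.character(protocol$sweep_var$values)
  traces
}

#' Write a family of traces as flat CSV
#'
#' Long format: one row per sample with columns time_ms, voltage_mV,
#' current, sweep_id, sweep_value.
#'
#' @param traces list of \code{current_trace} objects
#' @param path file path
#' @export
write_traces_csv <- function(traces, path) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(time_ms = tr$time, voltage_mV = tr$voltage,
               current = tr$current, sweep_id = i,
               sweep_value = attr(tr, "sweep_value") %||% NA_real_)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
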