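#' Parameters of the two-compartment myelinated axon model
#'
#' A Bostock-type space-clamped model of a human myelinated sensory
#' axon: an excitable node coupled to the internodal compartment
#' through the Barrett-Barrett pathway. Nodal currents: transient Na
#' (73\% HH-type m3h + 27\% Markov resurgent model), persistent Na, slow
#' K, fast K, leak, and a constant outward pump current; internodal
#' currents: fast K, HCN (h-current, activated by hyperpolarization),
#' leak. Units: nS, pF, mV, ms, pA.
#'
#' HH gates use Boltzmann steady states \eqn{x_\infty(V)} and
#' bell-shaped time constants
#' \eqn{\tau(V) = a/\cosh((V - V_\tau)/k_\tau) + \tau_{min}} defined at
#' 36 degrees C; their rates carry a global Q10 of 2.2. Markov rates
#' follow their own per-transition Q10 laws (reference 25 degrees C).
#'
#' @param genotype channel parameter set for the Markov fraction
#'   ("WT" or "IEM")
#' @param temperature model temperature (degrees C); 36 = baseline skin
#'   temperature, 25 = cooled
#' @param pump constant outward pump current (pA); 30 for the control
#'   scenario, 15 for the IEM scenario (reduced local perfusion)
#' @param resurgent_fraction fraction of transient Na conductance
#'   carried by the Markov model (default 0.27, the Nav1.7 share on
#'   peripheral axons)
#' @param ... overrides of any scalar membrane parameter
#' @return object of class \code{axon_params}
#' @export
axon_params <- function(genotype = c("WT", "IEM"), temperature = 36,
                        pump = 30, resurgent_fraction = 0.27, ...) {
  genotype <- match.arg(genotype)
  stopifnot(resurgent_fraction >= 0, resurgent_fraction <= 1)
  mem <- list(
    cn = 1.5,      # nodal capacitance (pF)
    ci = 120,      # internodal capacitance (pF)
    gna = 300,     # total nodal transient Na conductance (nS)
    gnap = 1.5,    # persistent Na (nS, first-order gate)
    gksn = 25,     # nodal slow K (nS)
    gkfn = 80,     # nodal fast K (nS)
    gln = 3,       # nodal leak (nS)
    gkfi = 60,     # internodal fast K (nS)
    gh = 10,       # internodal HCN (nS)
    gli = 6,       # internodal leak (nS)
    gbb = 20,      # Barrett-Barrett coupling (nS)
    ena = 50, ek = -95, eh = -45, elk = -85,
    gate_q10 = 2.2, gate_tref = 36)
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(mem)) stop("unknown axon parameter: ", nm)
    mem[[nm]] <- ov[[nm]]
  }
  # gate rows: vh, k, tau_amp, v_tau, k_tau, tau_min  (36 C values)
  gates <- rbind(
    m  = c(-40,   6, 0.05, -40, 15, 0.01),
    h  = c(-70,  -6.5, 4.0, -60, 20, 0.30),
    p  = c(-58,   7, 1.0,  -50, 20, 0.20),
    s  = c(-45,  10, 60,   -50, 30, 10),
    nn = c(-55,  10, 3.0,  -60, 25, 0.30),
    ni = c(-55,  10, 3.0,  -60, 25, 0.30),
    q  = c(-94, -11, 150,  -95, 25, 30))
  colnames(gates) <- c("vh", "k", "tau_amp", "v_tau", "k_tau", "tau_min")
  structure(list(membrane = mem, gates = gates, genotype = genotype,
                 temperature = temperature, pump = pump,
                 resurgent_fraction = resurgent_fraction),
            class = "axon_params")
}

#' @export
print.axon_params <- function(x, ...) {
  cat(sprintf("axon parameters: %s channels, %g C, pump %g pA, Markov fraction %g\n",
              x$genotype, x$temperature, x$pump, x$resurgent_fraction))
  invisible(x)
}

#' Read / write an axon scenario as YAML
#'
#' A scenario file holds the genotype, temperature, pump current,
#' resurgent fraction and any membrane-parameter overrides.
#'
#' @param params an [axon_params()] object
#' @param path file path
#' @export
write_axon_scenario <- function(params, path) {
  doc <- list(genotype = params$genotype,
              temperature = params$temperature,
              pump = params$pump,
              resurgent_fraction = params$resurgent_fraction,
              membrane = params$membrane[
                !names(params$membrane) %in% c("gate_q10", "gate_tref")])
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_axon_scenario
#' @export
read_axon_scenario <- function(path) {
  doc <- yaml::read_yaml(path)
  do.call(axon_params,
          c(list(genotype = doc$genotype, temperature = doc$temperature,
                 pump = doc$pump,
                 resurgent_fraction = doc$resurgent_fraction),
            doc$membrane))
}

#' Build an integrable axon model
#'
#' Assembles the C++-ready representation of the axon (membrane
#' parameters, gate table, Markov generator structure with
#' temperature-scaled rate constants) and relaxes it to its resting
#' state. Fails if no stable resting potential is found in
#' [-95, -55] mV.
#'
#' @param params an [axon_params()] object
#' @param channel optional [channel_params()] override (default:
#'   preset for \code{params$genotype})
#' @param scheme optional [gating_scheme()] (default topology)
#' @param dt integration time step (ms); default 1e-3
#' @return object of class \code{axon_model}
#' @export
build_axon <- function(params, channel = NULL, scheme = NULL, dt = 1e-3) {
  stopifnot(inherits(params, "axon_params"))
  if (is.null(channel)) channel <- channel_params(params$genotype)
  if (is.null(scheme)) scheme <- gating_scheme()
  T <- params$temperature
  mem <- params$membrane
  cpp_pars <- list(
    cn = mem$cn, ci = mem$ci,
    gnaf = (1 - params$resurgent_fraction) * mem$gna,
    gmk = params$resurgent_fraction * mem$gna,
    gnap = mem$gnap, gksn = mem$gksn, gkfn = mem$gkfn, gln = mem$gln,
    gkfi = mem$gkfi, gh = mem$gh, gli = mem$gli, gbb = mem$gbb,
    ena = mem$ena, ek = mem$ek, eh = mem$eh, elk = mem$elk,
    ipump = params$pump)
  # Markov structure: 0-based edges and temperature-folded k0
  idx <- stats::setNames(seq_along(scheme$states) - 1L, scheme$states)
  tr <- scheme$transitions
  ridx <- stats::setNames(seq_along(RATE_NAMES) - 1L, RATE_NAMES)
  edges <- cbind(from = idx[tr$from], to = idx[tr$to],
                 rate = ridx[tr$rate])
  storage.mode(edges) <- "integer"
  ratepars <- t(vapply(RATE_NAMES, function(nm) {
    l <- channel[[nm]]
    c(k0_eff = l$k0 * l$q10^((T - l$t0) / 10), k1 = l$k1)
  }, numeric(2L)))
  cpp_pars$emult <- as.numeric(tr$mult)
  conducting <- unname(idx[scheme$conducting])
  gate_tfac <- mem$gate_q10^((T - mem$gate_tref) / 10)

  model <- structure(list(params = params, channel = channel,
                          scheme = scheme, dt = dt,
                          cpp = list(pars = cpp_pars, gates = params$gates,
                                     edges = edges, ratepars = ratepars,
                                     conducting = as.integer(conducting),
                                     gate_tfac = gate_tfac)),
                     class = "axon_model")
  # initial guess: -80 mV, gates at steady state, Markov stationary
  v0 <- -80
  ginf <- apply(params$gates, 1L, function(g) 1 / (1 + exp((g[1L] - v0) / g[2L])))
  p0 <- stationary_distribution(build_generator(scheme, channel, v0, T))
  state <- c(v0, v0, ginf, p0)
  r <- axon_run(model, rep(0, round(500 / dt)), state = state,
                record_every = 1000L)
  chk <- axon_run(model, rep(0, round(100 / dt)), state = r$state,
                  record_every = 100L)
  drift <- abs(chk$state[1L] - r$state[1L])
  rest <- chk$state[1L]
  if (rest < -95 || rest > -55) {
    stop(sprintf("no resting potential in [-95, -55] mV (found %.1f)", rest))
  }
  if (drift > 0.05) {
    warning(sprintf("resting-state drift %.3g mV over 100 ms", drift))
  }
  model$rest_state <- chk$state
  model$resting_potential <- rest
  model
}

#' @export
print.axon_model <- function(x, ...) {
  cat(sprintf("axon model: %s, %g C, pump %g pA, resting %.2f mV, dt %g ms\n",
              x$params$genotype, x$params$temperature, x$params$pump,
              x$resting_potential, x$dt))
  invisible(x)
}

#' Integrate the axon model under an injected-current waveform
#'
#' @param model an [build_axon()] model
#' @param stim injected nodal current (pA), one value per time step
#' @param state initial state vector (default: resting state)
#' @param record_every record the nodal potential every this many steps
#' @return list with \code{time}, \code{v_node}, \code{v_internode},
#'   final \code{state}, and \code{vn_max}
#' @export
axon_run <- function(model, stim, state = model$rest_state,
                     record_every = 10L) {
  cp <- model$cpp
  axon_run_cpp(state, as.numeric(stim), model$dt, cp$pars, cp$gates,
               cp$edges, cp$ratepars, cp$conducting, cp$gate_tfac,
               as.integer(record_every))
}

#' Threshold current of the axon by bisection
#'
#' Finds the minimal amplitude of a rectangular test pulse of the given
#' width that evokes a spike (nodal potential crossing 0 mV within the
#' spike window after test onset), to a relative tolerance of 0.5\%.
#' An optional conditioning current (sampled per time step) can precede
#' and overlap the test; the state at test onset is computed once and
#' reused across bisection iterations.
#'
#' @param model an [build_axon()] model
#' @param width test-pulse width (ms)
#' @param cond optional conditioning waveform (pA per step) covering at
#'   least \code{t_test + width + spike_window}
#' @param t_test test onset time (ms) relative to conditioning start
#' @param state state at conditioning start (default: resting)
#' @param spike_window spike-detection window after test onset (ms)
#' @param guess starting amplitude guess (pA)
#' @param rel_tol relative bisection tolerance
#' @return threshold amplitude (pA); NA with a warning if unexcitable
#' @export
find_threshold <- function(model, width = 1, cond = NULL, t_test = 0,
                           state = model$rest_state, spike_window = 5,
                           guess = 200, rel_tol = 0.005) {
  stopifnot(width > 0)
  dt <- model$dt
  n_test <- round((width + spike_window) / dt)
  n_pre <- round(t_test / dt)
  base <- if (is.null(cond)) rep(0, n_pre + n_test) else as.numeric(cond)
  if (length(base) < n_pre + n_test) {
    base <- c(base, rep(0, n_pre + n_test - length(base)))
  }
  if (n_pre > 0L) {
    pre <- axon_run(model, base[seq_len(n_pre)], state = state,
                    record_every = n_pre)
    state <- pre$state
  }
  tail_stim <- base[(n_pre + 1L):(n_pre + n_test)]
  on <- c(rep(1, round(width / dt)), rep(0, n_test - round(width / dt)))
  spikes <- function(a) {
    r <- axon_run(model, tail_stim + a * on, state = state,
                  record_every = n_test)
    r$vn_max > 0
  }
  if (spikes(0)) {                     # conditioning alone already fires
    warning("conditioning is suprathreshold: threshold undefined")
    return(NA_real_)
  }
  lo <- 0
  hi <- guess
  tries <- 0L
  while (!spikes(hi)) {
    lo <- hi
    hi <- hi * 2
    tries <- tries + 1L
    if (tries > 9L) {                  # > 100x the initial guess
      warning("unexcitable: no spike up to ", hi, " pA")
      return(NA_real_)
    }
  }
  while (lo == 0 || (hi - lo) / hi > rel_tol) {
    mid <- if (lo == 0) hi / 2 else (hi + lo) / 2
    if (spikes(mid)) hi <- mid else lo <- mid
    if (lo == 0 && hi < 1e-6 * guess) break   # degenerate: threshold ~ 0
  }
  hi
}
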