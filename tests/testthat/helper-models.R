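# shared fixtures: scheme and parameter sets built once per test run
the_scheme <- gating_scheme()
wt_params <- channel_params("WT")
iem_params <- channel_params("IEM")

hold_state <- function(params, V = -120, T = 25, scheme = the_scheme) {
  stationary_distribution(build_generator(scheme, params, V, T))
}

# two-state toy scheme A <-> B driven by the alpha/beta laws
toy_scheme <- function() {
  structure(list(states = c("A", "B"),
                 transitions = data.frame(from = c("A", "B"),
                                          to = c("B", "A"),
                                          rate = c("alpha", "beta"),
                                          mult = c(1, 1)),
                 conducting = "B"),
            class = "gating_scheme")
}

# stiff-ODE integration of dp/dt = p Q(V) at the sample times of a
# simulated trace; independent oracle for the matrix-exponential
# propagator. Returns max |occupancy difference| over all samples.
ode_occupancy_error <- function(scheme, params, trace, T, p0) {
  skip_if_not_installed("deSolve")
  segments <- attr(trace, "segments")
  occ <- attr(trace, "occupancy")
  stopifnot(!is.null(occ))
  p <- p0
  t0 <- 0
  worst <- 0
  for (s in seq_len(nrow(segments))) {
    t1 <- t0 + segments$duration[s]
    sel <- which(trace$time > t0 + 1e-9 & trace$time <= t1 + 1e-9)
    Q <- build_generator(scheme, params, segments$level[s], T)
    f <- function(t, y, parms) list(as.numeric(y %*% Q))
    sol <- deSolve::lsoda(p, c(0, trace$time[sel] - t0), f, NULL,
                          rtol = 1e-10, atol = 1e-12)
    worst <- max(worst, max(abs(occ[sel, ] - sol[-1L, -1L, drop = FALSE])))
    p <- sol[nrow(sol), -1L]
    t0 <- t1
  }
  worst
}
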