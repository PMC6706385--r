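#' Assemble the generator (Q) matrix of the gating scheme
#'
#' Off-diagonal entry (i, j) is the transition rate from state i to
#' state j at the given membrane potential and temperature (multiplier
#' times the evaluated rate law); the diagonal is set so that every row
#' sums to zero. Occupancy row-vectors evolve as dp/dt = p Q.
#'
#' @param scheme a [gating_scheme()]
#' @param params a [channel_params()]
#' @param V membrane potential (mV)
#' @param T temperature (degrees C)
#' @return a states x states generator matrix (ms^-1)
#' @export
build_generator <- function(scheme, params, V, T) {
  stopifnot(inherits(scheme, "gating_scheme"),
            inherits(params, "channel_params"))
  tr <- scheme$transitions
  bad <- setdiff(unique(tr$rate), names(params))
  if (length(bad)) {
    stop("rate law(s) not found in parameter set: ",
         paste(bad, collapse = ", "))
  }
  n <- length(scheme$states)
  Q <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  for (i in seq_len(nrow(tr))) {
    Q[tr$from[i], tr$to[i]] <- Q[tr$from[i], tr$to[i]] +
      tr$mult[i] * evaluate_rate(params[[tr$rate[i]]], V, T)
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary occupancy distribution of a generator
#'
#' Solves p Q = 0 on the probability simplex (the equilibrium occupancy
#' at a constant holding potential). If the linear solve is numerically
#' singular, falls back to long-time propagation from the uniform
#' distribution, with a warning.
#'
#' @param Q generator matrix from [build_generator()]
#' @return named occupancy vector summing to 1
#' @export
stationary_distribution <- function(Q) {
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  p <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(p) || any(!is.finite(p)) || any(p < -1e-8)) {
    warning("singular generator; falling back to long-time propagation")
    p <- rep(1 / n, n)
    P <- expm_mat(Q * 1000)          # 1 s blocks
    for (i in 1:10) p <- as.numeric(p %*% P)
  }
  p <- pmax(p, 0)
  p <- p / sum(p)
  names(p) <- rownames(Q)
  p
}

# Matrix exponential by scaling and squaring with a Pade(6) approximant.
# Small dense matrices only (the gating model has < 10 states).
expm_mat <- function(A) {
  n <- nrow(A)
  nrm <- max(rowSums(abs(A)))
  j <- max(0L, ceiling(log2(max(nrm, .Machine$double.eps))) + 1L)
  As <- A / 2^j
  c6 <- c(1, 1 / 2, 5 / 44, 1 / 66, 1 / 792, 1 / 15840, 1 / 665280)
  X <- diag(n)
  N <- D <- c6[1] * X
  sign <- -1
  for (k in 1:6) {
    X <- X %*% As
    N <- N + c6[k + 1] * X
    D <- D + sign * c6[k + 1] * X
    sign <- -sign
  }
  E <- solve(D, N)
  for (k in seq_len(j)) E <- E %*% E
  E
}

# Propagate occupancy p0 under constant generator Q to each time in
# `times` (non-negative, relative to segment start). Eigendecomposition
# when well conditioned, otherwise uniform-step squaring fallback.
propagate_occupancy <- function(Q, p0, times) {
  n <- nrow(Q)
  eg <- eigen(Q)
  ok <- tryCatch(rcond(abs(eg$vectors)) > 1e-12, error = function(e) FALSE)
  if (ok) {
    Vinv <- solve(eg$vectors)
    a <- as.vector(p0 %*% eg$vectors)            # complex allowed
    E <- exp(outer(times, eg$values))            # |times| x n
    P <- Re((E * matrix(a, nrow = length(times), ncol = n,
                        byrow = TRUE)) %*% Vinv)
  } else {
    dts <- diff(c(0, times))
    if (max(abs(dts - dts[1])) > 1e-12 * max(dts)) {
      stop("non-uniform time grid with ill-conditioned generator")
    }
    Pdt <- expm_mat(Q * dts[1])
    P <- matrix(0, length(times), n)
    p <- p0
    for (i in seq_along(times)) {
      p <- as.numeric(p %*% Pdt)
      P[i, ] <- p
    }
  }
  colnames(P) <- rownames(Q)
  P
}

#' Simulate a voltage-clamp sweep by the Q-matrix method
#'
#' Advances the state occupancies across a piecewise-constant command
#' voltage using matrix-exponential propagation per segment, and forms
#' the macroscopic current assuming an Ohmic open-channel conductance:
#' I(t) = gmax * P_open(t) * (V(t) - erev), with the sodium reversal
#' potential erev = +100 mV by default.
#'
#' @param scheme a [gating_scheme()]
#' @param params a [channel_params()]
#' @param segments data.frame with columns \code{level} (mV) and
#'   \code{duration} (ms), one row per constant-voltage segment
#' @param T temperature (degrees C)
#' @param p0 initial occupancy (named or in state order); default is the
#'   stationary distribution at the first segment's voltage
#' @param dt sample interval (ms); default 0.005 at/above 35 degrees C,
#'   0.01 otherwise (kinetics are ~2-3x faster per 15 degrees C, so the
#'   warm condition is sampled more finely)
#' @param gmax conductance scale (arbitrary; reported metrics are ratios)
#' @param erev reversal potential (mV)
#' @param store_occupancy keep the full occupancy time course
#' @return a \code{current_trace}: data.frame with columns \code{time}
#'   (ms), \code{voltage} (mV), \code{current}, \code{popen}; attributes
#'   \code{temp}, \code{dt}, \code{segments}, optionally
#'   \code{occupancy}
#' @export
simulate_sweep <- function(scheme, params, segments, T, p0 = NULL,
                           dt = NULL, gmax = 1, erev = 100,
                           store_occupancy = FALSE) {
  segments <- as.data.frame(segments)
  stopifnot(nrow(segments) >= 1L, all(segments$duration > 0))
  if (is.null(dt)) dt <- if (T >= 35) 0.005 else 0.01
  if (dt > min(segments$duration) / 10) {
    dt <- min(segments$duration) / 10
  }
  Qs <- lapply(segments$level, function(v) build_generator(scheme, params, v, T))
  if (is.null(p0)) p0 <- stationary_distribution(Qs[[1L]])
  p0 <- as_occupancy(p0, scheme$states)

  time <- 0
  occ <- matrix(p0, nrow = 1L, dimnames = list(NULL, scheme$states))
  volt <- segments$level[1L]
  p <- p0
  t_off <- 0
  for (s in seq_len(nrow(segments))) {
    nstep <- max(1L, round(segments$duration[s] / dt))
    tt <- seq_len(nstep) * (segments$duration[s] / nstep)
    block <- propagate_occupancy(Qs[[s]], p, tt)
    p <- block[nrow(block), ]
    occ <- rbind(occ, block)
    time <- c(time, t_off + tt)
    volt <- c(volt, rep(segments$level[s], nstep))
    t_off <- t_off + segments$duration[s]
  }
  drift <- max(abs(rowSums(occ) - 1))
  if (drift > 1e-6) {
    stop(sprintf("occupancy drift %.3g exceeds 1e-6; reduce dt", drift))
  }
  popen <- rowSums(occ[, scheme$conducting, drop = FALSE])
  out <- data.frame(time = time, voltage = volt,
                    current = gmax * popen * (volt - erev),
                    popen = popen)
  structure(out, class = c("current_trace", "data.frame"),
            temp = T, dt = dt, gmax = gmax, erev = erev,
            segments = segments,
            occupancy = if (store_occupancy) occ else NULL,
            genotype = params$label)
}

as_occupancy <- function(p, states) {
  if (!is.null(names(p))) p <- p[states]
  p <- as.numeric(p)
  if (length(p) != length(states) || any(!is.finite(p)) ||
      any(p < -1e-12) || abs(sum(p) - 1) > 1e-9) {
    stop("p0 must be a probability vector over the scheme states")
  }
  names(p) <- states
  pmax(p, 0) / sum(pmax(p, 0))
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf(
    "current trace: %d samples, %.3g ms, dt = %g ms, T = %g C, %s\n",
    nrow(x), max(x$time), attr(x, "dt"), attr(x, "temp"),
    attr(x, "genotype") %||% "?"))
  invisible(x)
}

#' @export
plot.current_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$time, x$voltage, type = "s", xlab = "time (ms)",
       ylab = "V (mV)", ...)
  plot(x$time, x$current, type = "l", xlab = "time (ms)",
       ylab = "current", ...)
  invisible(x)
}
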