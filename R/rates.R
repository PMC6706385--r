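#' Voltage- and temperature-dependent transition rate law
#'
#' A transition rate of the channel gating model is parameterized as
#' \deqn{k(V, T) = k_0 \, e^{k_1 V} \, Q_{10}^{(T - T_0)/10}}
#' where \eqn{k_0} is the rate at 0 mV and the reference temperature
#' \eqn{T_0} (25 degrees C), \eqn{k_1} the voltage-dependence coefficient
#' (per mV) and \eqn{Q_{10}} the factor by which the rate grows per
#' 10 degrees C.
#'
#' @param k0 rate at 0 mV and reference temperature (ms^-1), > 0
#' @param k1 voltage-dependence coefficient (mV^-1)
#' @param q10 temperature coefficient, > 0
#' @param t0 reference temperature (degrees C), fixed at 25 by convention
#' @return an object of class \code{rate_law}
#' @seealso [evaluate_rate()], [channel_params()]
#' @export
rate_law <- function(k0, k1, q10, t0 = 25) {
  stopifnot(is.numeric(k0), length(k0) == 1L, is.finite(k0), k0 > 0,
            is.numeric(k1), length(k1) == 1L, is.finite(k1),
            is.numeric(q10), length(q10) == 1L, is.finite(q10), q10 > 0)
  structure(list(k0 = k0, k1 = k1, q10 = q10, t0 = t0), class = "rate_law")
}

#' @export
print.rate_law <- function(x, ...) {
  cat(sprintf("rate law: k(V,T) = %g * exp(%g * V) * %g^((T-%g)/10) ms^-1\n",
              x$k0, x$k1, x$q10, x$t0))
  invisible(x)
}

#' Evaluate a rate law at a membrane potential and temperature
#'
#' @param law a [rate_law()]
#' @param V membrane potential (mV); vectorized
#' @param T temperature (degrees C)
#' @return rate(s) in ms^-1, strictly positive
#' @export
evaluate_rate <- function(law, V, T) {
  stopifnot(inherits(law, "rate_law"))
  if (!all(is.finite(V))) stop("membrane potential V must be finite")
  if (!all(is.finite(T)) || length(T) != 1L) {
    stop("temperature T must be a single finite value")
  }
  law$k0 * exp(law$k1 * V) * law$q10^((T - law$t0) / 10)
}

# Transition names of the gating scheme, in canonical order.
RATE_NAMES <- c("alpha", "beta", "gamma", "delta",
                "c_on", "c_off", "o_on", "o_off",
                "o1o2", "o2o1", "o2i2", "i2o2", "i1i2", "i2i1")

#' Channel model parameter sets
#'
#' Returns the full set of fourteen transition-rate laws for the wild-type
#' ("WT") or the inherited-erythromelalgia mutant ("IEM") Nav1.7 channel
#' model. The two presets differ in the k0 of alpha, beta, o2i2, i2o2,
#' i1i2 and i2i1, and in the temperature dependence (Q10) of the
#' transitions into and out of the second (resurgent) open state O2:
#' Q10 ~ 2 in WT versus ~ 3.3 in IEM, the change that underlies the
#' anomalous heat enhancement of relative resurgent current.
#'
#' @param genotype "WT" or "IEM"
#' @return an object of class \code{channel_params}: a named list of
#'   [rate_law()] objects plus a \code{label}
#' @export
channel_params <- function(genotype = c("WT", "IEM")) {
  genotype <- match.arg(genotype)
  tab <- if (genotype == "WT") {
    list(
      alpha = c(100,   0.08,  2.1),
      beta  = c(0.55, -0.01,  2.1),
      gamma = c(40,    0.01,  2.1),
      delta = c(2,    -0.01,  2.1),
      c_on  = c(0.1,   0,     3.2),
      c_off = c(0.5,   0,     3.2),
      o_on  = c(2.5,   0,     3.2),
      o_off = c(0.004, 0,     3.2),
      o1o2  = c(0.12,  0.057, 2),
      o2o1  = c(0.001, -0.095, 2),
      o2i2  = c(0.5,   0.04,  2),
      i2o2  = c(0.06, -0.03,  2),
      i1i2  = c(0.002, 0.01,  2.6),
      i2i1  = c(0.2,  -0.038, 2.6)
    )
  } else {
    list(
      alpha = c(500,   0.08,  2.1),
      beta  = c(4,    -0.01,  2.1),
      gamma = c(40,    0.01,  2.1),
      delta = c(2,    -0.01,  2.1),
      c_on  = c(0.1,   0,     3.2),
      c_off = c(0.5,   0,     3.2),
      o_on  = c(2.5,   0,     3.2),
      o_off = c(0.004, 0,     3.2),
      o1o2  = c(0.12,  0.057, 2.6),
      o2o1  = c(0.001, -0.095, 2.6),
      o2i2  = c(0.3,   0.04,  3.3),
      i2o2  = c(0.07, -0.03,  3.3),
      i1i2  = c(0.001, 0.01,  2.6),
      i2i1  = c(0.12, -0.038, 2.6)
    )
  }
  laws <- lapply(tab, function(p) rate_law(p[1], p[2], p[3]))
  structure(c(laws, list(label = genotype)), class = "channel_params")
}

#' @export
print.channel_params <- function(x, ...) {
  cat(sprintf("channel parameter set '%s' (%d rate laws)\n",
              x$label, length(RATE_NAMES)))
  for (nm in RATE_NAMES) {
    l <- x[[nm]]
    cat(sprintf("  %-6s k0 = %-7g k1 = %-7g Q10 = %g\n",
                nm, l$k0, l$k1, l$q10))
  }
  invisible(x)
}

#' Evaluate every transition rate of a parameter set
#'
#' @param params a [channel_params()] set
#' @param V membrane potential (mV)
#' @param T temperature (degrees C)
#' @return named numeric vector of rates (ms^-1)
#' @export
evaluate_rates <- function(params, V, T) {
  stopifnot(inherits(params, "channel_params"))
  vapply(RATE_NAMES, function(nm) evaluate_rate(params[[nm]], V, T),
         numeric(1L))
}

#' Activation-energy change implied by a Q10
#'
#' Raising the temperature by 10 degrees C multiplies a rate by Q10;
#' in transition-state terms this corresponds to a free-energy barrier
#' change of \eqn{\ln Q_{10}} in units of RT per 10 degrees C step.
#' For example Q10 = 3 corresponds to ~1.1 RT and Q10 = 2 to ~0.69 RT.
#'
#' @param q10 temperature coefficient(s), > 0
#' @return barrier change in RT units per 10 degrees C
#' @export
q10_activation_energy <- function(q10) {
  stopifnot(all(q10 > 0))
  log(q10)
}

#' Read or write channel parameter sets as YAML
#'
#' One YAML document per genotype: a `label` plus one `{k0, k1, q10}`
#' triplet per named transition.
#'
#' @param params a [channel_params()] object
#' @param path file path
#' @return \code{read_channel_params} returns a [channel_params()] object.
#' @export
write_channel_params <- function(params, path) {
  stopifnot(inherits(params, "channel_params"))
  doc <- list(label = params$label)
  for (nm in RATE_NAMES) {
    l <- params[[nm]]
    doc[[nm]] <- list(k0 = l$k0, k1 = l$k1, q10 = l$q10)
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_channel_params
#' @export
read_channel_params <- function(path) {
  doc <- yaml::read_yaml(path)
  missing <- setdiff(RATE_NAMES, names(doc))
  if (length(missing)) {
    stop("parameter file lacks transitions: ", paste(missing, collapse = ", "))
  }
  laws <- lapply(doc[RATE_NAMES], function(p) rate_law(p$k0, p$k1, p$q10))
  structure(c(laws, list(label = doc$label %||% "custom")),
            class = "channel_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
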