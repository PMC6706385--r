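#' Noise model for synthetic recordings
#'
#' Additive Gaussian current noise with standard deviation expressed as
#' a fraction of the transient peak amplitude, plus log-normal
#' cell-to-cell scaling of the maximal conductance (CV 10\% by default)
#' to emulate cell-size variation.
#'
#' @param sigma noise standard deviation as a fraction of the transient
#'   peak (default 0.02)
#' @param gmax_cv coefficient of variation of the per-cell conductance
#'   jitter
#' @param seed integer master seed; identical seeds give identical
#'   datasets
#' @return object of class \code{noise_model}
#' @export
noise_model <- function(sigma = 0.02, gmax_cv = 0.10, seed = 1L) {
  stopifnot(sigma >= 0, gmax_cv >= 0)
  structure(list(sigma = sigma, gmax_cv = gmax_cv, seed = as.integer(seed)),
            class = "noise_model")
}

# deterministic per-replicate sub-seed from the master seed
derive_seed <- function(seed, i) {
  (as.integer(seed) * 1000003L + i * 7919L) %% 2147483647L
}

#' Generate noisy replicate sweeps from the gating model
#'
#' Simulates the protocol once, then produces \code{n_cells}
#' independent noisy replicates of each sweep: per-cell log-normal
#' conductance scaling and additive Gaussian noise with sd =
#' \code{sigma} x (absolute transient peak of the cell's largest
#' sweep).
#'
#' @param scheme a [gating_scheme()]
#' @param params a [channel_params()]
#' @param protocol a [make_protocol()] object
#' @param T temperature (degrees C)
#' @param noise a [noise_model()]
#' @param n_cells number of replicate cells
#' @param dt sample interval (ms)
#' @return object of class \code{synthetic_dataset}: list with
#'   \code{cells} (list of trace lists), \code{clean} (noiseless
#'   traces), \code{provenance}
#' @export
generate_noisy_sweeps <- function(scheme, params, protocol, T,
                                  noise = noise_model(), n_cells = 5L,
                                  dt = NULL) {
  stopifnot(n_cells >= 1L)
  clean <- run_battery(scheme, params, protocol, T, dt = dt)
  peak_all <- max(vapply(clean, function(tr) max(abs(tr$current)),
                         numeric(1L)))
  cells <- lapply(seq_len(n_cells), function(ic) {
    set.seed(derive_seed(noise$seed, ic))
    gscale <- if (noise$gmax_cv > 0) {
      sdlog <- sqrt(log(1 + noise$gmax_cv^2))
      stats::rlnorm(1L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else 1
    lapply(clean, function(tr) {
      out <- tr
      out$current <- gscale * tr$current +
        stats::rnorm(length(tr$current), 0, noise$sigma * peak_all * gscale)
      attr(out, "gscale") <- gscale
      out
    })
  })
  structure(list(cells = cells, clean = clean,
                 provenance = list(protocol = protocol$name,
                                   genotype = params$label,
                                   temperature = T,
                                   sigma = noise$sigma,
                                   gmax_cv = noise$gmax_cv,
                                   seed = noise$seed,
                                   n_cells = n_cells)),
            class = "synthetic_dataset")
}

#' Generate noisy samples of a parametric gating curve
#'
#' Draws replicate (x, y) datasets from a known generating curve plus
#' Gaussian noise, for parameter-recovery testing of the fitting
#' routines.
#'
#' \describe{
#'   \item{boltzmann}{\code{pars = list(vh, k)}; x = voltage (mV);
#'     y clipped to [0, 1].}
#'   \item{recovery}{\code{pars = list(tau)}; x = gap (ms);
#'     y = 1 - exp(-x/tau), clipped to [0, 1.05].}
#'   \item{prepulse_decay}{\code{pars = list(tau, f0)}; x = prepulse
#'     duration (ms); y = (1-f0) exp(-x/tau) + f0, clipped to [0, 1].}
#' }
#'
#' @param kind curve family
#' @param pars generating parameters (see Details)
#' @param x abscissa grid
#' @param noise a [noise_model()] (only \code{sigma} and \code{seed}
#'   are used)
#' @param n_replicates number of replicate datasets
#' @return object of class \code{synthetic_dataset}: list with
#'   \code{replicates} (list of data.frames x, y), \code{pars},
#'   \code{provenance}
#' @export
generate_curve_dataset <- function(kind = c("boltzmann", "recovery",
                                            "prepulse_decay"),
                                   pars, x, noise = noise_model(),
                                   n_replicates = 1L) {
  kind <- match.arg(kind)
  f <- switch(kind,
    boltzmann = function(x) 1 / (1 + exp((pars$vh - x) / pars$k)),
    recovery = function(x) 1 - exp(-x / pars$tau),
    prepulse_decay = function(x) (1 - pars$f0) * exp(-x / pars$tau) + pars$f0)
  hi <- if (kind == "recovery") 1.05 else 1
  y0 <- f(x)
  reps <- lapply(seq_len(n_replicates), function(i) {
    set.seed(derive_seed(noise$seed, i))
    y <- y0 + stats::rnorm(length(x), 0, noise$sigma)
    data.frame(x = x, y = pmin(pmax(y, 0), hi))
  })
  structure(list(replicates = reps, pars = pars,
                 provenance = list(kind = kind, sigma = noise$sigma,
                                   seed = noise$seed,
                                   n_replicates = n_replicates)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  p <- x$provenance
  if (!is.null(x$cells)) {
    cat(sprintf("synthetic sweeps: %s, %s, %g C, %d cells, sigma %g, seed %d\n",
                p$protocol, p$genotype, p$temperature, p$n_cells,
                p$sigma, p$seed))
  } else {
    cat(sprintf("synthetic %s curves: %d replicates, sigma %g, seed %d\n",
                p$kind, p$n_replicates, p$sigma, p$seed))
  }
  invisible(x)
}

#' Write a synthetic dataset as CSV with a JSON sidecar
#'
#' The CSV holds the samples in long format; the sidecar JSON records
#' the generating parameters and provenance.
#'
#' @param dataset a \code{synthetic_dataset}
#' @param path CSV file path (sidecar written next to it as
#'   \code{<path>.json})
#' @export
write_dataset <- function(dataset, path) {
  if (!is.null(dataset$replicates)) {
    rows <- do.call(rbind, lapply(seq_along(dataset$replicates), function(i) {
      cbind(replicate = i, dataset$replicates[[i]])
    }))
    utils::write.csv(rows, path, row.names = FALSE)
    side <- c(dataset$provenance, list(pars = dataset$pars))
  } else {
    rows <- do.call(rbind, lapply(seq_along(dataset$cells), function(ic) {
      tr <- dataset$cells[[ic]]
      do.call(rbind, lapply(seq_along(tr), function(is) {
        data.frame(cell = ic, sweep = is,
                   sweep_value = attr(tr[[is]], "sweep_value") %||% NA_real_,
                   time_ms = tr[[is]]$time, voltage_mV = tr[[is]]$voltage,
                   current = tr[[is]]$current)
      }))
    }))
    utils::write.csv(rows, path, row.names = FALSE)
    side <- dataset$provenance
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
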