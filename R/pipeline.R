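#' Study configuration
#'
#' Bundles the choices of a full in-silico study: which genotypes and
#' temperatures to characterize under voltage clamp, which protocols to
#' run, the axon scenarios for the excitability comparison, seeds and
#' an optional output directory.
#'
#' @param genotypes character vector ("WT", "IEM")
#' @param temperatures voltage-clamp temperatures (degrees C, in
#'   [0, 50])
#' @param protocols protocol kinds for the temperature sweep
#' @param axon_temperatures temperatures for the NET comparison
#' @param recovery_gaps gap grid (ms) for the recovery protocol; the
#'   default is a condensed grid spanning 0.2-100 ms (0.2-500 ms when
#'   cold) that resolves the mono-exponential recovery without the full
#'   0.1 ms-increment sweep family
#' @param seed master seed for synthetic replicates
#' @param outdir optional output directory for CSV/JSON exports
#' @return object of class \code{study_config}
#' @export
study_config <- function(genotypes = c("WT", "IEM"),
                         temperatures = c(15, 25, 40),
                         protocols = c("activation_iv", "inactivation",
                                       "resurgent", "recovery",
                                       "prepulse_duration"),
                         axon_temperatures = c(36, 25),
                         recovery_gaps = NULL,
                         seed = 1L, outdir = NULL) {
  stopifnot(length(genotypes) >= 1L,
            all(temperatures >= 0 & temperatures <= 50))
  structure(list(genotypes = genotypes, temperatures = temperatures,
                 protocols = protocols,
                 axon_temperatures = axon_temperatures,
                 recovery_gaps = recovery_gaps,
                 seed = as.integer(seed), outdir = outdir),
            class = "study_config")
}

default_recovery_gaps <- function(T) {
  mx <- if (T < 20) 500 else 100
  g <- c(seq(0.2, 2, 0.2), seq(2.5, 10, 0.5), seq(12, 30, 3),
         seq(40, 100, 20))
  if (mx > 100) g <- c(g, seq(150, mx, 50))
  g
}

#' Voltage-clamp temperature-sweep study
#'
#' For every (genotype, temperature) pair, runs the requested protocol
#' batteries through the gating model, applies the full analysis layer,
#' and returns a tidy metrics table (one row per metric with units),
#' including the mutant-over-WT relative-resurgent ratio column when
#' both genotypes are present.
#'
#' @param config a [study_config()]
#' @param scheme optional [gating_scheme()]
#' @return data.frame with columns genotype, temperature, protocol,
#'   metric, value, units
#' @export
run_temperature_sweep <- function(config = study_config(), scheme = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(scheme)) scheme <- gating_scheme()
  rows <- list()
  put <- function(g, T, prot, metric, value, units) {
    rows[[length(rows) + 1L]] <<- data.frame(
      genotype = g, temperature = T, protocol = prot, metric = metric,
      value = value, units = units)
  }
  for (g in config$genotypes) {
    par <- channel_params(g)
    for (T in config$temperatures) {
      act <- NULL
      ref <- NULL
      if ("activation_iv" %in% config$protocols) {
        act_tr <- run_battery(scheme, par, make_protocol("activation_iv"), T)
        iv <- analyze_iv(act_tr)
        put(g, T, "activation_iv", "v_na", iv$v_na, "mV")
        put(g, T, "activation_iv", "g_max", iv$g_max, "norm")
        keep <- iv$table$voltage <= 20
        act <- fit_boltzmann(iv$table$voltage[keep],
                             pmin(pmax(iv$table$g_norm[keep], 0), 1),
                             form = "activation")
        put(g, T, "activation_iv", "vh_act", act$vh, "mV")
        put(g, T, "activation_iv", "k_act", act$k, "mV")
        for (v in c(10, 20, 30)) {
          put(g, T, "activation_iv", sprintf("sustained_ratio_%+d", v),
              sustained_ratio(act_tr[[as.character(v)]]), "ratio")
        }
        ref <- act_tr[["-20"]]
      }
      inact <- NULL
      if ("inactivation" %in% config$protocols) {
        in_tr <- run_battery(scheme, par, make_protocol("inactivation"), T)
        vpre <- vapply(in_tr, function(tr) attr(tr, "sweep_value"),
                       numeric(1L))
        pk <- vapply(in_tr, function(tr) {
          segs <- attr(tr, "segments")
          abs(trace_peak(tr, segs$duration[1L], sum(segs$duration)))
        }, numeric(1L))
        inact <- fit_boltzmann(vpre, pk / max(pk), form = "inactivation")
        put(g, T, "inactivation", "vh_inact", inact$vh, "mV")
        put(g, T, "inactivation", "k_inact", inact$k, "mV")
      }
      if (!is.null(act) && !is.null(inact)) {
        w <- window_curve(act, inact)
        put(g, T, "window", "area", w$area, "mV")
        for (nm in names(w$spots)) {
          put(g, T, "window", paste0("product_", nm), w$spots[[nm]], "ratio")
        }
      }
      if ("resurgent" %in% config$protocols && !is.null(ref)) {
        res_tr <- run_battery(scheme, par, make_protocol("resurgent"), T)
        rm <- resurgent_metrics(res_tr, ref)
        tb <- rm$table
        put(g, T, "resurgent", "ires_itrans_max", max(tb$ratio), "ratio")
        put(g, T, "resurgent", "q_ratio_max", max(tb$charge_ratio), "ratio")
        i40 <- which(tb$voltage == -40)
        put(g, T, "resurgent", "time_to_peak_-40", tb$time_to_peak[i40], "ms")
        put(g, T, "resurgent", "tau_decay_-40", tb$tau_decay[i40], "ms")
        ok <- !is.na(tb$tau_decay)
        if (sum(ok) >= 3L) {
          dv <- fit_decay_voltage_regression(tb$voltage[ok], tb$tau_decay[ok])
          put(g, T, "resurgent", "decay_A", dv$A, "1/ms")
          put(g, T, "resurgent", "decay_k", dv$k, "")
        }
      }
      if ("recovery" %in% config$protocols) {
        gaps <- config$recovery_gaps %||% default_recovery_gaps(T)
        rec_tr <- run_battery(scheme, par,
                              make_protocol("recovery", gaps = gaps), T)
        fr <- recovery_fractions(rec_tr)
        rf <- fit_recovery(fr$gap, pmin(fr$fraction, 1.05),
                           v_recovery = -80, temperature = T)
        put(g, T, "recovery", "tau_recovery_-80", rf$tau, "ms")
      }
      if ("prepulse_duration" %in% config$protocols) {
        pp_tr <- run_battery(scheme, par,
                             make_protocol("prepulse_duration"), T)
        durs <- vapply(pp_tr, function(tr) attr(tr, "sweep_value"),
                       numeric(1L))
        pk <- vapply(pp_tr, function(tr) {
          segs <- attr(tr, "segments")
          rm1 <- resurgent_metrics(list(tr), tr)
          rm1$table$peak[1L]
        }, numeric(1L))
        pd <- fit_prepulse_decay(durs, pk / max(pk))
        put(g, T, "prepulse_duration", "tau_prepulse", pd$tau, "ms")
        put(g, T, "prepulse_duration", "f0", pd$f0, "ratio")
      }
    }
  }
  out <- do.call(rbind, rows)
  # mutant-over-WT relative resurgent ratio at matched temperature
  if ("WT" %in% config$genotypes) {
    base <- out[out$metric == "ires_itrans_max" & out$genotype == "WT", ]
    mut <- out[out$metric == "ires_itrans_max" & out$genotype != "WT", ]
    for (i in seq_len(nrow(mut))) {
      wtv <- base$value[base$temperature == mut$temperature[i]]
      if (length(wtv) == 1L) {
        out <- rbind(out, data.frame(
          genotype = mut$genotype[i], temperature = mut$temperature[i],
          protocol = "resurgent", metric = "ratio_to_wt",
          value = ratio_to_wt(mut$value[i], wtv), units = "ratio"))
      }
    }
  }
  if (!is.null(config$outdir)) {
    export_table(out, config, "temperature_sweep")
  }
  out
}

#' Control-versus-IEM nerve-excitability comparison
#'
#' Builds the two axon scenarios (control: WT channels + 30 pA pump;
#' IEM: mutant channels + 15 pA pump) at each requested temperature,
#' runs the NET battery, and returns the tidy index table. Curves are
#' attached as an attribute.
#'
#' @param config a [study_config()]
#' @param ... forwarded to [run_net_battery()] (protocol grids)
#' @return data.frame with columns scenario, temperature, metric,
#'   value; attribute \code{batteries} holds the full results
#' @export
run_net_comparison <- function(config = study_config(), ...) {
  stopifnot(inherits(config, "study_config"))
  scen <- list(control = list(genotype = "WT", pump = 30),
               iem = list(genotype = "IEM", pump = 15))
  rows <- list()
  bats <- list()
  for (T in config$axon_temperatures) {
    for (nm in names(scen)) {
      ap <- axon_params(genotype = scen[[nm]]$genotype, temperature = T,
                        pump = scen[[nm]]$pump)
      model <- build_axon(ap)
      bat <- run_net_battery(model, ...)
      bats[[sprintf("%s_%g", nm, T)]] <- bat
      vals <- c(bat$indices, threshold = bat$threshold,
                resting_potential = bat$resting_potential)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = nm, temperature = T, metric = names(vals),
        value = unname(vals))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "batteries") <- bats
  if (!is.null(config$outdir)) export_table(out, config, "net_comparison")
  out
}

export_table <- function(tab, config, name) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$outdir, paste0(name, ".csv"))
  utils::write.csv(tab, path, row.names = FALSE)
  prov <- list(
    generated_by = paste0("resurgentsim ",
                          as.character(utils::packageVersion("resurgentsim"))),
    seed = config$seed,
    config = config[c("genotypes", "temperatures", "protocols",
                      "axon_temperatures")])
  jsonlite::write_json(prov, file.path(config$outdir,
                                       paste0(name, "_provenance.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pivot a tidy metrics table to a wide comparison layout
#'
#' @param tab output of [run_temperature_sweep()]
#' @return data.frame with one row per metric and one column per
#'   (genotype, temperature)
#' @export
pivot_metrics <- function(tab) {
  key <- paste(tab$genotype, tab$temperature, sep = "_")
  stats::reshape(
    data.frame(metric = tab$metric, key = key, value = tab$value),
    idvar = "metric", timevar = "key", direction = "wide")
}
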