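#' Threshold tracking along a conditioning waveform
#'
#' Walks through a sorted set of test-onset times, propagating the
#' membrane state through the conditioning waveform once and bisecting
#' the test threshold at each onset.
#'
#' @param model an [build_axon()] model
#' @param cond conditioning current waveform (pA per step), or NULL
#' @param t_tests test onset times (ms), strictly increasing
#' @param width test-pulse width (ms)
#' @param guess starting amplitude guess (pA)
#' @return data.frame with \code{t_test} and \code{threshold}
#' @export
threshold_profile <- function(model, cond, t_tests, width = 1,
                              guess = 200) {
  stopifnot(!is.unsorted(t_tests, strictly = TRUE))
  dt <- model$dt
  n_need <- round((max(t_tests) + width + 5) / dt)
  cond <- if (is.null(cond)) rep(0, n_need) else as.numeric(cond)
  if (length(cond) < n_need) cond <- c(cond, rep(0, n_need - length(cond)))
  state <- model$rest_state
  t_prev <- 0
  thr <- numeric(length(t_tests))
  g <- guess
  for (i in seq_along(t_tests)) {
    n0 <- round(t_prev / dt)
    n1 <- round(t_tests[i] / dt)
    if (n1 > n0) {
      r <- axon_run(model, cond[(n0 + 1L):n1], state = state,
                    record_every = n1 - n0)
      state <- r$state
      t_prev <- t_tests[i]
    }
    resid <- cond[(n1 + 1L):min(length(cond), n1 + round((width + 5) / dt))]
    thr[i] <- find_threshold(model, width = width, cond = resid,
                             t_test = 0, state = state, guess = g)
    if (is.finite(thr[i])) g <- thr[i]
  }
  data.frame(t_test = t_tests, threshold = thr)
}

#' Run the nerve-excitability-test battery on an axon model
#'
#' Simulated analogue of the TROND threshold-tracking battery:
#' \describe{
#'   \item{SD}{thresholds at widths 0.2..1.0 ms; Weiss-law regression
#'     of threshold charge on width gives rheobase (slope) and the
#'     strength-duration time constant SDTC (intercept/slope).}
#'   \item{TE}{100 ms subthreshold conditioning at +/-20\% and +/-40\% of
#'     the unconditioned threshold; threshold tracked at delays during
#'     and after the current. Indices (threshold reduction, \%):
#'     TEd(10-20 ms), TEd(90-100 ms), TEh(10-20 ms), TEh(90-100 ms) and
#'     TEh(99 ms) from the +/-40\% level.}
#'   \item{IV}{200 ms polarizing currents from +50\% to -100\% of
#'     threshold in 10\% steps; threshold reduction at the end of the
#'     current gives the current-threshold relationship; the
#'     hyperpolarizing I/V slope is the chord slope of that curve over
#'     its hyperpolarized limb.}
#'   \item{RC}{supramaximal (2x threshold, 1 ms) conditioning stimulus;
#'     threshold change at interstimulus intervals 2-200 ms.
#'     Refractoriness = \% threshold increase at 2.5 ms (3.2 ms when
#'     cooled below 30 C); superexcitability = most negative \% change;
#'     subexcitability = largest late positive \% change; the relative
#'     refractory period is the first zero crossing.}
#' }
#'
#' Threshold reduction is (thr0 - thr)/thr0 x 100 (TE, IV); recovery-
#' cycle changes are (thr - thr0)/thr0 x 100.
#'
#' @param model an [build_axon()] model
#' @param width test-pulse width (ms)
#' @param te_levels conditioning levels (\% of threshold) for
#'   threshold electrotonus; indices are computed from the +/-40\% level
#' @param te_delays delays (ms) for threshold electrotonus
#' @param rc_intervals interstimulus intervals (ms)
#' @param iv_fractions conditioning levels (fractions of threshold)
#' @param sd_widths stimulus widths (ms) for strength-duration
#' @return object of class \code{net_battery}: list with
#'   \code{indices} (named vector), \code{curves} (per-protocol
#'   data.frames), \code{threshold} (unconditioned), and
#'   \code{resting_potential}
#' @export
run_net_battery <- function(model, width = 1,
                            te_levels = c(40, -40),
                            te_delays = c(10, 15, 20, 45, 70, 90, 95, 99,
                                          110, 130, 160, 200),
                            rc_intervals = c(2, 2.5, 3.2, 4, 5, 6.3, 8,
                                             10, 13, 18, 25, 35, 50, 70,
                                             100, 140, 200),
                            iv_fractions = c(0.5, 0.3, 0.1, -0.1, -0.3,
                                             -0.5, -0.7, -0.8, -0.9, -1),
                            sd_widths = c(0.2, 0.4, 0.6, 0.8, 1.0)) {
  dt <- model$dt
  thr0 <- find_threshold(model, width = width)
  if (!is.finite(thr0)) stop("axon unexcitable at rest")

  # --- strength-duration: Weiss law Q(w) = rheobase * (w + SDTC)
  sd_thr <- vapply(sd_widths, function(w) {
    find_threshold(model, width = w, guess = thr0 * width / w)
  }, numeric(1L))
  charge <- sd_thr * sd_widths
  wl <- stats::lm(charge ~ sd_widths)
  rheobase <- stats::coef(wl)[[2L]]
  sdtc <- stats::coef(wl)[[1L]] / rheobase

  # --- threshold electrotonus
  te_curves <- lapply(te_levels, function(lev) {
    amp <- lev / 100 * thr0
    cond <- rep(amp, round(100 / dt))
    pr <- threshold_profile(model, cond, te_delays, width = width,
                            guess = thr0)
    data.frame(level = lev, delay = pr$t_test,
               reduction = 100 * (thr0 - pr$threshold) / thr0)
  })
  te <- do.call(rbind, te_curves)
  te_idx <- function(lev, delays) {
    sel <- te$level == lev & te$delay %in% delays
    mean(te$reduction[sel], na.rm = TRUE)
  }

  # --- current-threshold (I/V)
  iv_rows <- lapply(iv_fractions, function(f) {
    amp <- f * thr0
    cond <- rep(amp, round(200 / dt) + round((width + 5) / dt))
    thr <- find_threshold(model, width = width, cond = cond,
                          t_test = 200 - width, guess = max(thr0, 50))
    data.frame(fraction = 100 * f,
               reduction = 100 * (thr0 - thr) / thr0)
  })
  iv <- do.call(rbind, iv_rows)
  iv_red <- function(fpct) iv$reduction[iv$fraction == fpct]
  # chord slope of normalized current vs normalized threshold reduction
  hyp_slope <- (iv_red(-100) / 100 - iv_red(-70) / 100)
  hyp_slope <- (-1 - (-0.7)) / hyp_slope

  # --- recovery cycle
  supra <- 2 * thr0
  n_c <- round(1 / dt)
  rc_rows <- threshold_profile(
    model,
    cond = c(rep(supra, n_c), rep(0, round(max(rc_intervals) / dt))),
    t_tests = rc_intervals, width = width, guess = thr0)
  rc <- data.frame(interval = rc_rows$t_test,
                   change = 100 * (rc_rows$threshold - thr0) / thr0)
  cooled <- model$params$temperature < 30
  refr_int <- if (cooled) 3.2 else 2.5
  refractoriness <- rc$change[match(refr_int, rc$interval)]
  if (is.na(refractoriness)) {        # interpolate across undefined points
    ok <- is.finite(rc$change)
    refractoriness <- stats::approx(rc$interval[ok], rc$change[ok],
                                    xout = refr_int, rule = 2)$y
  }
  superex <- min(rc$change, na.rm = TRUE)
  i_sup <- which.min(rc$change)
  subex <- if (i_sup < nrow(rc)) {
    max(rc$change[(i_sup + 1L):nrow(rc)], na.rm = TRUE)
  } else 0
  # relative refractory period: first positive-to-negative crossing
  rrp <- NA_real_
  for (i in seq_len(nrow(rc) - 1L)) {
    if (is.na(rc$change[i]) || is.na(rc$change[i + 1L])) next
    if (rc$change[i] > 0 && rc$change[i + 1L] <= 0) {
      rrp <- rc$interval[i] + (rc$interval[i + 1L] - rc$interval[i]) *
        rc$change[i] / (rc$change[i] - rc$change[i + 1L])
      break
    }
  }

  indices <- c(
    rheobase = rheobase,
    sdtc = sdtc,
    te_d_10_20 = te_idx(40, c(10, 15, 20)),
    te_d_90_100 = te_idx(40, c(90, 95, 99)),
    te_h_10_20 = te_idx(-40, c(10, 15, 20)),
    te_h_90_100 = te_idx(-40, c(90, 95, 99)),
    te_h_99 = te_idx(-40, 99),
    refractoriness = refractoriness,
    superexcitability = superex,
    subexcitability = subex,
    rrp = rrp,
    iv_80 = iv_red(-80),
    iv_100 = iv_red(-100),
    hyperpol_iv_slope = hyp_slope)
  structure(list(indices = indices, threshold = thr0,
                 resting_potential = model$resting_potential,
                 curves = list(sd = data.frame(width = sd_widths,
                                               threshold = sd_thr,
                                               charge = charge),
                               te = te, iv = iv, rc = rc)),
            class = "net_battery")
}

#' @export
print.net_battery <- function(x, ...) {
  cat(sprintf("NET battery: threshold %.1f pA, resting %.2f mV\n",
              x$threshold, x$resting_potential))
  print(round(x$indices, 3))
  invisible(x)
}

#' Export NET results as tidy CSV
#'
#' One file per protocol curve plus an index row, mirroring a
#' QTRACP-style export.
#'
#' @param battery a [run_net_battery()] result
#' @param dir output directory
#' @param label scenario label used in file names
#' @export
write_net_csv <- function(battery, dir, label = "scenario") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(battery$curves)) {
    utils::write.csv(battery$curves[[nm]],
                     file.path(dir, sprintf("%s_%s.csv", label, nm)),
                     row.names = FALSE)
  }
  idx <- data.frame(index = names(battery$indices),
                    value = unname(battery$indices))
  utils::write.csv(idx, file.path(dir, sprintf("%s_indices.csv", label)),
                   row.names = FALSE)
  invisible(dir)
}
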