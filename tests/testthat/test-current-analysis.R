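test_that("I-V analysis recovers the reversal potential and conductance", {
  # synthetic peaks exactly on a line through (+100, 0)
  v <- seq(-20, 40, 5)
  g <- 0.8
  peaks <- g * (v - 100)
  traces <- lapply(seq_along(v), function(i) {
    tr <- data.frame(time = c(0, 1), voltage = v[i],
                     current = c(peaks[i], peaks[i] / 2))
    structure(tr, class = c("current_trace", "data.frame"),
              sweep_value = v[i])
  })
  iv <- analyze_iv(traces)
  expect_equal(iv$v_na, 100, tolerance = 1e-9)
  expect_equal(iv$g_max, g, tolerance = 1e-9)
  # normalized conductance equals peak/((V-VNa)Gmax) = 1 here
  expect_equal(iv$table$g_norm, rep(1, length(v)), tolerance = 1e-9)
  # current scaled x2: G_max doubles, normalized conductance unchanged
  traces2 <- lapply(traces, function(tr) {
    tr$current <- tr$current * 2
    tr
  })
  iv2 <- analyze_iv(traces2)
  expect_equal(iv2$g_max, 2 * g, tolerance = 1e-9)
  expect_equal(iv2$table$g_norm, iv$table$g_norm, tolerance = 1e-9)
  # simulated WT family recovers the model's erev (+100). The peak
  # conductance still grows ~3% across +10..+40 mV (activation is not
  # fully saturated there), which displaces the x-intercept by ~10 mV;
  # the estimate must land within that systematic envelope.
  prot <- make_protocol("activation_iv", increment = 10,
                        test_duration = 30)
  sim <- run_battery(the_scheme, wt_params, prot, 25)
  ivs <- analyze_iv(sim)
  expect_lt(abs(ivs$v_na - 100), 15)
  expect_gt(ivs$g_max, 0)
})

test_that("Boltzmann fitting recovers generating parameters", {
  v <- seq(-90, 30, 5)
  # noiseless activation curve with the reported WT parameters
  y <- 1 / (1 + exp((-21.8 - v) / 8.3))
  fit <- fit_boltzmann(v, y, form = "activation")
  expect_lt(abs(fit$vh - (-21.8)), 0.01)
  expect_lt(abs(fit$k - 8.3), 0.01)
  # signed-k single form: inactivation curve has negative k
  v2 <- seq(-140, -30, 5)
  y2 <- 1 / (1 + exp((-85.7 - v2) / (-12.5)))
  fit2 <- fit_boltzmann(v2, y2, form = "inactivation")
  expect_lt(abs(fit2$vh - (-85.7)), 0.01)
  expect_lt(abs(fit2$k - (-12.5)), 0.01)
  # half-point definition: y = 0.5 exactly at vh
  expect_equal(predict(fit, fit$vh), 0.5, tolerance = 1e-9)
  expect_error(fit_boltzmann(v, rep(0.5, length(v))), "flat")
})

test_that("Boltzmann fit is unbiased at sigma = 0.02 over 100 replicates", {
  v <- seq(-90, 50, 5)                      # 29 voltages
  ds <- generate_curve_dataset("boltzmann", list(vh = -21.8, k = 8.3),
                               v, noise_model(sigma = 0.02, seed = 42L),
                               n_replicates = 100L)
  vhs <- vapply(ds$replicates, function(d) {
    fit_boltzmann(d$x, d$y, form = "activation")$vh
  }, numeric(1L))
  expect_lt(abs(mean(vhs) - (-21.8)), 0.5)
})

test_that("window curve multiplies the two fitted curves", {
  v <- seq(-120, 40, 5)
  act <- fit_boltzmann(v, 1 / (1 + exp((-21.8 - v) / 8.3)), "activation")
  inact <- fit_boltzmann(v, 1 / (1 + exp((-85.7 - v) / (-12.5))),
                         "inactivation")
  w <- window_curve(act, inact)
  # independent evaluation of both Boltzmann forms at -80 mV
  direct <- (1 / (1 + exp((-21.8 + 80) / 8.3))) *
    (1 / (1 + exp((-85.7 + 80) / (-12.5))))
  expect_equal(unname(w$spots["-80mV"]), direct, tolerance = 1e-6)
  expect_equal(direct, 3.5e-4, tolerance = 0.05)
  expect_gt(w$area, 0)
  expect_true(all(w$product >= 0 & w$product <= 1))
  # inactivation ~ 1 everywhere reduces the product to the activation curve
  flat <- inact
  flat$vh <- 500
  w2 <- window_curve(act, flat, grid = v)
  expect_equal(w2$product, predict(act, v), tolerance = 1e-3)
})

test_that("each mutant's window product exceeds WT at the four spot voltages", {
  # fitted-curve products from the reported 25 C Boltzmann parameters
  pars <- list(
    WT = list(act = c(-21.8, 8.3), inact = c(-85.7, -12.5)),
    I136V = list(act = c(-27.5, 7.7), inact = c(-80.5, -12.8)),
    I848T = list(act = c(-32.6, 7.6), inact = c(-73.5, -12.5)),
    V1316A = list(act = c(-34.04, 8.7), inact = c(-77.1, -11.9)))
  spot <- function(p) {
    v <- c(-20, -40, -60, -80)
    act <- 1 / (1 + exp((p$act[1L] - v) / p$act[2L]))
    inact <- 1 / (1 + exp((p$inact[1L] - v) / p$inact[2L]))
    act * inact
  }
  wt <- spot(pars$WT)
  for (mut in c("I136V", "I848T", "V1316A")) {
    expect_true(all(spot(pars[[mut]]) > wt), info = mut)
  }
})

test_that("sustained/peak ratio behaves per definition", {
  # constant current -> ratio 1
  tr <- structure(data.frame(time = seq(0, 100, 0.5), voltage = 10,
                             current = -3),
                  class = c("current_trace", "data.frame"))
  expect_equal(sustained_ratio(tr), 1)
  # mono-exponential decay tau = 10 ms from peak at t = 0:
  # mean over [90, 95] = tau/5 (e^-9 - e^-9.5) ~ e^-9.25 * sinh(.25)/.25
  t <- seq(0, 100, 0.01)
  tr2 <- structure(data.frame(time = t, voltage = 10,
                              current = -exp(-t / 10)),
                   class = c("current_trace", "data.frame"))
  closed <- (10 / 5) * (exp(-9) - exp(-9.5))
  expect_equal(sustained_ratio(tr2), closed, tolerance = 1e-4)
  # simulated IEM sweeps have larger sustained fraction than WT
  for (v in c(10, 20, 30)) {
    seg <- data.frame(level = v, duration = 100)
    wt <- simulate_sweep(the_scheme, wt_params, seg, 25,
                         p0 = hold_state(wt_params))
    iem <- simulate_sweep(the_scheme, iem_params, seg, 25,
                          p0 = hold_state(iem_params, -120, 25))
    expect_gt(sustained_ratio(iem), sustained_ratio(wt))
  }
})

test_that("resurgent metrics are scale invariant and locate the hump", {
  prot <- make_protocol("resurgent", test_duration = 60)
  traces <- run_battery(the_scheme, wt_params, prot, 25)
  ref <- run_battery(the_scheme, wt_params,
                     make_protocol("activation_iv", v_min = -20,
                                   v_max = -20, test_duration = 60), 25)[[1L]]
  met <- resurgent_metrics(traces, ref)
  tb <- met$table
  expect_equal(tb$voltage, c(-20, -30, -40, -50, -60))
  expect_true(all(tb$ratio > 0))
  expect_true(all(tb$time_to_peak > 0, na.rm = TRUE))
  expect_true(all(tb$tau_decay > 0, na.rm = TRUE))
  expect_true(all(tb$charge_ratio > 0))
  # scaling every current by c leaves all ratios and taus unchanged
  sc_traces <- lapply(traces, function(tr) {
    tr$current <- 3.7 * tr$current
    tr
  })
  sc_ref <- ref
  sc_ref$current <- 3.7 * sc_ref$current
  met2 <- resurgent_metrics(sc_traces, sc_ref)
  expect_equal(met2$table$ratio, tb$ratio, tolerance = 1e-9)
  expect_equal(met2$table$charge_ratio, tb$charge_ratio, tolerance = 1e-9)
  expect_equal(met2$table$tau_decay, tb$tau_decay, tolerance = 1e-5)
})

test_that("exponential decay tau self-recovers from an exact exponential", {
  t <- seq(0, 50, 0.01)
  tau_true <- 7.3
  y <- 2.4 * exp(-t / tau_true) + 0.1
  expect_equal(resurgentsim:::fit_exp_decay(t, y), tau_true,
               tolerance = 1e-6)
})

test_that("decay-voltage regression is exact on log-linear data", {
  v <- c(-20, -30, -40, -50, -60)
  # constant tau -> k = 0, A = 1/tau
  fit <- fit_decay_voltage_regression(v, rep(4, 5L))
  expect_equal(fit$k, 0, tolerance = 1e-12)
  expect_equal(fit$A, 0.25, tolerance = 1e-12)
  # generated from (A*, k*) -> exact recovery
  A_true <- 0.18
  k_true <- 1.4
  tau <- 1 / (A_true * exp(k_true * v / 25))
  fit2 <- fit_decay_voltage_regression(v, tau)
  expect_equal(fit2$A, A_true, tolerance = 1e-10)
  expect_equal(fit2$k, k_true, tolerance = 1e-10)
  expect_error(fit_decay_voltage_regression(v, c(-1, 1, 1, 1, 1)),
               "positive")
})

test_that("prepulse-decay fit recovers (tau, f0) and flags flat data", {
  d <- c(2, 5, 10, 20, 50, 100, 200, 500)
  y <- (1 - 0.4) * exp(-d / 64.2) + 0.4
  fit <- fit_prepulse_decay(d, y)
  expect_equal(fit$tau, 64.2, tolerance = 1e-6)
  expect_equal(fit$f0, 0.4, tolerance = 1e-6)
  flat <- fit_prepulse_decay(d, rep(0.4, length(d)))
  expect_true(flat$degenerate)
  expect_equal(flat$f0, 0.4)
  expect_true(is.na(flat$tau))
  # unbiased f0 at sigma = 0.02 over seeded replicates
  ds <- generate_curve_dataset("prepulse_decay",
                               list(tau = 64.2, f0 = 0.4), d,
                               noise_model(sigma = 0.02, seed = 7L),
                               n_replicates = 50L)
  f0s <- vapply(ds$replicates, function(r) {
    fit_prepulse_decay(r$x, r$y)$f0
  }, numeric(1L))
  expect_lt(abs(mean(f0s) - 0.4), 0.05)
})

test_that("recovery fit recovers tau and the reported reference values", {
  g <- seq(0.2, 12, 0.2)
  fit <- fit_recovery(g, 1 - exp(-g / 1.13), v_recovery = -80,
                      temperature = 25)
  expect_equal(fit$tau, 1.13, tolerance = 1e-8)
  fit2 <- fit_recovery(g, 1 - exp(-g / 1.78))
  expect_equal(fit2$tau, 1.78, tolerance = 1e-8)
  expect_error(fit_recovery(g, rep(2, length(g))), "fraction")
})

test_that("mutant-over-WT ratios reproduce the published worked examples", {
  expect_equal(round(ratio_to_wt(0.12, 0.071), 2), 1.69)
  expect_equal(round(ratio_to_wt(0.22, 0.05), 1), 4.4)
  expect_equal(ratio_to_wt(0.37, 0.37), 1)
  expect_error(ratio_to_wt(1, 0), "positive")
})
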