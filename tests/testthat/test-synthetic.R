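test_that("synthetic sweep generation is seeded and collapses at zero noise", {
  prot <- make_protocol("resurgent", levels = c(-40), test_duration = 30)
  # sigma = 0, no jitter, one cell -> bitwise equal to the simulation
  ds0 <- generate_noisy_sweeps(the_scheme, wt_params, prot, 25,
                               noise_model(sigma = 0, gmax_cv = 0),
                               n_cells = 1L)
  expect_identical(ds0$cells[[1L]][[1L]]$current, ds0$clean[[1L]]$current)
  # same seed twice -> identical datasets; different seed -> different
  nm <- noise_model(sigma = 0.02, seed = 11L)
  d1 <- generate_noisy_sweeps(the_scheme, wt_params, prot, 25, nm, 3L)
  d2 <- generate_noisy_sweeps(the_scheme, wt_params, prot, 25, nm, 3L)
  expect_identical(d1$cells, d2$cells)
  d3 <- generate_noisy_sweeps(the_scheme, wt_params, prot, 25,
                              noise_model(sigma = 0.02, seed = 12L), 3L)
  expect_false(identical(d1$cells[[1L]][[1L]]$current,
                         d3$cells[[1L]][[1L]]$current))
  # provenance carries the generating conditions
  expect_identical(d1$provenance$genotype, "WT")
  expect_equal(d1$provenance$sigma, 0.02)
})

test_that("noisy replicates reproduce the noiseless metric within spread", {
  prot <- make_protocol("resurgent", levels = c(-40), test_duration = 60)
  ref_prot <- make_protocol("activation_iv", v_min = -20, v_max = -20,
                            test_duration = 60)
  clean_res <- run_battery(the_scheme, wt_params, prot, 25)
  clean_ref <- run_battery(the_scheme, wt_params, ref_prot, 25)[[1L]]
  # single-sample peaks are upward-biased under noise; the analysis
  # pipeline therefore smooths noisy sweeps, and the noiseless
  # reference is put through the identical pipeline
  truth <- resurgent_metrics(lapply(clean_res, smooth_trace, width_ms = 0.5),
                             smooth_trace(clean_ref, width_ms = 0.5)
                             )$table$ratio[1L]
  ds <- generate_noisy_sweeps(the_scheme, wt_params, prot, 25,
                              noise_model(sigma = 0.02, seed = 5L),
                              n_cells = 5L)
  ref_ds <- generate_noisy_sweeps(the_scheme, wt_params, ref_prot, 25,
                                  noise_model(sigma = 0.02, seed = 5L),
                                  n_cells = 5L)
  per_cell <- vapply(seq_len(5L), function(ic) {
    sm <- lapply(ds$cells[[ic]], smooth_trace, width_ms = 0.5)
    ref_sm <- smooth_trace(ref_ds$cells[[ic]][[1L]], width_ms = 0.5)
    resurgent_metrics(sm, ref_sm)$table$ratio[1L]
  }, numeric(1L))
  sem <- stats::sd(per_cell) / sqrt(5)
  expect_lt(abs(mean(per_cell) - truth), 3 * max(sem, 0.003))
})

test_that("curve datasets honour the generating curve and the clip range", {
  v <- seq(-90, 30, 5)
  ds <- generate_curve_dataset("boltzmann", list(vh = -21.8, k = 8.3), v,
                               noise_model(sigma = 0), 1L)
  expect_equal(ds$replicates[[1L]]$y, 1 / (1 + exp((-21.8 - v) / 8.3)))
  g <- seq(0.5, 10, 0.5)
  ds2 <- generate_curve_dataset("recovery", list(tau = 1.78), g,
                                noise_model(sigma = 0), 1L)
  fit <- fit_recovery(ds2$replicates[[1L]]$x, ds2$replicates[[1L]]$y)
  expect_equal(fit$tau, 1.78, tolerance = 1e-8)
  noisy <- generate_curve_dataset("recovery", list(tau = 1.78), g,
                                  noise_model(sigma = 0.1, seed = 3L), 20L)
  ys <- unlist(lapply(noisy$replicates, `[[`, "y"))
  expect_true(all(ys >= 0 & ys <= 1.05))
  expect_error(generate_curve_dataset("weibull", list(), 1:10), "arg")
})

test_that("Monte-Carlo spread of vh matches the asymptotic standard error", {
  v <- seq(-90, 50, 5)
  ds <- generate_curve_dataset("boltzmann", list(vh = -21.8, k = 8.3), v,
                               noise_model(sigma = 0.02, seed = 21L), 100L)
  fits <- lapply(ds$replicates, function(d) {
    fit_boltzmann(d$x, d$y, form = "activation")
  })
  emp_se <- stats::sd(vapply(fits, function(f) f$vh, numeric(1L)))
  asy_se <- mean(vapply(fits, function(f) f$se[["vh"]], numeric(1L)))
  expect_lt(abs(emp_se - asy_se) / asy_se, 0.5)
})

test_that("full simulate -> noise -> analyze pipeline shows no systematic bias", {
  # paired sign test over seeds on the resurgent charge ratio: charge is
  # a linear functional of the trace, so additive zero-mean noise
  # perturbs it without systematic bias (unlike single-sample peaks)
  prot <- make_protocol("resurgent", levels = c(-40), test_duration = 40)
  ref_prot <- make_protocol("activation_iv", v_min = -20, v_max = -20,
                            test_duration = 40)
  clean_res <- run_battery(the_scheme, wt_params, prot, 25)
  clean_ref <- run_battery(the_scheme, wt_params, ref_prot, 25)[[1L]]
  truth <- resurgent_metrics(clean_res, clean_ref)$table$charge_ratio[1L]
  diffs <- vapply(1:20, function(seed) {
    nm <- noise_model(sigma = 0.02, gmax_cv = 0, seed = seed)
    ds <- generate_noisy_sweeps(the_scheme, wt_params, prot, 25, nm, 1L)
    dr <- generate_noisy_sweeps(the_scheme, wt_params, ref_prot, 25, nm, 1L)
    resurgent_metrics(ds$cells[[1L]],
                      dr$cells[[1L]][[1L]])$table$charge_ratio[1L] - truth
  }, numeric(1L))
  # two-sided exact sign test at alpha = 0.05
  n_pos <- sum(diffs > 0)
  p <- 2 * min(stats::pbinom(n_pos, 20, 0.5),
               1 - stats::pbinom(n_pos - 1L, 20, 0.5))
  expect_gt(p, 0.05)
})

test_that("datasets export to CSV with a JSON provenance sidecar", {
  path <- withr::local_tempfile(fileext = ".csv")
  ds <- generate_curve_dataset("boltzmann", list(vh = -21.8, k = 8.3),
                               seq(-80, 20, 10),
                               noise_model(sigma = 0.02, seed = 1L), 2L)
  write_dataset(ds, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 2L * 11L)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$kind, "boltzmann")
  expect_equal(side$pars$vh, -21.8)
})
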