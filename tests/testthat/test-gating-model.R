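test_that("rate laws evaluate per the exponential Q10 form", {
  # WT alpha at 0 mV, 25 C is the tabulated k0
  expect_equal(evaluate_rate(wt_params$alpha, 0, 25), 100)
  # independent arithmetic: 100 * e^(0.08*25) * 2.1^1 at (25 mV, 35 C)
  expect_equal(evaluate_rate(wt_params$alpha, 25, 35),
               100 * exp(0.08 * 25) * 2.1^1, tolerance = 1e-12)
  # k1 = 0, q10 = 1 collapses to k0 everywhere
  law <- rate_law(3.7, 0, 1)
  for (v in c(-200, -40, 0, 200)) {
    for (T in c(0, 25, 50)) expect_equal(evaluate_rate(law, v, T), 3.7)
  }
  # one Q10 step per 10 degrees, exactly
  expect_equal(evaluate_rate(wt_params$o2i2, -30, 35) /
                 evaluate_rate(wt_params$o2i2, -30, 25),
               wt_params$o2i2$q10)
  expect_error(evaluate_rate(wt_params$alpha, NaN, 25), "finite")
  expect_error(rate_law(-1, 0, 2), ".")
})

test_that("WT and IEM presets carry the published rate table", {
  for (p in list(wt_params, iem_params)) {
    expect_setequal(setdiff(names(p), "label"), RATE_NAMES)
  }
  expect_equal(wt_params$alpha$k0, 100)
  expect_equal(iem_params$alpha$k0, 500)
  expect_equal(wt_params$beta$k0, 0.55)
  expect_equal(iem_params$beta$k0, 4)
  expect_equal(wt_params$o2i2$q10, 2)
  expect_equal(iem_params$o2i2$q10, 3.3)
  expect_equal(wt_params$i2i1$k0, 0.2)
  expect_equal(iem_params$i2i1$k0, 0.12)
  # shared rates identical between genotypes
  for (nm in c("gamma", "delta", "c_on", "c_off", "o_on", "o_off")) {
    expect_equal(wt_params[[nm]], iem_params[[nm]])
  }
})

test_that("parameter sets round-trip through YAML exactly", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_channel_params(iem_params, path)
  back <- read_channel_params(path)
  for (nm in RATE_NAMES) expect_equal(back[[nm]], iem_params[[nm]])
  expect_identical(back$label, "IEM")
})

test_that("generator matrices conserve probability and resolve the scheme", {
  for (params in list(wt_params, iem_params)) {
    for (v in c(-120, -40, 40)) {
      for (T in c(15, 25, 40)) {
        Q <- build_generator(the_scheme, params, v, T)
        expect_lt(max(abs(rowSums(Q))), 1e-10)
        off <- Q
        diag(off) <- 0
        expect_true(all(off >= 0))
      }
    }
  }
  # entries equal multiplier x rate law: spot-check the 3-alpha edge and
  # an element-by-element assembly at (-120 mV, 25 C)
  Q <- build_generator(the_scheme, wt_params, -120, 25)
  r <- evaluate_rates(wt_params, -120, 25)
  expect_equal(Q["C1", "C2"], 3 * r[["alpha"]])
  expect_equal(Q["C2", "C1"], 1 * r[["beta"]])
  hand <- matrix(0, 12, 12, dimnames = dimnames(Q))
  tr <- the_scheme$transitions
  for (i in seq_len(nrow(tr))) {
    hand[tr$from[i], tr$to[i]] <- hand[tr$from[i], tr$to[i]] +
      tr$mult[i] * r[[tr$rate[i]]]
  }
  diag(hand) <- -rowSums(hand)
  expect_equal(Q, hand)
  # unresolvable rate name is a configuration error
  bad <- the_scheme
  bad$transitions$rate[1L] <- "nonexistent"
  expect_error(build_generator(bad, wt_params, 0, 25), "not found")
})

test_that("stationary distribution solves pQ = 0 on the simplex", {
  # two-state toy: occupancy of B = a/(a+b)
  toy <- toy_scheme()
  Q <- build_generator(toy, wt_params, -30, 25)
  a <- evaluate_rate(wt_params$alpha, -30, 25)
  b <- evaluate_rate(wt_params$beta, -30, 25)
  p <- stationary_distribution(Q)
  expect_equal(unname(p["B"]), a / (a + b), tolerance = 1e-10)
  # symmetric rates give 50/50
  Qs <- matrix(c(-1, 1, 1, -1), 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(unname(stationary_distribution(Qs)), c(0.5, 0.5))
  # full scheme at -120 mV: pQ = 0, simplex, resting, non-conducting
  Q <- build_generator(the_scheme, wt_params, -120, 25)
  p <- stationary_distribution(Q)
  expect_lt(max(abs(p %*% Q)), 1e-9)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0))
  expect_lt(sum(p[c("O1", "O2")]), 1e-3)
  # agrees with long-time propagation from a uniform start (10 s)
  pu <- rep(1 / 12, 12)
  prop <- propagate_occupancy(Q, pu, 10000)
  expect_equal(unname(prop[1L, ]), unname(p), tolerance = 1e-7)
  # invariant under state relabeling (row/col permutation)
  perm <- sample(12)
  pp <- stationary_distribution(Q[perm, perm])
  expect_equal(pp[rownames(Q)], p, tolerance = 1e-10)
})

test_that("sweep simulation conserves occupancy and obeys Ohmic driving force", {
  p120 <- hold_state(wt_params)
  # zero conducting occupancy at the reversal potential -> zero current
  tr <- simulate_sweep(the_scheme, wt_params,
                       data.frame(level = 100, duration = 5), 25,
                       p0 = p120, store_occupancy = TRUE)
  expect_lt(max(abs(tr$current)), 1e-12)
  occ <- attr(tr, "occupancy")
  expect_lt(max(abs(rowSums(occ) - 1)), 1e-9)
  # depolarizing step: transient inward current that peaks then decays
  tr <- simulate_sweep(the_scheme, wt_params,
                       data.frame(level = -20, duration = 50), 25,
                       p0 = p120)
  ipk <- which.min(tr$current)
  expect_lt(tr$current[ipk], -0.1)          # inward
  expect_gt(tr$time[ipk], 0)                # delayed peak
  expect_gt(tr$current[length(tr$current)], tr$current[ipk])  # decays
  # current = gmax * popen * (V - erev) exactly
  expect_equal(tr$current, 1 * tr$popen * (tr$voltage - 100))
  # gmax scales currents linearly
  tr2 <- simulate_sweep(the_scheme, wt_params,
                        data.frame(level = -20, duration = 50), 25,
                        p0 = p120, gmax = 2.5)
  expect_equal(tr2$current, 2.5 * tr$current, tolerance = 1e-12)
})

test_that("temperature is inert when all Q10 = 1", {
  flat <- wt_params
  for (nm in RATE_NAMES) flat[[nm]]$q10 <- 1
  p0 <- stationary_distribution(build_generator(the_scheme, flat, -120, 25))
  segs <- data.frame(level = c(40, -40), duration = c(10, 20))
  tr25 <- simulate_sweep(the_scheme, flat, segs, 25, p0 = p0, dt = 0.01)
  tr40 <- simulate_sweep(the_scheme, flat, segs, 40, p0 = p0, dt = 0.01)
  expect_equal(tr25$current, tr40$current, tolerance = 1e-12)
})

test_that("matrix-exponential propagation matches stiff-ODE integration", {
  # oracle equivalence on a representative protocol set; full battery
  # coverage lives in the acceptance suite
  p120 <- hold_state(wt_params)
  segs <- data.frame(level = c(40, -40), duration = c(10, 20))
  tr <- simulate_sweep(the_scheme, wt_params, segs, 25, p0 = p120,
                       dt = 0.1, store_occupancy = TRUE)
  expect_lt(ode_occupancy_error(the_scheme, wt_params, tr, 25, p120), 1e-6)
})

test_that("suppressing the O1->O2 transition abolishes the resurgent hump", {
  for (params in list(wt_params, iem_params)) {
    p0 <- hold_state(params)
    segs <- data.frame(level = c(40, -40), duration = c(10, 100))
    no_res <- params
    no_res$o1o2$k0 <- 1e-12
    hump_above_tail <- function(pp) {
      tr <- simulate_sweep(the_scheme, pp, segs, 25, p0 = p0,
                           store_occupancy = TRUE)
      i <- tr$time > 10.5                # past the instantaneous tail
      list(h = max(abs(tr$current[i])) - abs(tr$current[length(tr$current)]),
           o2 = max(attr(tr, "occupancy")[, "O2"]),
           peak = max(abs(tr$current[i])),
           tail = abs(tr$current[length(tr$current)]))
    }
    ko <- hump_above_tail(no_res)
    intact <- hump_above_tail(params)
    # the O2 pathway carries the hump: without it the residual
    # recovery-reopening overshoot is a small fraction of the intact
    # hump, the O2 state stays essentially unoccupied, and the current
    # relaxes to its steady tail
    expect_lt(ko$h, 0.2 * intact$h)
    expect_lt(ko$o2, 5e-3)
    expect_lt(ko$peak, 1.1 * ko$tail)
    # intact branch shows a clear delayed hump above its own tail
    expect_gt(intact$peak, 1.5 * intact$tail)
  }
})

test_that("scheme validation catches broken topologies", {
  sc <- the_scheme
  sc$transitions <- sc$transitions[-1L, ]   # drop C1->C2, keep C2->C1
  expect_error(validate_scheme(sc), "reversible")
  expect_error(gating_scheme(1), ".")
  # cycle imbalance diagnostic reports the unbalanced squares
  imb <- cycle_imbalance(the_scheme, wt_params, V = -40, T = 25)
  expect_true(length(imb) >= 1L)
  expect_true(any(abs(imb) > 1))      # table is thermodynamically unbalanced
})

test_that("gating schemes round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_gating_scheme(the_scheme, path)
  back <- read_gating_scheme(path)
  expect_identical(back$states, the_scheme$states)
  expect_identical(back$conducting, the_scheme$conducting)
  expect_equal(back$transitions, the_scheme$transitions)
})
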