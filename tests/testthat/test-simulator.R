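test_that("a zero-dose schedule stays at the unstimulated fixed point", {
  sched <- make_schedule("sustained", dose = 0, total_min = 120)
  for (id in c("A1", "B3", "D2")) {
    m <- get_model(id)
    sim <- simulate_model(m, generic_params(m), sched)
    expect_equal(sim$readout, rep(1, length(sim$time)))
    expect_true(all(sim$states == 0))
  }
})

test_that("pool conservation holds along trajectories", {
  sched <- test_schedule()
  for (id in c("B3", "C2", "A1")) {
    m <- get_model(id)
    p <- generic_params(m)
    sim <- simulate_model(m, p, sched)
    hf <- sim$states[, "HF"]; hfr <- sim$states[, "HFR"]
    fr <- if ("FR" %in% m$species) sim$states[, "FR"] else 0
    # free pools are defined by the conservation law, so check bounds
    expect_true(all(hf + hfr <= p["HSPG_tot"] + 1e-6 * p["HSPG_tot"]))
    expect_true(all(hfr + fr <= p["FGFR_tot"] + 1e-6 * p["FGFR_tot"]))
    expect_true(all(sim$states >= -1e-9))
  }
})

test_that("nesting equivalences hold across all stimulation kinds", {
  scheds <- list(
    make_schedule("sustained", 25, total_min = 120),
    make_schedule("multi_pulse", 25, width_min = 3, pause_min = 20,
                  n_pulses = 3),
    make_schedule("mixed_pulse", 25))
  for (fb in c("A", "B")) {
    m1 <- build_model(1, fb); m2 <- build_model(2, fb); m3 <- build_model(3, fb)
    p3 <- generic_params(m3)
    for (sched in scheds) {
      # receptor 3 with w_FR = 0 equals receptor 2
      p3w0 <- replace(p3, "w_FR", 0)
      r3 <- simulate_model(m3, p3w0, sched)$readout
      r2 <- simulate_model(m2, p3w0[m2$params], sched)$readout
      expect_lt(max(abs(r3 - r2)), 1e-6)
      # receptor 2 with k3 = 0 equals receptor 1
      p2k0 <- replace(p3w0[m2$params], "k3", 0)
      r2k0 <- simulate_model(m2, p2k0, sched)$readout
      r1 <- simulate_model(m1, p2k0[m1$params], sched)$readout
      expect_lt(max(abs(r2k0 - r1)), 1e-6)
    }
  }
  # feedback ablation: B with k_nfb = 0 equals A
  mB <- get_model("B3"); mA <- get_model("A3")
  pB <- replace(generic_params(mB), "k_nfb", 0)
  sched <- test_schedule()
  expect_lt(max(abs(simulate_model(mB, pB, sched)$readout -
                    simulate_model(mA, pB[mA$params], sched)$readout)), 1e-6)
})

test_that("halving integrator tolerances leaves the readout unchanged", {
  m <- get_model("B3")
  sched <- test_schedule()
  r1 <- simulate_model(m, b3_truth(), sched, rtol = 1e-6, atol = 1e-8)
  r2 <- simulate_model(m, b3_truth(), sched, rtol = 5e-7, atol = 5e-9)
  expect_lt(max(abs(r1$readout - r2$readout)), 1e-5)
})

test_that("the implicit and explicit integration routes agree", {
  m <- get_model("B3")
  full <- expand_params(m, b3_truth())
  sched <- test_schedule()
  tt <- sample_grid(sched)$time_min
  ros <- .simulate_cpp(unname(full), 3, 1, 0, erknet:::schedule_matrix(sched),
                       tt, 1e-7, 1e-9, 2e6, 0)
  rk <- .simulate_cpp(unname(full), 3, 1, 0, erknet:::schedule_matrix(sched),
                      tt, 1e-7, 1e-9, 2e6, 1)
  expect_lt(max(abs(ros$readout - rk$readout)), 1e-5)
})

test_that("prior draws never produce NaN or Inf outputs", {
  sched <- make_schedule("multi_pulse", 25, width_min = 3, pause_min = 20,
                         n_pulses = 2, total_min = 70)
  set.seed(42)
  for (m in enumerate_models()) {
    pr <- default_prior(m)
    n_ok <- 0
    for (i in 1:200) {
      p <- prior_transform(pr, stats::runif(prior_dim(pr)))
      sim <- tryCatch(simulate_model(m, p, sched, max_steps = 3000),
                      error = function(e) NULL)
      if (!is.null(sim)) {
        n_ok <- n_ok + 1
        expect_true(all(is.finite(sim$readout)) &&
                      all(is.finite(sim$states)))
      }
    }
    expect_gt(n_ok, 0)  # failures are allowed, silence is not
  }
})

test_that("latent states expose pruned species only, plus the signal S", {
  m <- get_model("A1")
  sim <- simulate_model(m, generic_params(m), test_schedule())
  expect_error(latent_states(sim, m, generic_params(m), "FR"),
               "not in model")
  m3 <- get_model("B3")
  p3 <- b3_truth()
  sim3 <- simulate_model(m3, p3, test_schedule())
  ls <- latent_states(sim3, m3, p3)
  expect_equal(ls$S,
               unname(sim3$states[, "HFR"] + p3["w_FR"] * sim3$states[, "FR"]))
  expect_true(all(vapply(ls, function(v) all(v >= -1e-9), logical(1))))
})

test_that("steady-state dose response reflects the receptor architecture", {
  m1 <- get_model("A1"); m2 <- get_model("A2")
  p <- b3_truth()
  doses <- c(0, 0.25, 2.5, 25, 250)
  d1 <- steady_state_dose_response(m1, p[m1$params], doses, t_max = 30000)
  expect_equal(d1$S_ss[1], 0, tolerance = 1e-8)
  expect_true(all(diff(d1$S_ss) >= -1e-8))     # monotone non-decreasing
  d2 <- steady_state_dose_response(m2, p[m2$params], c(doses, 1e4),
                                   t_max = 30000)
  expect_lt(d2$S_ss[nrow(d2)], max(d2$S_ss))   # biphasic: collapses at high dose
})

test_that("HSPG knockout zeroes the pool and nothing else", {
  p <- b3_truth()
  ko <- hspg_knockout(p)
  expect_equal(unname(ko["HSPG_tot"]), 0)
  expect_equal(ko[names(ko) != "HSPG_tot"], p[names(p) != "HSPG_tot"])
  expect_identical(hspg_knockout(ko), ko)  # idempotent

  # no HSPG-independent route for receptor scheme 1
  m1 <- get_model("B1")
  p1 <- generic_params(m1)
  sim <- simulate_model(m1, hspg_knockout(p1), test_schedule())
  expect_equal(sim$readout, rep(1, length(sim$time)))

  # receptor scheme 3 keeps the direct FR route
  m3 <- get_model("B3")
  sim3 <- simulate_model(m3, hspg_knockout(b3_truth()), test_schedule())
  expect_gt(max(sim3$readout), 1.01)
  expect_equal(max(sim3$states[, "HFR"]), 0)
})

test_that("integration failure is reported with the parameter vector", {
  m <- get_model("A1")
  expect_error(simulate_model(m, generic_params(m), test_schedule(),
                              max_steps = 3),
               "integration failed.*k1=")
})
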