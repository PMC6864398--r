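test_that("the Gaussian log-likelihood has its closed forms", {
  m <- get_model("A1")
  p <- generic_params(m)
  sched <- test_schedule()
  sim <- simulate_model(m, p, sched)
  N <- length(sim$time)

  p1 <- replace(p, "sigma", 1)
  ds <- list(erk_dataset(sched, sim$time, sim$readout))
  expect_equal(log_likelihood(m, p1, ds), -(N / 2) * log(2 * pi),
               tolerance = 1e-6)

  p2 <- replace(p, "sigma", 2)
  expect_equal(log_likelihood(m, p1, ds) - log_likelihood(m, p2, ds),
               N * log(2), tolerance = 1e-6)

  # dataset weights multiply
  ds2 <- list(erk_dataset(sched, sim$time, sim$readout, weight = 3))
  expect_equal(log_likelihood(m, p1, ds2), 3 * log_likelihood(m, p1, ds),
               tolerance = 1e-8)

  # unintegrable parameters map to -Inf, not an error
  expect_identical(log_likelihood(m, p1, ds, max_steps = 3), -Inf)
})

test_that("constant likelihood gives the evidence exactly", {
  pr <- prior_spec(c(a = 0.1, b = 0.5), c(a = 10, b = 50))
  r <- ns_run(function(th) -1.25, pr, ns_config(n_live = 50, rng_seed = 3))
  expect_equal(r$logZ, -1.25, tolerance = 1e-6)
  expect_true(r$terminated)
})

test_that("nested sampling recovers a closed-form 1-D evidence", {
  pr <- prior_spec(c(x = -5), c(x = 5), scale = "linear")
  truth <- log((pnorm(5) - pnorm(-5)) / 10)
  r <- ns_run(function(th) dnorm(th[["x"]], log = TRUE), pr,
              ns_config(n_live = 300, rng_seed = 5))
  expect_lt(abs(r$logZ - truth), 3 * r$logZ_err)
})

test_that("nested sampling is deterministic given the seed", {
  pr <- prior_spec(c(x = -5), c(x = 5), scale = "linear")
  ll <- function(th) dnorm(th[["x"]], log = TRUE)
  cfg <- ns_config(n_live = 80, rng_seed = 11)
  r1 <- ns_run(ll, pr, cfg)
  r2 <- ns_run(ll, pr, cfg)
  expect_identical(r1$logZ, r2$logZ)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$log_weights, r2$log_weights)
})

test_that("run invariants: monotone dead likelihoods, shrinking volumes, unit weights", {
  pr <- prior_spec(c(x = -5, y = -5), c(x = 5, y = 5), scale = "linear")
  r <- ns_run(function(th) sum(dnorm(th, log = TRUE)), pr,
              ns_config(n_live = 100, rng_seed = 2))
  dead <- r$logL[seq_len(r$n_dead)]
  expect_true(all(diff(dead) >= 0))
  expect_true(all(diff(r$logX) < 0))
  expect_equal(sum(exp(r$log_weights)), 1, tolerance = 1e-12)
  expect_equal(r$logZ_err, sqrt(r$H / r$n_live))
})

test_that("evidence error bar is consistent with seed-to-seed spread", {
  pr <- prior_spec(c(x = -5), c(x = 5), scale = "linear")
  ll <- function(th) dnorm(th[["x"]], log = TRUE)
  runs <- lapply(1:10, function(s)
    ns_run(ll, pr, ns_config(n_live = 150, rng_seed = s)))
  z <- vapply(runs, `[[`, numeric(1), "logZ")
  err <- mean(vapply(runs, `[[`, numeric(1), "logZ_err"))
  expect_lt(sd(z), 2 * err)
  expect_gt(sd(z), err / 2)
})

test_that("all proposal mechanisms agree on the 1-D toy", {
  pr <- prior_spec(c(x = -5), c(x = 5), scale = "linear")
  truth <- log((pnorm(5) - pnorm(-5)) / 10)
  ll <- function(th) dnorm(th[["x"]], log = TRUE)
  for (prop in c("prior_rejection", "box_rejection", "kde_rejection")) {
    r <- ns_run(ll, pr, ns_config(n_live = 200, rng_seed = 9,
                                  proposal = prop))
    expect_lt(abs(r$logZ - truth), 3 * r$logZ_err)
  }
})

test_that("posterior resampling respects the weights", {
  pr <- prior_spec(c(x = -5), c(x = 5), scale = "linear")
  r <- ns_run(function(th) dnorm(th[["x"]], log = TRUE), pr,
              ns_config(n_live = 300, rng_seed = 13))
  draws <- posterior_resample(r, 500, seed = 1)
  expect_equal(nrow(draws), 500)
  # symmetric posterior: mean within 3 standard errors of 0
  expect_lt(abs(mean(draws)) , 3 * sd(draws) / sqrt(100))

  # a single dominant point yields copies of itself
  r1 <- r
  r1$log_weights <- rep(-Inf, length(r1$log_weights))
  r1$log_weights[42] <- 0
  d1 <- posterior_resample(r1, 20, seed = 2)
  expect_true(all(d1[, 1] == r1$samples[42, 1]))

  r0 <- r
  r0$log_weights <- rep(-Inf, length(r0$log_weights))
  expect_error(posterior_resample(r0, 10), "zero")
})

test_that("maximum_likelihood returns the best recorded point", {
  pr <- prior_spec(c(x = -5), c(x = 5), scale = "linear")
  r <- ns_run(function(th) dnorm(th[["x"]], log = TRUE), pr,
              ns_config(n_live = 300, rng_seed = 17))
  mle <- maximum_likelihood(r)
  expect_true(abs(mle[["x"]]) < 0.5)
  expect_equal(max(r$logL), dnorm(mle[["x"]], log = TRUE))
  draws <- posterior_resample(r, 200, seed = 3)
  expect_true(all(dnorm(draws[, "x"], log = TRUE) <= max(r$logL) + 1e-12))
})

test_that("a stalled constrained sampler raises a diagnostic error", {
  pr <- prior_spec(c(x = 0), c(x = 1), scale = "linear")
  # an acceptable region too small to ever hit once the -Inf plateau must
  # be escaped
  ll <- function(th) if (th[["x"]] < 1e-8) 1 else -Inf
  expect_error(
    ns_run(ll, pr, ns_config(n_live = 20, rng_seed = 1,
                             max_rejections = 50)),
    "stalled")
})

test_that("model-level nested sampling wires the likelihood correctly", {
  # tiny smoke run: loose termination, few live points
  m <- get_model("A1")
  suite <- ideal_suite_seed1()
  pr <- default_prior(m)
  cfg <- ns_config(n_live = 25, rng_seed = 4, proposal = "kde_rejection",
                   evidence_tolerance = 0.5, live_spread_tolerance = 50,
                   max_iter = 400)
  r <- nested_sampling(m, suite$training[1], prior = pr, config = cfg)
  expect_s3_class(r, "ns_result")
  expect_true(is.finite(r$logZ))
  expect_identical(colnames(r$samples), m$params)
})
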