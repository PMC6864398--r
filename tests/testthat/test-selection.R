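# a lightweight hand-built ns_result around a known parameter vector, for
# exercising the selection mechanics without a full sampling run
fake_fit <- function(model, center, n = 60, jitter = 0.01, logZ = 0,
                     seed = 1) {
  set.seed(seed)
  samples <- matrix(rep(center, each = n), nrow = n,
                    dimnames = list(NULL, names(center)))
  samples <- samples * exp(matrix(rnorm(n * length(center), sd = jitter),
                                  nrow = n))
  samples[1, ] <- center
  logL <- c(0, rep(-1, n - 1))  # the exact center is the MLE
  structure(list(logZ = logZ, logZ_err = 0.1, H = 1, n_iter = n,
                 samples = samples, logL = logL,
                 log_weights = rep(log(1 / n), n),
                 logX = -(seq_len(n)) / 10, n_live = 10, n_dead = n,
                 terminated = TRUE, model_id = model$id,
                 config = ns_config(n_live = 10)),
            class = "ns_result")
}

test_that("rank_by_evidence sorts, differences and breaks ties by id", {
  m <- get_model("B3")
  res <- list(B3 = fake_fit(m, b3_truth(), logZ = 10),
              A1 = fake_fit(get_model("A1"), generic_params(get_model("A1")),
                            logZ = -5),
              C3 = fake_fit(get_model("C3"), generic_params(get_model("C3")),
                            logZ = -5))
  rank <- rank_by_evidence(res)
  expect_equal(rank$model, c("B3", "A1", "C3"))  # tie broken alphabetically
  expect_equal(rank$delta_logZ, c(0, 15, 15))

  single <- rank_by_evidence(res["B3"])
  expect_equal(single$delta_logZ, 0)
  expect_error(rank_by_evidence(list(x = structure(list(), class = "ns_failure"))),
               "no successful fits")
})

test_that("fit_all returns one result per model and is reproducible", {
  suite <- ideal_suite_seed1()
  cfg <- ns_config(n_live = 20, rng_seed = 5, proposal = "kde_rejection",
                   evidence_tolerance = 0.5, live_spread_tolerance = 100,
                   max_iter = 150)
  ids <- c("A1", "B3")
  f1 <- fit_all(ids, suite$training[1:2], cfg)
  f2 <- fit_all(ids, suite$training[1:2], cfg)
  expect_named(f1, ids)
  expect_identical(vapply(f1, `[[`, numeric(1), "logZ"),
                   vapply(f2, `[[`, numeric(1), "logZ"))
})

test_that("predict_validation reports envelopes, coverage and RMSE", {
  m <- get_model("B3")
  truth <- b3_truth()
  suite <- ideal_suite_seed1()
  fit <- fake_fit(m, truth, jitter = 0.02)
  val <- predict_validation(m, fit, suite$validation, n_draws = 60, seed = 2)
  expect_named(val, names(suite$validation))
  for (v in val) {
    expect_true(v$rmse >= 0)
    expect_true(v$coverage >= 0 && v$coverage <= 1)
    expect_equal(dim(v$envelope), c(2, length(v$mle_trajectory)))
  }
  # the generating model predicts its own held-out data well
  expect_lt(mean(vapply(val, `[[`, numeric(1), "rmse")), 0.05)

  # a zero-dose validation set is scored against the flat baseline
  zero <- erk_dataset(make_schedule("sustained", 0, total_min = 60),
                      seq(0, 60, 2), rep(1, 31))
  v0 <- predict_validation(m, fit, list(zero), n_draws = 20, seed = 3)
  expect_equal(v0[[1]]$rmse, 0, tolerance = 1e-9)
})

test_that("the MLE trajectory lies inside its own posterior envelope", {
  m <- get_model("B3")
  suite <- ideal_suite_seed1()
  fit <- fake_fit(m, b3_truth(), jitter = 0.02)
  val <- predict_validation(m, fit, suite$validation[1], n_draws = 80,
                            seed = 4)
  v <- val[[1]]
  inside <- mean(v$mle_trajectory >= v$envelope["lo", ] &
                   v$mle_trajectory <= v$envelope["hi", ])
  expect_gte(inside, 0.95)
})

test_that("the HSPG-knockout prediction distinguishes receptor schemes", {
  suite <- ideal_suite_seed1()
  ko <- suite$knockout[[1]]

  # receptor scheme 1: no HSPG-independent route, flat prediction
  m1 <- get_model("B1")
  p1 <- generic_params(m1)
  pred1 <- predict_hspg_knockout(m1, p1, ko)
  expect_equal(pred1$trajectory, rep(1, length(ko$times)))
  expect_true(is.finite(pred1$rmse))  # reported even though visibly wrong

  # the generating model predicts the knockout closely
  m3 <- get_model("B3")
  pred3 <- predict_hspg_knockout(m3, b3_truth(), ko)
  expect_lt(pred3$rmse, 0.05)
  expect_lt(pred3$rmse, pred1$rmse)
})

test_that("selection reports serialize losslessly", {
  m <- get_model("B3")
  suite <- ideal_suite_seed1()
  res <- list(B3 = fake_fit(m, b3_truth(), logZ = 3),
              B1 = fake_fit(get_model("B1"),
                            generic_params(get_model("B1")), logZ = -2))
  rep1 <- selection_report(res, suite$training, suite$validation,
                           suite$knockout, n_draws = 30, seed = 5)
  expect_s3_class(rep1, "selection_report")
  expect_equal(rep1$evidence$model, c("B3", "B1"))
  expect_false(rep1$models$B3$flagged)

  path <- tempfile(fileext = ".json")
  write_selection_report(rep1, path)
  back <- read_selection_report(path)
  expect_equal(back$evidence$logZ, rep1$evidence$logZ)
  expect_equal(back$models$B3$mle, rep1$models$B3$mle)
  expect_equal(back$models$B1$validation_rmse,
               unname(rep1$models$B1$validation_rmse),
               tolerance = 1e-12, ignore_attr = TRUE)
})
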