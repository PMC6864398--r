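#' Fit a set of candidate models by nested sampling
#'
#' One nested-sampling run per model on the shared training datasets.
#' Per-model seeds are derived deterministically from the master seed in
#' `config$rng_seed` and the model's position in the full enumeration, so a
#' batch is reproducible as a whole. Per-model failures are caught and
#' reported, not fatal.
#'
#' @param models list of `candidate_model`s (or character ids).
#' @param training list of [erk_dataset()]s.
#' @param config an [ns_config()]; `rng_seed` acts as the master seed.
#' @param ... passed to [nested_sampling()] (integrator settings, `verbose`).
#' @return Named list of `ns_result` (or `try-error` for failed fits).
#' @export
fit_all <- function(models, training, config = ns_config(), ...) {
  stopifnot(length(models) >= 1, length(training) >= 1)
  if (is.character(models)) models <- lapply(models, get_model)
  ids <- vapply(models, `[[`, character(1), "id")
  names(models) <- ids
  all_ids <- names(enumerate_models(include_positive_feedback = TRUE))
  out <- lapply(ids, function(id) {
    cfg <- config
    cfg$rng_seed <- (config$rng_seed * 1009L + match(id, all_ids)) %% .Machine$integer.max
    tryCatch(nested_sampling(models[[id]], training, config = cfg, ...),
             error = function(e) {
               warning("fit failed for ", id, ": ", conditionMessage(e))
               structure(list(message = conditionMessage(e)),
                         class = "ns_failure")
             })
  })
  stats::setNames(out, ids)
}

#' Rank fitted models by Bayesian evidence
#'
#' @param results named list of `ns_result`s (failed fits are dropped).
#' @return data.frame ordered by decreasing `logZ` with columns `model`,
#'   `logZ`, `logZ_err`, `delta_logZ` (to the best model). Ties are broken by
#'   model id. No model is excluded: the advisory Jeffreys-scale threshold is
#'   a reporting aid, not a filter.
#' @export
rank_by_evidence <- function(results) {
  ok <- vapply(results, inherits, logical(1), "ns_result")
  if (!any(ok)) stop("no successful fits to rank")
  results <- results[ok]
  df <- data.frame(model = names(results),
                   logZ = vapply(results, `[[`, numeric(1), "logZ"),
                   logZ_err = vapply(results, `[[`, numeric(1), "logZ_err"))
  df <- df[order(-df$logZ, df$model), ]
  df$delta_logZ <- max(df$logZ) - df$logZ
  rownames(df) <- NULL
  df
}

.rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

#' Posterior-predictive benchmarking on held-out stimulation schemes
#'
#' For each validation dataset: the maximum-likelihood trajectory and its
#' RMSE, plus a pointwise 2.5-97.5 percent envelope from posterior draws and
#' the fraction of observed points falling inside it (coverage). Simulation
#' failures among posterior draws are counted, not fatal.
#'
#' @param model a `candidate_model`.
#' @param result its `ns_result`.
#' @param validation list of [erk_dataset()]s whose schedules were not used
#'   for training.
#' @param n_draws posterior draws for the envelope (default 500).
#' @param seed seed for the posterior resampling.
#' @return Named list per dataset: `mle_trajectory`, `rmse`, `envelope`
#'   (matrix lo/hi), `coverage`, `n_failed`.
#' @export
predict_validation <- function(model, result, validation, n_draws = 500,
                               seed = 1) {
  stopifnot(inherits(result, "ns_result"))
  mle <- maximum_likelihood(result)
  draws <- posterior_resample(result, n_draws, seed = seed)
  out <- lapply(validation, function(ds) {
    sim_mle <- simulate_model(model, mle, ds$schedule, times = ds$times)
    preds <- matrix(NA_real_, n_draws, length(ds$times))
    n_failed <- 0
    for (i in seq_len(n_draws)) {
      s <- tryCatch(simulate_model(model,
                                   stats::setNames(draws[i, ], colnames(draws)),
                                   ds$schedule, times = ds$times),
                    error = function(e) NULL)
      if (is.null(s)) n_failed <- n_failed + 1 else preds[i, ] <- s$readout
    }
    keep <- stats::complete.cases(preds)
    env <- apply(preds[keep, , drop = FALSE], 2, stats::quantile,
                 probs = c(0.025, 0.975))
    rownames(env) <- c("lo", "hi")
    cover <- mean(ds$values >= env["lo", ] & ds$values <= env["hi", ])
    list(mle_trajectory = sim_mle$readout,
         rmse = .rmse(ds$values, sim_mle$readout),
         envelope = env, coverage = cover, n_failed = n_failed)
  })
  stats::setNames(out, vapply(validation, function(d)
    if (nzchar(d$name)) d$name else "dataset", character(1)))
}

#' Predict the HSPG-knockout perturbation
#'
#' Simulates the model with the HSPG pool set to zero at the
#' maximum-likelihood estimate from training (the posterior envelope is
#' deliberately not used here) and reports the trajectory and its RMSE
#' against the observed perturbed dataset. The RMSE is reported even when the
#' prediction is visibly wrong - that is the point of the comparison.
#'
#' @param model a fitted `candidate_model`.
#' @param mle named maximum-likelihood parameter vector.
#' @param observed an [erk_dataset()] measured under the perturbation (its
#'   schedule is used for the simulation).
#' @return List with `trajectory` and `rmse`.
#' @export
predict_hspg_knockout <- function(model, mle, observed) {
  sim <- simulate_model(model, hspg_knockout(mle), observed$schedule,
                        times = observed$times)
  list(trajectory = sim$readout, rmse = .rmse(observed$values, sim$readout))
}

#' Full model-selection report
#'
#' Runs the selection workflow over fitted results: evidence ranking,
#' training RMSE of each maximum-likelihood fit, held-out prediction metrics
#' and the HSPG-knockout RMSE. Exclusion is advisory only: `delta_logZ`
#' above `advisory_threshold` (default 10, about decisive on the Jeffreys
#' scale) flags a model, mirroring a human-in-the-loop inspection step as a
#' reported table.
#'
#' @param results named list of `ns_result`s from [fit_all()].
#' @param training,validation,knockout dataset lists.
#' @param n_draws posterior draws for envelopes.
#' @param advisory_threshold `delta_logZ` flag level.
#' @param seed seed for posterior resampling.
#' @return An object of class `selection_report`: list with `evidence`
#'   (ranking data.frame), `models` (per-model metrics) and `settings`.
#' @export
selection_report <- function(results, training, validation = list(),
                             knockout = list(), n_draws = 200,
                             advisory_threshold = 10, seed = 1) {
  rank <- rank_by_evidence(results)
  per_model <- lapply(rank$model, function(id) {
    res <- results[[id]]
    model <- get_model(id)
    mle <- maximum_likelihood(res)
    train_rmse <- vapply(training, function(ds) {
      sim <- simulate_model(model, mle, ds$schedule, times = ds$times)
      .rmse(ds$values, sim$readout)
    }, numeric(1))
    val <- if (length(validation))
      predict_validation(model, res, validation, n_draws = n_draws,
                         seed = seed) else NULL
    ko <- if (length(knockout))
      lapply(knockout, function(ds) predict_hspg_knockout(model, mle, ds))
    else NULL
    list(id = id, mle = mle,
         train_rmse = train_rmse,
         validation_rmse = if (!is.null(val))
           vapply(val, `[[`, numeric(1), "rmse") else NULL,
         validation_coverage = if (!is.null(val))
           vapply(val, `[[`, numeric(1), "coverage") else NULL,
         knockout_rmse = if (!is.null(ko))
           vapply(ko, `[[`, numeric(1), "rmse") else NULL,
         flagged = rank$delta_logZ[rank$model == id] > advisory_threshold)
  })
  structure(list(evidence = rank,
                 models = stats::setNames(per_model, rank$model),
                 settings = list(n_draws = n_draws,
                                 advisory_threshold = advisory_threshold,
                                 seed = seed)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("selection_report over", nrow(x$evidence), "models\n")
  df <- x$evidence
  df$mean_val_rmse <- vapply(df$model, function(id) {
    v <- x$models[[id]]$validation_rmse
    if (is.null(v)) NA_real_ else mean(v)
  }, numeric(1))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Serialize / restore a selection report as JSON
#'
#' @param report a `selection_report`.
#' @param path output JSON path.
#' @export
write_selection_report <- function(report, path) {
  stopifnot(inherits(report, "selection_report"))
  out <- unclass(report)
  # named vectors must become JSON objects, not bare arrays
  out$models <- lapply(out$models, function(m) {
    m$mle <- as.list(m$mle)
    m
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_selection_report
#' @export
read_selection_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$models <- lapply(x$models, function(m) {
    m$mle <- unlist(m$mle)
    m
  })
  structure(x, class = "selection_report")
}
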