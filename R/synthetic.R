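#' Reference ground-truth parameters for model B3
#'
#' A committed, synthetic reference parameter set for the competitive
#' joint-activation receptor layer with ERK-driven negative feedback (model
#' B3), chosen once so that the simulated phenomenology matches the
#' qualitative behaviors the experimental system shows: an initial ERK
#' transient with mild adaptation under sustained low dose and strong
#' adaptation under sustained high dose, in-phase ERK pulses under 2.5 ng/ml
#' multi-pulse stimulation, anti-phase pulses under 250 ng/ml multi-pulse
#' stimulation, and a reduced-amplitude in-phase response at 250 ng/ml after
#' HSPG knockout. It is a synthetic stand-in fixture, not a published
#' estimate. Stored as plain JSON under `inst/extdata/`.
#'
#' @return Named numeric vector over model B3's free parameters.
#' @export
b3_reference_params <- function() {
  path <- system.file("extdata", "b3_reference_params.json",
                      package = "erknet")
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  unlist(p)
}

#' Specification of a synthetic single-cell population
#'
#' Cell-to-cell heterogeneity emulates variability in the expression of
#' signaling components: each cell's values for a designated parameter subset
#' (pool totals and cascade activation gains by default) are multiplied by
#' independent lognormal factors with mean 1 and coefficient of variation
#' `heterogeneity_cv`. Additive Gaussian measurement noise is applied to the
#' ratio readout, and each trajectory is then normalized to its own baseline
#' mean, as the measured data would be.
#'
#' @param model_id candidate model id (default `"B3"`).
#' @param params ground-truth free parameters (default
#'   [b3_reference_params()]).
#' @param n_cells number of cells (>= 1).
#' @param heterogeneity_cv lognormal CV of the per-cell parameter multipliers
#'   (>= 0; default 0.2, an order-of-magnitude choice for expression
#'   variability).
#' @param noise_sd additive Gaussian noise s.d. on the ratio (default 0.02).
#' @param schedule a `pulse_schedule`.
#' @param heterogeneous_params which parameters vary between cells; default
#'   the pool totals and cascade gains present in the model.
#' @param rng_seed integer seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(model_id = "B3", params = b3_reference_params(),
                            n_cells = 50, heterogeneity_cv = 0.2,
                            noise_sd = 0.02, schedule,
                            heterogeneous_params = NULL, rng_seed = 1) {
  stopifnot(n_cells >= 1, heterogeneity_cv >= 0, noise_sd >= 0,
            inherits(schedule, "pulse_schedule"))
  model <- get_model(model_id)
  if (is.null(heterogeneous_params))
    heterogeneous_params <- intersect(
      c("HSPG_tot", "FGFR_tot", "NFB_tot",
        "k_act_Ras", "k_act_Raf", "k_act_MEK", "k_act_ERK"),
      model$params)
  stopifnot(all(heterogeneous_params %in% model$params))
  structure(list(model_id = model_id, params = params,
                 n_cells = as.integer(n_cells),
                 heterogeneity_cv = heterogeneity_cv, noise_sd = noise_sd,
                 schedule = schedule,
                 heterogeneous_params = heterogeneous_params,
                 rng_seed = as.integer(rng_seed)),
            class = "population_spec")
}

#' Generate a heterogeneous single-cell trajectory population
#'
#' Per cell: draw lognormal parameter multipliers, simulate the model, add
#' Gaussian measurement noise, and normalize to the cell's own baseline mean.
#' Cells whose perturbed parameters make the integration fail are redrawn
#' (the count is recorded in the `redraws` attribute). Seeded and
#' reproducible.
#'
#' @param spec a [population_spec()].
#' @return A `trajectory_set` with treatment metadata from the spec.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  model <- get_model(spec$model_id)
  set.seed(spec$rng_seed)
  grid <- sample_grid(spec$schedule)
  tt <- grid$time_min
  cv <- spec$heterogeneity_cv
  sdlog <- sqrt(log(1 + cv^2))
  vals <- matrix(NA_real_, spec$n_cells, length(tt))
  redraws <- 0
  for (i in seq_len(spec$n_cells)) {
    repeat {
      p <- spec$params
      if (cv > 0) {
        mult <- stats::rlnorm(length(spec$heterogeneous_params),
                              meanlog = -sdlog^2 / 2, sdlog = sdlog)
        p[spec$heterogeneous_params] <- p[spec$heterogeneous_params] * mult
      }
      sim <- tryCatch(simulate_model(model, p, spec$schedule),
                      error = function(e) NULL)
      if (!is.null(sim)) break
      redraws <- redraws + 1
      if (redraws > 50 * spec$n_cells)
        stop("too many failed cell simulations")
    }
    r <- sim$readout + stats::rnorm(length(tt), sd = spec$noise_sd)
    base <- tt <= spec$schedule$baseline_min
    bmean <- mean(r[base])
    vals[i, ] <- if (bmean > 0) r / bmean else r
  }
  dose <- max(spec$schedule$episodes$dose, 0)
  meta <- data.frame(cell_id = sprintf("cell_%03d", seq_len(spec$n_cells)),
                     treatment = spec$model_id, dose_ng_ml = dose)
  out <- trajectory_set(vals, tt, meta)
  attr(out, "redraws") <- redraws
  out
}

# the canonical stimulation suite used for training/validation/knockout
.suite_schedules <- function() {
  list(
    train_sustained_2.5 = make_schedule("sustained", 2.5, total_min = 160),
    train_sustained_250 = make_schedule("sustained", 250, total_min = 160),
    train_pulse_2.5 = make_schedule("multi_pulse", 2.5, width_min = 3,
                                    pause_min = 20, n_pulses = 4),
    train_pulse_250 = make_schedule("multi_pulse", 250, width_min = 3,
                                    pause_min = 20, n_pulses = 4),
    valid_single5_2.5 = make_schedule("single_pulse", 2.5, width_min = 5,
                                      total_min = 100),
    valid_single5_250 = make_schedule("single_pulse", 250, width_min = 5,
                                      total_min = 100),
    valid_mixed_250 = make_schedule("mixed_pulse", 250),
    ko_pulse_250 = make_schedule("multi_pulse", 250, width_min = 3,
                                 pause_min = 20, n_pulses = 4))
}

#' Generate the training / validation / knockout dataset suite
#'
#' Emulates the experimental design: four training conditions (sustained and
#' multi-pulse stimulation at 2.5 and 250 ng/ml), three held-out validation
#' conditions (5-minute single pulses at both doses and the mixed
#' 3'/30'/20'/60'/5' scheme at 250 ng/ml), and one perturbation condition
#' (multi-pulse 250 ng/ml with the HSPG pool set to zero). Each dataset is
#' the population average of a generated single-cell population.
#'
#' @param params ground-truth free parameters for `model_id`.
#' @param model_id candidate model id (default `"B3"`).
#' @param n_cells cells per condition (default 20).
#' @param heterogeneity_cv,noise_sd passed to [population_spec()].
#' @param seed master integer seed; per-condition seeds are derived from it.
#' @return List with elements `training`, `validation`, `knockout` (lists of
#'   [erk_dataset()]), plus `populations` (the underlying trajectory sets).
#' @export
generate_training_suite <- function(params = b3_reference_params(),
                                    model_id = "B3", n_cells = 20,
                                    heterogeneity_cv = 0.2, noise_sd = 0.02,
                                    seed = 1) {
  sch <- .suite_schedules()
  pops <- list()
  mk <- function(name, p, idx) {
    spec <- population_spec(model_id = model_id, params = p,
                            n_cells = n_cells,
                            heterogeneity_cv = heterogeneity_cv,
                            noise_sd = noise_sd, schedule = sch[[name]],
                            rng_seed = seed * 131L + idx)
    pop <- generate_population(spec)
    pops[[name]] <<- pop
    erk_dataset(sch[[name]], pop$time, colMeans(pop$values), name = name)
  }
  nm <- names(sch)
  training <- lapply(seq_len(4), function(i) mk(nm[i], params, i))
  names(training) <- nm[1:4]
  validation <- lapply(5:7, function(i) mk(nm[i], params, i))
  names(validation) <- nm[5:7]
  knockout <- list(mk(nm[8], hspg_knockout(params), 8L))
  names(knockout) <- nm[8]
  list(training = training, validation = validation, knockout = knockout,
       populations = pops, schedules = sch)
}

#' Likelihood-consistent dataset suite for inference benchmarking
#'
#' Generates the same 4 training / 3 validation / 1 knockout conditions as
#' [generate_training_suite()], but as direct model simulations plus i.i.d.
#' Gaussian noise of standard deviation `noise_sd` - exactly the observation
#' model the Gaussian likelihood assumes. [generate_training_suite()]
#' emulates measured data more closely (per-cell heterogeneity, noise, then
#' baseline normalization), but the normalization step introduces a small
#' correlated scale error that a well-specified-likelihood benchmark (e.g.
#' parameter-recovery coverage) must not contain; this variant is the one to
#' use there.
#'
#' @param params ground-truth free parameters.
#' @param model_id candidate model id (default `"B3"`).
#' @param noise_sd additive Gaussian noise s.d. (default 0.02).
#' @param seed integer seed.
#' @return List with `training`, `validation`, `knockout` dataset lists and
#'   `schedules`.
#' @export
generate_ideal_suite <- function(params = b3_reference_params(),
                                 model_id = "B3", noise_sd = 0.02, seed = 1) {
  model <- get_model(model_id)
  sch <- .suite_schedules()
  set.seed(seed)
  mk <- function(name, p) {
    sim <- simulate_model(model, p, sch[[name]])
    erk_dataset(sch[[name]], sim$time,
                sim$readout + stats::rnorm(length(sim$time), sd = noise_sd),
                name = name)
  }
  nm <- names(sch)
  training <- stats::setNames(lapply(nm[1:4], mk, p = params), nm[1:4])
  validation <- stats::setNames(lapply(nm[5:7], mk, p = params), nm[5:7])
  knockout <- stats::setNames(list(mk(nm[8], hspg_knockout(params))), nm[8])
  list(training = training, validation = validation, knockout = knockout,
       schedules = sch)
}

#' Two diverging noisy populations (separability benchmark fixture)
#'
#' Two Gaussian-noise trajectory populations on `t` in `[0, t_end]` with
#' interval `dt` (defaults 100 trajectories each, 51 timepoints). Population
#' A has mean 0 throughout; population B's mean ramps linearly from 0 to
#' `mean_separation`, so the per-timepoint separation grows over time.
#'
#' @param n_per_pop trajectories per population (default 100).
#' @param t_end,dt time range and step (defaults 5 and 0.1).
#' @param mean_separation final mean offset of population B.
#' @param noise_sd i.i.d. Gaussian noise s.d. (default 0.2).
#' @param seed integer seed.
#' @return List of two `trajectory_set`s, `a` and `b`.
#' @export
generate_ev2b_fixture <- function(n_per_pop = 100, t_end = 5, dt = 0.1,
                                  mean_separation = 1, noise_sd = 0.2,
                                  seed = 1) {
  set.seed(seed)
  tt <- seq(0, t_end, by = dt)
  ramp <- seq(0, mean_separation, length.out = length(tt))
  mk <- function(mu, label) {
    vals <- matrix(stats::rnorm(n_per_pop * length(tt), sd = noise_sd),
                   n_per_pop, length(tt), byrow = TRUE)
    vals <- sweep(vals, 2, mu, "+")
    trajectory_set(vals, tt,
                   data.frame(cell_id = sprintf("%s_%03d", label,
                                                seq_len(n_per_pop)),
                              treatment = label, dose_ng_ml = NA_real_))
  }
  list(a = mk(rep(0, length(tt)), "a"), b = mk(ramp, "b"))
}

# archetypal trajectory shapes on a 0..100 min grid (2-min step, 40-min
# baseline), mimicking transient / sustained / rebound cluster prototypes
.cluster_template <- function(shape, tt, baseline = 40) {
  s <- numeric(length(tt))
  post <- tt > baseline
  x <- tt[post] - baseline
  s[post] <- switch(shape,
    transient = 0.6 * (x / 6) * exp(1 - x / 6),
    sustained = 0.6 * (1 - exp(-x / 8)),
    rebound = 0.6 * (x / 6) * exp(1 - x / 6) +
      0.4 * (1 - exp(-pmax(x - 25, 0) / 15)),
    stop("unknown template: ", shape))
  1 + s
}

#' Planted two-cluster trajectory fixture
#'
#' A labeled mixture of two archetypal trajectory shapes (`"transient"`,
#' `"sustained"`, `"rebound"`) with additive Gaussian noise, for validating
#' clustering.
#'
#' @param n_a,n_b cells per group (either may be 0).
#' @param shape_a,shape_b template names.
#' @param noise_sd additive noise s.d. (default 0.02).
#' @param seed integer seed.
#' @return List with `set` (a `trajectory_set`) and `labels` (integer 1/2).
#' @export
generate_two_cluster_fixture <- function(n_a = 30, n_b = 30,
                                         shape_a = "transient",
                                         shape_b = "sustained",
                                         noise_sd = 0.02, seed = 1) {
  set.seed(seed)
  tt <- seq(0, 100, by = 2)
  n <- n_a + n_b
  if (n < 1) stop("need at least one cell")
  templates <- rbind(
    if (n_a > 0) matrix(rep(.cluster_template(shape_a, tt), n_a),
                        n_a, byrow = TRUE),
    if (n_b > 0) matrix(rep(.cluster_template(shape_b, tt), n_b),
                        n_b, byrow = TRUE))
  vals <- templates + matrix(stats::rnorm(n * length(tt), sd = noise_sd),
                             n, length(tt))
  labels <- c(rep(1L, n_a), rep(2L, n_b))
  set <- trajectory_set(vals, tt,
                        data.frame(cell_id = sprintf("cell_%03d", seq_len(n)),
                                   treatment = c(rep(shape_a, n_a),
                                                 rep(shape_b, n_b)),
                                   dose_ng_ml = NA_real_))
  list(set = set, labels = labels)
}
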