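#' Simulate a candidate model over a stimulation schedule
#'
#' Integrates the model ODEs from the unstimulated fixed point (all complexes
#' and active fractions zero; free pools at their totals) with an adaptive
#' Runge-Kutta 5(4) scheme that restarts exactly at every pulse edge, and
#' returns the states and the normalized FRET-ratio readout
#' `r(t) = 1 + rho * EKARp(t)` on the schedule's output grid. Starting at the
#' fixed point means `r(t) = 1` throughout the baseline, matching trajectories
#' normalized to their pre-stimulation mean.
#'
#' @param model a `candidate_model`.
#' @param params named free-parameter vector (see [expand_params()]).
#' @param schedule a `pulse_schedule`.
#' @param times optional output times (minutes); default the schedule grid.
#' @param rtol,atol integrator tolerances.
#' @param max_steps step budget before the run is declared failed.
#' @return A `sim_result`: list with `time`, `states` (matrix, one column per
#'   model species) and `readout`.
#' @examples
#' m <- get_model("A1")
#' p <- c(k1 = 0.02, k_1 = 0.05, k2 = 1, k_2 = 0.25, HSPG_tot = 1,
#'        FGFR_tot = 1, k_act_Ras = 2, Km_Ras = 0.3, d_Ras = 1,
#'        k_act_Raf = 2, Km_Raf = 0.3, d_Raf = 1, k_act_MEK = 2,
#'        Km_MEK = 0.3, d_MEK = 1, k_act_ERK = 2, Km_ERK = 0.3, d_ERK = 1,
#'        k_f = 2, Km_f = 0.5, k_r = 1, Km_r = 0.5, rho = 1, sigma = 0.02)
#' s <- simulate_model(m, p, make_schedule("sustained", 25, total_min = 120))
#' range(s$readout)
#' @export
simulate_model <- function(model, params, schedule, times = NULL,
                           rtol = 1e-6, atol = 1e-8, max_steps = 50000) {
  stopifnot(inherits(model, "candidate_model"),
            inherits(schedule, "pulse_schedule"))
  full <- expand_params(model, params)
  if (is.null(times)) times <- sample_grid(schedule)$time_min
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  res <- .simulate_cpp(unname(full), model$receptor, model$feedback_code,
                       as.integer(model$positive_feedback),
                       schedule_matrix(schedule), times,
                       rtol = rtol, atol = atol, max_steps = max_steps)
  if (res$status != 0)
    stop("integration failed for model ", model$id, " with parameters: ",
         paste(sprintf("%s=%.4g", names(params), params), collapse = ", "))
  states <- res$states
  colnames(states) <- .SPECIES
  states <- states[, model$species, drop = FALSE]
  structure(list(time = times, states = states, readout = res$readout,
                 model_id = model$id, schedule = schedule),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result:", x$model_id, "-", length(x$time), "timepoints,",
      ncol(x$states), "species; readout range",
      sprintf("[%.4f, %.4f]", min(x$readout), max(x$readout)), "\n")
  invisible(x)
}

#' Latent per-species trajectories of a simulation
#'
#' Returns the named species trajectories plus the derived total receptor
#' signaling activity `S` (see [receptor_signal()]).
#'
#' @param result a `sim_result`.
#' @param model the `candidate_model` that produced it.
#' @param params the free parameters used (needed for `w_FR` with receptor 3).
#' @param species which species to return; default all plus `"S"`.
#' @return Named list of numeric trajectories.
#' @export
latent_states <- function(result, model, params, species = NULL) {
  stopifnot(inherits(result, "sim_result"), inherits(model, "candidate_model"))
  avail <- c(model$species, "S")
  if (is.null(species)) species <- avail
  bad <- setdiff(species, avail)
  if (length(bad))
    stop("species not in model ", model$id, ": ", paste(bad, collapse = ", "))
  full <- expand_params(model, params)
  out <- lapply(species, function(sp) {
    if (sp == "S") receptor_signal(result$states, full, model$receptor)
    else result$states[, sp]
  })
  stats::setNames(out, species)
}

#' Steady-state dose response of the receptor layer
#'
#' Steady states are obtained by long-horizon integration under sustained
#' stimulation with a convergence check on the right-hand side (max |dy/dt| <
#' `tol`), which is robust across all receptor schemes.
#'
#' @param model a `candidate_model`.
#' @param params named free-parameter vector.
#' @param doses doses in ng/ml (>= 0).
#' @param t_max integration horizon in minutes (default 5000).
#' @param tol steady-state tolerance on the derivative norm.
#' @return data.frame with columns `dose`, `HFR_ss`, `FR_ss` (NA for receptor
#'   1) and `S_ss`.
#' @export
steady_state_dose_response <- function(model, params, doses, t_max = 5000,
                                       tol = 1e-10) {
  stopifnot(all(doses >= 0))
  full <- expand_params(model, params)
  rows <- lapply(doses, function(dose) {
    sched <- pulse_schedule(
      data.frame(onset = 0, duration = t_max, dose = dose),
      baseline_min = 0, total_min = t_max)
    # long horizons at conservative step sizes: give the stepper room
    sim <- simulate_model(model, params, sched, times = c(0, t_max),
                          max_steps = 2e6)
    st <- stats::setNames(numeric(9), .SPECIES)
    st[model$species] <- sim$states[2, ]
    rhs_at <- function(y) .rhs_cpp(unname(full), model$receptor,
                                   model$feedback_code,
                                   as.integer(model$positive_feedback),
                                   dose, unname(y))
    # Newton polish: integration gets within its own tolerance of the
    # fixed point; a few damped Newton steps push the residual to the
    # requested precision
    act <- match(model$species, .SPECIES)  # pruned species stay at zero
    for (it in 1:20) {
      dy <- rhs_at(st)
      if (max(abs(dy)) < tol) break
      J <- matrix(0, length(act), length(act))
      for (jj in seq_along(act)) {
        j <- act[jj]
        h <- 1e-7 * max(abs(st[j]), 1e-5)
        stp <- st; stp[j] <- stp[j] + h
        J[, jj] <- (rhs_at(stp)[act] - dy[act]) / h
      }
      step <- tryCatch(solve(J, -dy[act]), error = function(e) NULL)
      if (is.null(step)) break
      st_new <- st; st_new[act] <- pmax(st[act] + step, 0)
      if (max(abs(rhs_at(st_new))) < max(abs(dy))) st <- st_new else break
    }
    dy <- rhs_at(st)
    if (max(abs(dy)) >= tol)
      stop("no steady state within horizon at dose ", dose,
           " (max |dy/dt| = ", format(max(abs(dy))), ")")
    data.frame(dose = dose, HFR_ss = st[["HFR"]],
               FR_ss = if (model$receptor >= 2) st[["FR"]] else NA_real_,
               S_ss = receptor_signal(st, full, model$receptor))
  })
  do.call(rbind, rows)
}

#' In-silico HSPG knockout
#'
#' Returns a copy of the parameter vector with the total HSPG pool set to
#' zero, emulating chlorate inhibition of HSPG sulfation. All other entries
#' are untouched, so the operation is idempotent.
#'
#' @param params named free-parameter vector containing `HSPG_tot`.
#' @return Modified copy of `params`.
#' @export
hspg_knockout <- function(params) {
  if (!"HSPG_tot" %in% names(params)) stop("params must contain HSPG_tot")
  params["HSPG_tot"] <- 0
  params
}
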