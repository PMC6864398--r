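#' Candidate network models
#'
#' Candidate models cross a receptor-layer scheme with an intracellular
#' feedback wiring. Receptor schemes: 1 = simple activation (only the ternary
#' HSPG.FGF2.FGFR complex, HFR, signals), 2 = competitive activation (ligand
#' also titrates FGFR into a non-signaling binary FR complex), 3 = competitive
#' joint activation (FR signals too, with relative weight `w_FR`). Feedback
#' wirings: A = basic cascade, B = negative feedback (ERK* activates an
#' abstract inhibitor NFB of Raf activation), C = incoherent feed-forward
#' (receptor species activate NFB through Hill terms), D = combined (receptor
#' Hill terms multiplied by ERK*). Optional variants carry a positive feedback
#' from ERK* onto Raf activation: E1-E3 (positive feedback only) and
#' B1p/C1p/D1p (added to B1/C1/D1).
#'
#' The downstream cascade (Ras, Raf, MEK, ERK and the FRET sensor
#' phospho-fraction EKARp) uses normalized pools: activation is
#' Michaelis-Menten in the inactive fraction, deactivation first-order.
#'
#' @name candidate_models
NULL

# full 39-slot parameter layout shared with the compiled core
.PARAM_NAMES <- c(
  "k1", "k_1", "k2", "k_2", "k3", "k_3", "HSPG_tot", "FGFR_tot", "w_FR",
  "k_act_Ras", "Km_Ras", "d_Ras",
  "k_act_Raf", "Km_Raf", "d_Raf",
  "k_act_MEK", "Km_MEK", "d_MEK",
  "k_act_ERK", "Km_ERK", "d_ERK",
  "NFB_tot", "k_nfb", "d_nfb", "K_inh", "h_nfb",
  "K_hfr", "h_hfr", "K_fgfr", "h_fgfr",
  "k_f", "Km_f", "k_r", "Km_r", "rho", "sigma",
  "a_pf", "K_pf", "h_pf")

# neutral values for pruned parameters: absent routes off, absent Hill terms
# inert, so nested topologies coincide exactly
.PARAM_NEUTRAL <- c(
  k1 = 0, k_1 = 0, k2 = 0, k_2 = 0, k3 = 0, k_3 = 0,
  HSPG_tot = 0, FGFR_tot = 0, w_FR = 0,
  k_act_Ras = 0, Km_Ras = 1, d_Ras = 0,
  k_act_Raf = 0, Km_Raf = 1, d_Raf = 0,
  k_act_MEK = 0, Km_MEK = 1, d_MEK = 0,
  k_act_ERK = 0, Km_ERK = 1, d_ERK = 0,
  NFB_tot = 0, k_nfb = 0, d_nfb = 1, K_inh = 1, h_nfb = 1,
  K_hfr = 1, h_hfr = 1, K_fgfr = 1, h_fgfr = 1,
  k_f = 0, Km_f = 1, k_r = 0, Km_r = 1, rho = 0, sigma = 1,
  a_pf = 0, K_pf = 1, h_pf = 1)

.SPECIES <- c("HF", "HFR", "FR", "Ras", "Raf", "MEK", "ERK", "NFB", "EKARp")

.FEEDBACK_CODE <- c(A = 0L, B = 1L, C = 2L, D = 3L, E = 0L)

#' Build one candidate model
#'
#' Species and parameters are pruned to the topology: receptor 1 has no FR
#' complex (no `k3`, `k_3`); `w_FR` exists only for receptor 3; feedbacks A and
#' E have no NFB species; feedback B has no receptor Hill terms; feedbacks C/D
#' carry `K_fgfr`/`h_fgfr` only when FR exists (receptors 2-3).
#'
#' @param receptor receptor scheme, 1, 2 or 3.
#' @param feedback feedback wiring, one of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`.
#' @param positive_feedback add the ERK->Raf positive feedback
#'   (`a_pf`, `K_pf`, `h_pf`); implied for feedback `"E"`.
#' @return An object of class `candidate_model` with fields `id`, `receptor`,
#'   `feedback`, `positive_feedback`, `species`, `params`.
#' @examples
#' m <- build_model(3, "B")
#' m$id                 # "B3"
#' length(m$params)     # 34 free parameters
#' @export
build_model <- function(receptor, feedback, positive_feedback = FALSE) {
  if (!receptor %in% 1:3) stop("unknown receptor topology: ", receptor)
  if (!feedback %in% names(.FEEDBACK_CODE))
    stop("unknown feedback topology: ", feedback)
  if (feedback == "E") positive_feedback <- TRUE

  pars <- c("k1", "k_1", "k2", "k_2", "HSPG_tot", "FGFR_tot")
  if (receptor >= 2) pars <- c(pars, "k3", "k_3")
  if (receptor == 3) pars <- c(pars, "w_FR")
  pars <- c(pars, .PARAM_NAMES[10:21])
  if (feedback %in% c("B", "C", "D")) {
    pars <- c(pars, "NFB_tot", "k_nfb", "d_nfb", "K_inh", "h_nfb")
    if (feedback %in% c("C", "D")) {
      pars <- c(pars, "K_hfr", "h_hfr")
      if (receptor >= 2) pars <- c(pars, "K_fgfr", "h_fgfr")
    }
  }
  pars <- c(pars, "k_f", "Km_f", "k_r", "Km_r", "rho", "sigma")
  if (positive_feedback) pars <- c(pars, "a_pf", "K_pf", "h_pf")
  pars <- .PARAM_NAMES[.PARAM_NAMES %in% pars]  # canonical order

  species <- .SPECIES
  if (receptor == 1) species <- setdiff(species, "FR")
  if (!feedback %in% c("B", "C", "D")) species <- setdiff(species, "NFB")

  id <- paste0(feedback, receptor,
               if (positive_feedback && feedback != "E") "p" else "")
  structure(list(id = id, receptor = as.integer(receptor), feedback = feedback,
                 positive_feedback = positive_feedback,
                 species = species, params = pars,
                 feedback_code = .FEEDBACK_CODE[[feedback]]),
            class = "candidate_model")
}

#' Enumerate the candidate model family
#'
#' The base family crosses feedback wirings A-D with receptor schemes 1-3
#' (12 models). With `include_positive_feedback = TRUE` the six
#' positive-feedback variants E1, E2, E3, B1p, C1p, D1p are appended.
#'
#' @param include_positive_feedback include the positive-feedback variants.
#' @return Named list of `candidate_model` objects, ids in enumeration order
#'   (A1, A2, A3, B1, ..., D3, then the variants).
#' @export
enumerate_models <- function(include_positive_feedback = FALSE) {
  out <- list()
  for (fb in c("A", "B", "C", "D"))
    for (rc in 1:3)
      out[[paste0(fb, rc)]] <- build_model(rc, fb)
  if (include_positive_feedback) {
    for (rc in 1:3) out[[paste0("E", rc)]] <- build_model(rc, "E")
    for (fb in c("B", "C", "D"))
      out[[paste0(fb, "1p")]] <- build_model(1, fb, positive_feedback = TRUE)
  }
  out
}

#' Look up a model by id
#' @param id model id such as `"B3"` or `"D1p"`.
#' @return A `candidate_model`.
#' @export
get_model <- function(id) {
  all <- enumerate_models(include_positive_feedback = TRUE)
  if (!id %in% names(all)) stop("unknown model id: ", id)
  all[[id]]
}

#' @export
print.candidate_model <- function(x, ...) {
  cat("candidate_model", x$id, "- receptor", x$receptor, "feedback",
      x$feedback, if (x$positive_feedback) "+PF" else "", "\n")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  cat("  free parameters:", length(x$params), "\n")
  invisible(x)
}

#' Expand a model's free parameters to the full internal layout
#'
#' Pruned parameters take neutral values (absent binding routes have zero
#' rates, absent feedback terms are inert), which is what makes the nesting
#' equivalences between topologies exact.
#'
#' @param model a `candidate_model`.
#' @param params named numeric vector over `model$params` (any order).
#' @return Named numeric vector of length 39.
#' @export
expand_params <- function(model, params) {
  stopifnot(inherits(model, "candidate_model"))
  if (is.null(names(params)) || !setequal(names(params), model$params))
    stop("params must be named exactly by the model's free parameters; ",
         "missing: ", paste(setdiff(model$params, names(params)), collapse = ", "),
         "; extra: ", paste(setdiff(names(params), model$params), collapse = ", "))
  if (any(!is.finite(params)) || any(params < 0))
    stop("parameters must be finite and non-negative")
  full <- .PARAM_NEUTRAL
  full[names(params)] <- params
  full
}

#' Receptor-layer signaling activity
#'
#' Total FGFR signaling activity S: the ternary complex HFR for receptor
#' schemes 1 and 2; `HFR + w_FR * FR` for scheme 3.
#'
#' @param state named numeric vector (or matrix with named columns) holding at
#'   least `HFR` and, for receptors 2-3, `FR`.
#' @param params named parameters containing `w_FR` when receptor = 3.
#' @param receptor receptor scheme (1, 2 or 3).
#' @return Numeric signal in concentration units.
#' @export
receptor_signal <- function(state, params, receptor) {
  get_s <- function(nm) {
    if (is.matrix(state)) state[, nm] else unname(state[nm])
  }
  s <- get_s("HFR")
  if (receptor == 3) s <- s + unname(params["w_FR"]) * get_s("FR")
  s
}

#' Log-uniform prior for a model's free parameters
#'
#' Every free parameter gets a log-uniform prior: rates and
#' Michaelis/threshold constants on `[1e-3, 1e3]`; pool totals (`HSPG_tot`,
#' `FGFR_tot`, `NFB_tot`) on `[1e-2, 1e2]`; Hill coefficients on `[1, 8]`;
#' `w_FR` and `a_pf` on `[1e-3, 10]`; the ratio dynamic range `rho` on
#' `[1e-2, 10]`; the measurement noise `sigma` on `[1e-3, 1]`.
#'
#' @param model a `candidate_model`.
#' @return A `prior_spec` over `model$params`.
#' @export
default_prior <- function(model) {
  stopifnot(inherits(model, "candidate_model"))
  lo <- numeric(0); hi <- numeric(0)
  for (p in model$params) {
    b <- if (p %in% c("HSPG_tot", "FGFR_tot", "NFB_tot")) c(1e-2, 1e2)
    else if (p %in% c("h_nfb", "h_hfr", "h_fgfr", "h_pf")) c(1, 8)
    else if (p %in% c("w_FR", "a_pf")) c(1e-3, 1e1)
    else if (p == "rho") c(1e-2, 1e1)
    else if (p == "sigma") c(1e-3, 1)
    else c(1e-3, 1e3)
    lo[p] <- b[1]; hi[p] <- b[2]
  }
  prior_spec(lo, hi)
}

#' Evaluate the model right-hand side at one state (mainly for testing and
#' steady-state checks)
#'
#' @param model a `candidate_model`.
#' @param state named state vector over `model$species`.
#' @param params named free-parameter vector.
#' @param u input dose (ng/ml).
#' @return Named derivative vector over `model$species`.
#' @export
model_rhs <- function(model, state, params, u) {
  stopifnot(inherits(model, "candidate_model"))
  if (is.null(names(state)) || !setequal(names(state), model$species))
    stop("state must be named exactly by the model's species")
  if (any(state < 0)) stop("state violates non-negativity")
  full_state <- stats::setNames(numeric(9), .SPECIES)
  full_state[names(state)] <- state
  full <- expand_params(model, params)
  d <- .rhs_cpp(unname(full), model$receptor, model$feedback_code,
                as.integer(model$positive_feedback), u, unname(full_state))
  stats::setNames(d[match(model$species, .SPECIES)], model$species)
}
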