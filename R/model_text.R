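#' Human-readable model files
#'
#' Emit and parse candidate models in a plain-text format with sections
#' `MODEL`, `SPECIES`, `PARAMETERS`, `REACTIONS` (one rate law per line) and
#' `OUTPUT`, terminated by `END`. Grammar: a file is a sequence of section
#' headers (one of the five keywords, upper-case, column 1) each followed by
#' indented content lines; `#` starts a comment. The `MODEL` section holds the
#' id; `SPECIES` and `PARAMETERS` hold one name per line; `REACTIONS` and
#' `OUTPUT` are informative rate-law text regenerated from the topology on
#' parse. Parsing reconstructs the model from the id and verifies that the
#' listed species and parameters match the topology exactly.
#'
#' @param model a `candidate_model`.
#' @param path file path.
#' @return `write_model_text` returns `path` invisibly; `read_model_text`
#'   returns a `candidate_model`.
#' @export
write_model_text <- function(model, path) {
  stopifnot(inherits(model, "candidate_model"))
  rx <- .model_reactions(model)
  lines <- c(
    "# candidate receptor/MAPK network model",
    "MODEL",
    paste0("  ", model$id),
    "SPECIES",
    paste0("  ", model$species),
    "PARAMETERS",
    paste0("  ", model$params),
    "REACTIONS",
    paste0("  ", rx),
    "OUTPUT",
    "  r = 1 + rho * EKARp",
    "END")
  writeLines(lines, path)
  invisible(path)
}

.model_reactions <- function(model) {
  rc <- model$receptor; fb <- model$feedback
  rx <- c(
    "dHF/dt = k1*u*HSPG_free - k_1*HF - k2*HF*FGFR_free + k_2*HFR",
    "dHFR/dt = k2*HF*FGFR_free - k_2*HFR")
  if (rc >= 2) rx <- c(rx, "dFR/dt = k3*u*FGFR_free - k_3*FR")
  s <- if (rc == 3) "S = HFR + w_FR*FR" else "S = HFR"
  inh <- if (fb %in% c("B", "C", "D")) "*Infb" else ""
  pfx <- if (model$positive_feedback) "*Ppf" else ""
  rx <- c(rx, s,
          "dRas/dt = k_act_Ras*S*(1-Ras)/(Km_Ras+1-Ras) - d_Ras*Ras",
          paste0("dRaf/dt = k_act_Raf*Ras", inh, pfx,
                 "*(1-Raf)/(Km_Raf+1-Raf) - d_Raf*Raf"),
          "dMEK/dt = k_act_MEK*Raf*(1-MEK)/(Km_MEK+1-MEK) - d_MEK*MEK",
          "dERK/dt = k_act_ERK*MEK*(1-ERK)/(Km_ERK+1-ERK) - d_ERK*ERK")
  if (fb %in% c("B", "C", "D")) {
    act <- switch(fb,
      B = "k_nfb*ERK",
      C = if (rc >= 2)
        "k_nfb*(hill(HFR,K_hfr,h_hfr) + hill(FR,K_fgfr,h_fgfr))"
      else "k_nfb*hill(HFR,K_hfr,h_hfr)",
      D = if (rc >= 2)
        "k_nfb*(hill(HFR,K_hfr,h_hfr) + hill(FR,K_fgfr,h_fgfr))*ERK"
      else "k_nfb*hill(HFR,K_hfr,h_hfr)*ERK")
    rx <- c(rx, "Infb = 1/(1 + (NFB/K_inh)^h_nfb)",
            paste0("dNFB/dt = ", act, "*(NFB_tot-NFB) - d_nfb*NFB"))
  }
  if (model$positive_feedback)
    rx <- c(rx, "Ppf = 1 + a_pf*ERK^h_pf/(K_pf^h_pf + ERK^h_pf)")
  c(rx, "dEKARp/dt = k_f*ERK*(1-EKARp)/(Km_f+1-EKARp) - k_r*EKARp/(Km_r+EKARp)")
}

#' @rdname write_model_text
#' @export
read_model_text <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  sections <- c("MODEL", "SPECIES", "PARAMETERS", "REACTIONS", "OUTPUT", "END")
  cur <- NULL
  content <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    stripped <- sub("#.*$", "", ln)
    if (!nzchar(trimws(stripped))) next
    if (!grepl("^\\s", stripped)) {
      kw <- trimws(stripped)
      if (!kw %in% sections)
        stop("parse error at line ", i, ": unknown section header '", kw, "'")
      if (kw == "END") break
      cur <- kw
      content[[cur]] <- character(0)
    } else {
      if (is.null(cur))
        stop("parse error at line ", i, ": content before any section header")
      content[[cur]] <- c(content[[cur]], trimws(stripped))
    }
  }
  for (need in c("MODEL", "SPECIES", "PARAMETERS"))
    if (is.null(content[[need]]))
      stop("parse error: missing ", need, " section")
  id <- content$MODEL[1]
  model <- get_model(id)
  if (!identical(content$SPECIES, model$species))
    stop("species list does not match topology ", id, ": expected ",
         paste(model$species, collapse = ", "))
  if (!identical(content$PARAMETERS, model$params))
    stop("parameter list does not match topology ", id, ": expected ",
         paste(model$params, collapse = ", "))
  model
}
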