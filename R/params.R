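# Model parameters: fixed physical/anatomical constants, optimized kinetic
# constants, and constrained (steady-state-derived) transport/enzyme capacities.

#' Default model parameters
#'
#' Returns the complete parameter set of the neuron-glia-vasculature (NGV)
#' metabolic model as a named list. Parameters fall into three groups
#' (recoverable with [param_groups()]):
#'
#' * `fixed` -- anatomical volume fractions, physical constants, membrane
#'   conductances and affinities taken from the literature,
#' * `optimized` -- kinetic constants determined by fitting activity-evoked
#'   NADH transients (see [fit_free_parameters()]),
#' * `constrained` -- capacities solved from steady-state flux balances at the
#'   imposed resting concentrations (see [steady_state_constrain()]).
#'
#' Units: concentrations mM, time s, voltage mV, conductances mS cm^-2,
#' membrane capacitance mF cm^-2, fluxes mM s^-1, flows s^-1.
#'
#' @param ... Named overrides, e.g. `ngv_params(F_0 = 0.015)`. Unknown names
#'   are an error.
#' @return A named list of class `ngv_params`.
#' @export
#' @examples
#' p <- ngv_params()
#' p$F_0
ngv_params <- function(...) {
  p <- list(
    ## -- fixed: geometry -------------------------------------------------
    V_e   = 0.2,     # extracellular volume fraction
    V_cap = 0.0055,  # capillary volume fraction
    V_g   = 0.25,    # astrocytic volume fraction
    V_n   = 0.45,    # neuronal volume fraction
    xi    = 0.07,    # mitochondrial fraction of cell volume
    SmVn  = 2.5e4,   # neuronal surface-to-volume ratio, cm^-1
    SmVg  = 2.5e4,   # astrocytic surface-to-volume ratio, cm^-1
    ## -- fixed: physical constants --------------------------------------
    RTF   = 26.73,      # RT/F, mV
    Faraday = 9.64853e4, # C mol^-1
    psi_g = -70,        # astrocytic membrane voltage (held fixed), mV
    Na_e  = 150,        # extracellular sodium, mM
    ## -- fixed: transport affinities ------------------------------------
    Kt_GLC_en = 8, Kt_GLC_eg = 8, Kt_GLC_cg = 8, Kt_GLC_ce = 8,  # mM
    Kt_LAC_ne = 0.74, Kt_LAC_ge = 3.5, Kt_LAC_gc = 1, Kt_LAC_ec = 1, # mM
    ## -- fixed: hexokinase-phosphofructokinase --------------------------
    K_I_ATP = 1, nH = 4, K_g = 0.05,
    ## -- fixed: oxygen ----------------------------------------------------
    K_O2 = 0.0361, HbOP = 8.6, nh = 2.73, K_O2_mito = 0.001,
    ## -- fixed: Hodgkin-Huxley ------------------------------------------
    C_m = 1e-3,          # mF cm^-2
    g_L = 0.02, g_Na = 40, g_K = 18, g_Ca = 0.02, g_mAHP = 6.5, # mS cm^-2
    K_D = 30e-3,         # mM
    tau_Ca = 150e-3,     # s
    Ca_0 = 0.5e-4,       # mM
    E_K = -80, E_Ca = 120, # mV
    phi_n = 4, phi_h = 4,
    ## -- fixed: venous balloon ------------------------------------------
    tau_v = 35, alpha_v = 0.5,
    ## -- fixed: arterial supply -----------------------------------------
    O2_a = 8.35, GLC_a = 4.75,
    ## -- fixed: pumps and sodium leak -----------------------------------
    gNa_n = 0.0136, gNa_g = 0.0061, gKpas = 0.2035, # mS cm^-2
    k_pump_n = 2.2e-6, k_pump_g = 4.5e-7,           # cm mM^-1 s^-1
    Jpump0_g = 0.0687,  # baseline astrocytic pump flux, mM s^-1
    K_m_pump = 0.5,     # mM
    ## -- fixed: conserved pools -----------------------------------------
    Ctot = 10,      # creatine + phosphocreatine, mM
    Ntot = 0.212,   # NAD+ + NADH per sub-compartment, mM
    Atot = 2.212,   # AMP + ADP + ATP, mM
    q_AK = 0.92,    # adenylate kinase equilibrium constant
    K_m_mito = 0.04, # TCA pyruvate affinity, mM
    ## -- fixed: hemodynamics / BOLD -------------------------------------
    F_0 = 0.012, Vv_0 = 0.02,
    k1 = 2.22, k2 = 0.46, k3 = 0.43,
    Na0_n = 8,   # resting neuronal sodium entering the pump current, mM
    ## -- optimized -------------------------------------------------------
    kLDHp_n = 72.3, kLDHp_g = 1.59,              # mM^-1 s^-1
    M_cyto_n = 4.9e-8, M_cyto_g = 2.5e-4,
    M_mito_n = 3.93e5, M_mito_g = 1.06e4,
    K_m_ADP_n = 3.41e-3, K_m_ADP_g = 0.483e-3,   # mM
    K_m_NADH_n = 4.44e-2, K_m_NADH_g = 2.69e-2,  # mM
    kCKp_n = 0.0433, kCKp_g = 0.00135,           # mM^-1 s^-1
    K_m_NAD_n = 0.409, K_m_NAD_g = 40.3,         # mM
    ## -- constrained -----------------------------------------------------
    Tmax_GLC_en = 0.041, Tmax_GLC_ce = 0.239,
    Tmax_GLC_eg = 0.147, Tmax_GLC_cg = 0.0016,   # mM s^-1
    Tmax_LAC_gc = 0.00243, Tmax_LAC_ne = 24.3,
    Tmax_LAC_ge = 106.1, Tmax_LAC_ec = 0.25,     # mM s^-1
    kHKPFK_n = 0.0504, kHKPFK_g = 0.185,         # s^-1
    kLDHm_n = 0.72, kLDHm_g = 0.071,             # mM^-1 s^-1
    PScapVn = 1.66, PScapVg = 0.87,              # s^-1
    Vmax_out_n = 0.164, Vmax_out_g = 0.064,      # mM s^-1
    Vmax_in_n = 0.1303, Vmax_in_g = 5.7,         # mM s^-1
    kPGK_n = 3.97, kPGK_g = 135.2,               # mM^-1 s^-1
    kPK_n = 36.7, kPK_g = 401.7,                 # mM^-1 s^-1
    JATPases_n = 0.1695, JATPases_g = 0.1404,    # mM s^-1
    kCKm_n = 0.00028, kCKm_g = 1e-5,             # mM^-1 s^-1
    TNADH_n = 10330, TNADH_g = 150,              # mM s^-1
    LAC_a = 0.506                                # arterial lactate, mM
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    p[names(over)] <- over
  }
  structure(p, class = c("ngv_params", "list"))
}

# parameter names by Table-3 style group
.param_group_names <- function() {
  opt <- c("kLDHp_n", "kLDHp_g", "M_cyto_n", "M_cyto_g", "M_mito_n", "M_mito_g",
           "K_m_ADP_n", "K_m_ADP_g", "K_m_NADH_n", "K_m_NADH_g",
           "kCKp_n", "kCKp_g", "K_m_NAD_n", "K_m_NAD_g")
  con <- c("Tmax_GLC_en", "Tmax_GLC_ce", "Tmax_GLC_eg", "Tmax_GLC_cg",
           "Tmax_LAC_gc", "Tmax_LAC_ne", "Tmax_LAC_ge", "Tmax_LAC_ec",
           "kHKPFK_n", "kHKPFK_g", "kLDHm_n", "kLDHm_g",
           "PScapVn", "PScapVg", "Vmax_out_n", "Vmax_out_g",
           "Vmax_in_n", "Vmax_in_g", "kPGK_n", "kPGK_g", "kPK_n", "kPK_g",
           "JATPases_n", "JATPases_g", "kCKm_n", "kCKm_g",
           "TNADH_n", "TNADH_g", "LAC_a")
  all <- names(ngv_params())
  list(fixed = setdiff(all, c(opt, con)), optimized = opt, constrained = con)
}

#' Parameter grouping
#'
#' @param params An `ngv_params` list.
#' @return A tibble with columns `name`, `value`, `group`
#'   (fixed / optimized / constrained).
#' @export
param_groups <- function(params = ngv_params()) {
  g <- .param_group_names()
  grp <- rep(NA_character_, length(params))
  nm <- names(params)
  grp[nm %in% g$fixed] <- "fixed"
  grp[nm %in% g$optimized] <- "optimized"
  grp[nm %in% g$constrained] <- "constrained"
  tibble::tibble(name = nm, value = unlist(params, use.names = FALSE), group = grp)
}

#' Validate a parameter set
#'
#' Checks that every capacity, affinity, conductance and volume is strictly
#' positive and that no parameter is missing or unknown.
#'
#' @param params An `ngv_params` list.
#' @return `params`, invisibly; errors describe every offending entry.
#' @export
validate_params <- function(params) {
  ref <- names(ngv_params())
  missing <- setdiff(ref, names(params))
  unknown <- setdiff(names(params), ref)
  if (length(missing)) stop("missing parameter(s): ", paste(missing, collapse = ", "))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  # parameters allowed to be non-positive (voltages, reversal potentials)
  signed <- c("psi_g", "E_K", "E_Ca", "Na0_n")
  vals <- unlist(params)
  bad <- names(vals)[!(names(vals) %in% signed) & !(vals > 0)]
  if (length(bad)) stop("non-positive parameter(s): ", paste(bad, collapse = ", "))
  invisible(params)
}

#' Read / write parameter files
#'
#' Parameters are stored as a flat JSON or YAML mapping plus a `group` tag per
#' entry. Unknown keys are rejected on read.
#'
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @param params An `ngv_params` list.
#' @return `read_params()` returns an `ngv_params` list; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported parameter file extension: ", ext)
  )
  vals <- doc[["parameters"]] %||% doc
  ref <- ngv_params()
  unknown <- setdiff(names(vals), names(ref))
  if (length(unknown)) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  p <- ref
  p[names(vals)] <- lapply(vals, as.numeric)
  validate_params(p)
  p
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  validate_params(params)
  groups <- param_groups(params)
  doc <- list(parameters = lapply(params, unclass),
              group = stats::setNames(as.list(groups$group), groups$name))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE),
    yaml = ,
    yml  = yaml::write_yaml(doc, path),
    stop("unsupported parameter file extension: ", ext)
  )
  invisible(path)
}

#' @export
print.ngv_params <- function(x, ...) {
  g <- param_groups(x)
  cat("<ngv_params> ", nrow(g), " parameters (",
      sum(g$group == "fixed"), " fixed, ",
      sum(g$group == "optimized"), " optimized, ",
      sum(g$group == "constrained"), " constrained)\n", sep = "")
  invisible(x)
}

# canonical state ordering shared with the compiled right-hand side
.state_names <- c(
  "Na_n", "Na_g", "GLC_n", "GLC_g", "GAP_n", "GAP_g", "PEP_n", "PEP_g",
  "PYR_n", "PYR_g", "LAC_n", "LAC_g",
  "NADH_cyto_n", "NADH_cyto_g", "NADH_mito_n", "NADH_mito_g",
  "ATP_n", "ATP_g", "PCr_n", "PCr_g",
  "O2_n", "O2_g", "O2_c", "GLC_c", "LAC_c", "GLC_e", "LAC_e",
  "Vv", "dHb", "psi_n", "h", "n_gate", "Ca"
)

#' State variable names
#'
#' The canonical ordering of the 33 dynamic variables.
#' @return A character vector of length 33.
#' @export
state_names <- function() .state_names

#' Literature resting state
#'
#' The imposed resting concentrations/voltages used to seed steady-state
#' solves and to constrain parameters.
#'
#' @return A named numeric vector over [state_names()].
#' @export
resting_state <- function() {
  c(Na_n = 8, Na_g = 15, GLC_n = 1.2, GLC_g = 1.19,
    GAP_n = 0.0046, GAP_g = 0.0046, PEP_n = 0.015, PEP_g = 0.015,
    PYR_n = 0.17, PYR_g = 0.17, LAC_n = 0.6, LAC_g = 0.6,
    NADH_cyto_n = 0.006, NADH_cyto_g = 0.1,
    NADH_mito_n = 0.12, NADH_mito_g = 0.12,
    ATP_n = 2.2, ATP_g = 2.2, PCr_n = 4.9, PCr_g = 4.9,
    O2_n = 0.028, O2_g = 0.028, O2_c = 7, GLC_c = 4.5, LAC_c = 0.55,
    GLC_e = 2.48, LAC_e = 0.6, Vv = 0.02, dHb = 0.058,
    psi_n = -73, h = 0.99, n_gate = 0.02, Ca = 0.5e-4)
}

#' Check state invariants
#'
#' Concentrations non-negative, NADH within the NAD pool, PCr within the
#' creatine pool, ATP within the adenine pool, gates in \[0, 1\], venous
#' volume positive.
#'
#' @param state Named numeric vector over [state_names()].
#' @param params An `ngv_params` list.
#' @return Logical scalar.
#' @export
state_valid <- function(state, params = ngv_params()) {
  s <- state[.state_names]
  if (anyNA(s)) return(FALSE)
  conc <- setdiff(.state_names, c("psi_n", "h", "n_gate", "Vv"))
  all(s[conc] >= 0) &&
    all(s[c("NADH_cyto_n", "NADH_cyto_g", "NADH_mito_n", "NADH_mito_g")] <= params$Ntot) &&
    all(s[c("PCr_n", "PCr_g")] <= params$Ctot) &&
    all(s[c("ATP_n", "ATP_g")] <= params$Atot) &&
    all(s[c("h", "n_gate")] >= 0) && all(s[c("h", "n_gate")] <= 1) &&
    s[["Vv"]] > 0
}
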