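# Reaction, transport and membrane-current expressions, and the assembly of
# the full 33-state right-hand side. All functions here are vectorized over
# states so that fluxes can be evaluated along a whole trajectory at once.
# A compiled C implementation of the same right-hand side (src/ngv_model.c)
# is used for integration; this R transcription is the reference path used by
# the steady-state solver, the flux annotation of trajectories and the
# cross-checks in the test suite.

#' Adenylate pool closure
#'
#' Given ATP and the conserved adenine pool `Atot`, returns ADP from the
#' adenylate-kinase equilibrium (AMP * ATP = q_AK * ADP^2 with
#' AMP + ADP + ATP = Atot), AMP by difference, and the analytic derivative
#' dAMP/dATP used to correct the ATP balance.
#'
#' @param ATP ATP concentration, mM (vectorized).
#' @param params An [ngv_params()] list.
#' @return A tibble with columns `ADP`, `AMP`, `dAMP_dATP` (mM, mM, unitless).
#' @export
#' @examples
#' adenylate_closure(2.2)
adenylate_closure <- function(ATP, params = ngv_params()) {
  A <- params$Atot; q <- params$q_AK
  if (any(ATP <= 0) || any(ATP > A)) {
    stop("ATP must lie in (0, Atot]; got range [",
         min(ATP), ", ", max(ATP), "]", call. = FALSE)
  }
  u <- q^2 + 4 * q * (A / ATP - 1)
  ADP <- ATP / 2 * (-q + sqrt(u))
  AMP <- A - ATP - ADP
  dAMP <- -1 + q / 2 - sqrt(u) / 2 + q * A / (ATP * sqrt(u))
  tibble::tibble(ADP = ADP, AMP = pmax(AMP, 0), dAMP_dATP = dAMP)
}

#' Reversible saturable carrier flux
#'
#' Shared Michaelis-Menten carrier form used for glucose and lactate
#' transport between compartments:
#' `J = Tmax * (src/(src+Kt) - dst/(dst+Kt))`.
#'
#' @param src,dst Source and destination concentrations, mM.
#' @param Tmax Carrier capacity, mM/s. @param Kt Carrier affinity, mM.
#' @return Net flux, mM/s, positive from `src` to `dst`.
#' @export
carrier_flux <- function(src, dst, Tmax, Kt) {
  if (any(src < 0) || any(dst < 0)) stop("negative concentration", call. = FALSE)
  Tmax * (src / (src + Kt) - dst / (dst + Kt))
}

# gate rate constants; removable singularities of alpha_m (psi = -33) and
# alpha_n (psi = -34) evaluated by their analytic limits
.alpha_m <- function(psi) {
  x <- psi + 33
  ifelse(abs(x) < 1e-6, 1, 0.1 * x / (1 - exp(-0.1 * x)))
}
.alpha_n <- function(psi) {
  x <- psi + 34
  ifelse(abs(x) < 1e-6, 0.1, 0.01 * x / (1 - exp(-0.1 * x)))
}

#' Hodgkin-Huxley gate kinetics
#'
#' Steady-state activations and time constants of the spiking model, plus the
#' instantaneous calcium activation. Rate constants are per ms as printed, so
#' time constants carry a 1e-3 factor to be in seconds.
#'
#' @param psi Membrane voltage, mV (vectorized).
#' @return A tibble with `m_inf`, `h_inf`, `n_inf`, `tau_h`, `tau_n` (s),
#'   `m_Ca`.
#' @export
gate_kinetics <- function(psi) {
  am <- .alpha_m(psi)
  bm <- 4 * exp(-(psi + 58) / 12)
  ah <- 0.07 * exp(-(psi + 50) / 10)
  bh <- 1 / (exp(-0.1 * (psi + 20)) + 1)
  an <- .alpha_n(psi)
  bn <- 0.125 * exp(-(psi + 44) / 25)
  tibble::tibble(
    m_inf = am / (am + bm),
    h_inf = ah / (ah + bh),
    n_inf = an / (an + bn),
    tau_h = 1e-3 / (ah + bh),
    tau_n = 1e-3 / (an + bn),
    m_Ca  = 1 / (1 + exp(-(psi + 20) / 9))
  )
}

#' Sodium pump and leak fluxes
#'
#' @param Na Intracellular sodium, mM. @param ATP ATP, mM.
#' @param psi Membrane voltage of the compartment, mV.
#' @param params An [ngv_params()] list.
#' @param compartment `"neuron"` or `"astrocyte"`.
#' @return A tibble with `J_pump` and `J_leak_Na`, mM/s.
#' @export
pump_and_leak <- function(Na, ATP, psi, params = ngv_params(),
                          compartment = c("neuron", "astrocyte")) {
  compartment <- match.arg(compartment)
  if (any(Na <= 0)) stop("Na must be positive", call. = FALSE)
  if (compartment == "neuron") {
    SmV <- params$SmVn; gNa <- params$gNa_n; kp <- params$k_pump_n
  } else {
    SmV <- params$SmVg; gNa <- params$gNa_g; kp <- params$k_pump_g
  }
  J_leak <- SmV / params$Faraday * gNa *
    (params$RTF * log(params$Na_e / Na) - psi)
  J_pump <- SmV * kp * ATP * Na / (1 + ATP / params$K_m_pump)
  tibble::tibble(J_pump = J_pump, J_leak_Na = J_leak)
}

#' Glycolytic fluxes
#'
#' Lumped hexokinase-phosphofructokinase (ATP-inhibited committed step),
#' phosphoglycerate kinase (NAD+-dependent) and pyruvate kinase.
#'
#' @param GLC,GAP,PEP,ATP,ADP,NADH_cyto Concentrations, mM.
#' @param params An [ngv_params()] list.
#' @param compartment `"neuron"` or `"astrocyte"`.
#' @return A tibble with `J_HKPFK`, `J_PGK`, `J_PK`, mM/s.
#' @export
glycolysis_fluxes <- function(GLC, GAP, PEP, ATP, ADP, NADH_cyto,
                              params = ngv_params(),
                              compartment = c("neuron", "astrocyte")) {
  compartment <- match.arg(compartment)
  if (any(NADH_cyto <= 0)) {
    stop("NADH_cyto must be positive (PGK is singular at 0)", call. = FALSE)
  }
  k_hk <- if (compartment == "neuron") params$kHKPFK_n else params$kHKPFK_g
  k_pgk <- if (compartment == "neuron") params$kPGK_n else params$kPGK_g
  k_pk <- if (compartment == "neuron") params$kPK_n else params$kPK_g
  J_HKPFK <- k_hk * ATP * GLC / (GLC + params$K_g) /
    (1 + (ATP / params$K_I_ATP)^params$nH)
  J_PGK <- k_pgk * GAP * ADP * (params$Ntot - NADH_cyto) / NADH_cyto
  J_PK <- k_pk * PEP * ADP
  tibble::tibble(J_HKPFK = J_HKPFK, J_PGK = J_PGK, J_PK = J_PK)
}

#' Lactate dehydrogenase flux
#'
#' Near-equilibrium mass-action kinetics interconverting pyruvate and lactate
#' against the cytosolic NADH/NAD+ couple:
#' `J = k+ * PYR * NADH - k- * LAC * (N - NADH)`. Positive flux produces
#' lactate.
#'
#' @param PYR,LAC,NADH_cyto Concentrations, mM.
#' @param params An [ngv_params()] list.
#' @param compartment `"neuron"` or `"astrocyte"`.
#' @return Net flux, mM/s.
#' @export
ldh_flux <- function(PYR, LAC, NADH_cyto, params = ngv_params(),
                     compartment = c("neuron", "astrocyte")) {
  compartment <- match.arg(compartment)
  if (any(PYR < 0) || any(LAC < 0) || any(NADH_cyto < 0)) {
    stop("negative concentration", call. = FALSE)
  }
  kp <- if (compartment == "neuron") params$kLDHp_n else params$kLDHp_g
  km <- if (compartment == "neuron") params$kLDHm_n else params$kLDHm_g
  kp * PYR * NADH_cyto - km * LAC * (params$Ntot - NADH_cyto)
}

#' Mitochondrial fluxes
#'
#' TCA-cycle NADH production (saturable in pyruvate and mitochondrial NAD+)
#' and electron-transport-chain NADH oxidation (saturable in oxygen, ADP and
#' mitochondrial NADH).
#'
#' @param PYR,O2,ADP,NADH_mito Concentrations, mM.
#' @param params An [ngv_params()] list.
#' @param compartment `"neuron"` or `"astrocyte"`.
#' @return A tibble with `J_mito_in`, `J_mito_out`, mM/s.
#' @export
mito_fluxes <- function(PYR, O2, ADP, NADH_mito, params = ngv_params(),
                        compartment = c("neuron", "astrocyte")) {
  compartment <- match.arg(compartment)
  if (compartment == "neuron") {
    Vin <- params$Vmax_in_n; Vout <- params$Vmax_out_n
    KmNAD <- params$K_m_NAD_n; KmADP <- params$K_m_ADP_n; KmNADH <- params$K_m_NADH_n
  } else {
    Vin <- params$Vmax_in_g; Vout <- params$Vmax_out_g
    KmNAD <- params$K_m_NAD_g; KmADP <- params$K_m_ADP_g; KmNADH <- params$K_m_NADH_g
  }
  NADm <- params$Ntot - NADH_mito
  J_in <- Vin * PYR / (PYR + params$K_m_mito) * NADm / (NADm + KmNAD)
  J_out <- Vout * O2 / (O2 + params$K_O2_mito) * ADP / (ADP + KmADP) *
    NADH_mito / (NADH_mito + KmNADH)
  tibble::tibble(J_mito_in = J_in, J_mito_out = J_out)
}

#' Cytosol-to-mitochondria NADH shuttle flux
#'
#' Saturable malate-aspartate-type shuttle driven by the cytosolic reduction
#' ratio R- = NADHc/(N-NADHc) and the mitochondrial oxidation ratio
#' R+ = (N-NADHm)/NADHm.
#'
#' @param NADH_cyto,NADH_mito Concentrations, mM, strictly inside (0, N).
#' @param params An [ngv_params()] list.
#' @param compartment `"neuron"` or `"astrocyte"`.
#' @return Shuttle flux, mM/s (cytosol to mitochondria positive).
#' @export
nadh_shuttle_flux <- function(NADH_cyto, NADH_mito, params = ngv_params(),
                              compartment = c("neuron", "astrocyte")) {
  compartment <- match.arg(compartment)
  N <- params$Ntot
  if (any(NADH_cyto <= 0) || any(NADH_cyto >= N) ||
      any(NADH_mito <= 0) || any(NADH_mito >= N)) {
    stop("NADH outside (0, Ntot): shuttle ratios are singular", call. = FALSE)
  }
  if (compartment == "neuron") {
    TN <- params$TNADH_n; Mc <- params$M_cyto_n; Mm <- params$M_mito_n
  } else {
    TN <- params$TNADH_g; Mc <- params$M_cyto_g; Mm <- params$M_mito_g
  }
  Rm <- NADH_cyto / (N - NADH_cyto)
  Rp <- (N - NADH_mito) / NADH_mito
  TN * Rm / (Rm + Mc) * Rp / (Rp + Mm)
}

#' Creatine kinase flux
#'
#' `J = k+ * ADP * PCr - k- * ATP * (C - PCr)`; positive flux consumes PCr to
#' regenerate ATP.
#'
#' @param ADP,ATP,PCr Concentrations, mM.
#' @param params An [ngv_params()] list.
#' @param compartment `"neuron"` or `"astrocyte"`.
#' @return Net flux, mM/s.
#' @export
creatine_kinase_flux <- function(ADP, ATP, PCr, params = ngv_params(),
                                 compartment = c("neuron", "astrocyte")) {
  compartment <- match.arg(compartment)
  kp <- if (compartment == "neuron") params$kCKp_n else params$kCKp_g
  km <- if (compartment == "neuron") params$kCKm_n else params$kCKm_g
  kp * ADP * PCr - km * ATP * (params$Ctot - PCr)
}

#' Capillary-to-cell oxygen exchange
#'
#' The free capillary oxygen concentration in equilibrium with hemoglobin is
#' `K_O2 * (HbOP/O2_c - 1)^(-1/nh)`; exchange is proportional to its excess
#' over intracellular oxygen.
#'
#' @param O2_x Intracellular oxygen, mM. @param O2_c Capillary (total) oxygen, mM.
#' @param params An [ngv_params()] list.
#' @param compartment `"neuron"` or `"astrocyte"`.
#' @return Influx, mM/s.
#' @export
oxygen_exchange_flux <- function(O2_x, O2_c, params = ngv_params(),
                                 compartment = c("neuron", "astrocyte")) {
  compartment <- match.arg(compartment)
  if (any(O2_c <= 0) || any(O2_c >= params$HbOP)) {
    stop("O2_c must lie in (0, HbOP): hemoglobin saturation overflow", call. = FALSE)
  }
  PSV <- if (compartment == "neuron") params$PScapVn else params$PScapVg
  PSV * (params$K_O2 * (params$HbOP / O2_c - 1)^(-1 / params$nh) - O2_x)
}

#' Capillary inflow-driven exchange
#'
#' Arteriovenous exchange of oxygen, glucose and lactate with the capillary
#' compartment, plus the end-capillary oxygen concentration used by the
#' deoxyhemoglobin balance (`O2c_bar = 2*O2_c - O2_a`, the capillary
#' concentration being the arterial / end-capillary average).
#'
#' @param O2_c,GLC_c,LAC_c Capillary concentrations, mM.
#' @param F_in Inflow, 1/s.
#' @param params An [ngv_params()] list.
#' @return A tibble with `J_O2_c`, `J_GLC_c`, `J_LAC_c` (mM/s) and `O2c_bar` (mM).
#' @export
capillary_flows <- function(O2_c, GLC_c, LAC_c, F_in, params = ngv_params()) {
  if (any(F_in < 0)) stop("F_in must be non-negative", call. = FALSE)
  k <- 2 * F_in / params$V_cap
  tibble::tibble(
    J_O2_c = k * (params$O2_a - O2_c),
    J_GLC_c = k * (params$GLC_a - GLC_c),
    J_LAC_c = k * (params$LAC_a - LAC_c),
    O2c_bar = 2 * O2_c - params$O2_a
  )
}

#' Neuronal membrane currents
#'
#' Hodgkin-Huxley currents with instantaneous sodium activation (m_inf^3 h),
#' continuously recomputed sodium reversal potential, high-threshold calcium
#' current, calcium-gated potassium (mAHP) current and the electrogenic pump
#' current. The leak reversal absorbs baseline sodium and potassium leaks.
#'
#' @param psi Membrane voltage, mV. @param h,n_gate Gating variables.
#' @param Na_n,ATP_n,Ca Neuronal sodium, ATP and calcium, mM.
#' @param params An [ngv_params()] list.
#' @return A tibble with `I_L`, `I_Na`, `I_K`, `I_Ca`, `I_mAHP`, `I_pump`
#'   (mS cm^-2 mV, i.e. uA cm^-2).
#' @export
hh_currents <- function(psi, h, n_gate, Na_n, ATP_n, Ca, params = ngv_params()) {
  if (any(Na_n <= 0)) stop("Na_n must be positive", call. = FALSE)
  g <- gate_kinetics(psi)
  E_Na <- params$RTF * log(params$Na_e / Na_n)
  E_L <- (params$gKpas * params$E_K + params$gNa_n * E_Na) /
    (params$gKpas + params$gNa_n)
  tibble::tibble(
    I_L = params$g_L * (psi - E_L),
    I_Na = params$g_Na * g$m_inf^3 * h * (psi - E_Na),
    I_K = params$g_K * n_gate^4 * (psi - params$E_K),
    I_Ca = params$g_Ca * g$m_Ca^2 * (psi - params$E_Ca),
    I_mAHP = params$g_mAHP * Ca / (Ca + params$K_D) * (psi - params$E_K),
    I_pump = params$Faraday * params$k_pump_n * ATP_n * (Na_n - params$Na0_n) /
      (1 + ATP_n / params$K_m_pump)
  )
}

#' Venous balloon outflow
#'
#' Direct evaluation of the outflow law
#' `F_out = F_0 * ((Vv/Vv0)^(1/alpha_v) + tau_v/Vv0 * (Vv/Vv0)^(-1/2) * dVv/dt)`.
#' During integration the implicit pair with `dVv/dt = F_in - F_out` is
#' resolved algebraically by [balloon_outflow_resolved()].
#'
#' @param Vv Venous volume fraction. @param dVv_dt Its rate of change, 1/s.
#' @param params An [ngv_params()] list.
#' @return Outflow, 1/s.
#' @export
balloon_outflow <- function(Vv, dVv_dt, params = ngv_params()) {
  if (any(Vv <= 0)) stop("Vv must be positive", call. = FALSE)
  v <- Vv / params$Vv_0
  params$F_0 * (v^(1 / params$alpha_v) +
                  params$tau_v / params$Vv_0 * v^(-1 / 2) * dVv_dt)
}

#' @rdname balloon_outflow
#' @param F_in Inflow, 1/s.
#' @export
balloon_outflow_resolved <- function(Vv, F_in, params = ngv_params()) {
  if (any(Vv <= 0)) stop("Vv must be positive", call. = FALSE)
  v <- Vv / params$Vv_0
  a <- params$F_0 * params$tau_v / params$Vv_0 / sqrt(v)
  (params$F_0 * v^(1 / params$alpha_v) + a * F_in) / (1 + a)
}

# coerce a state (named vector or data frame) into a list of columns in
# canonical order
.state_cols <- function(state) {
  if (is.data.frame(state)) {
    missing <- setdiff(.state_names, names(state))
    if (length(missing)) stop("state lacks column(s): ", paste(missing, collapse = ", "))
    as.list(state[.state_names])
  } else {
    missing <- setdiff(.state_names, names(state))
    if (length(missing)) stop("state lacks entrie(s): ", paste(missing, collapse = ", "))
    as.list(state[.state_names])
  }
}

#' Evaluate every flux and current at a state
#'
#' @param state Named numeric vector over [state_names()], or a data frame of
#'   such rows (e.g. a trajectory), in which case all outputs are vectorized.
#' @param params An [ngv_params()] list.
#' @param inputs A list with elements `f_exc` (Hz), `F_in` (1/s); both may be
#'   vectors matching the state rows. Defaults to resting inputs
#'   (no stimulus, baseline flow).
#' @return A tibble of fluxes (mM/s), currents (uA cm^-2), drives and flows.
#' @export
compute_fluxes <- function(state, params = ngv_params(),
                           inputs = list(f_exc = 0, F_in = params$F_0)) {
  s <- .state_cols(state)
  f_exc <- inputs$f_exc %||% 0
  F_in <- inputs$F_in %||% params$F_0
  stim_on <- inputs$stim_on %||% (f_exc > 0)

  aden_n <- adenylate_closure(s$ATP_n, params)
  aden_g <- adenylate_closure(s$ATP_g, params)

  pl_n <- pump_and_leak(s$Na_n, s$ATP_n, s$psi_n, params, "neuron")
  pl_g <- pump_and_leak(s$Na_g, s$ATP_g, params$psi_g, params, "astrocyte")

  gly_n <- glycolysis_fluxes(s$GLC_n, s$GAP_n, s$PEP_n, s$ATP_n, aden_n$ADP,
                             s$NADH_cyto_n, params, "neuron")
  gly_g <- glycolysis_fluxes(s$GLC_g, s$GAP_g, s$PEP_g, s$ATP_g, aden_g$ADP,
                             s$NADH_cyto_g, params, "astrocyte")

  mito_n <- mito_fluxes(s$PYR_n, s$O2_n, aden_n$ADP, s$NADH_mito_n, params, "neuron")
  mito_g <- mito_fluxes(s$PYR_g, s$O2_g, aden_g$ADP, s$NADH_mito_g, params, "astrocyte")

  cap <- capillary_flows(s$O2_c, s$GLC_c, s$LAC_c, F_in, params)
  hh <- hh_currents(s$psi_n, s$h, s$n_gate, s$Na_n, s$ATP_n, s$Ca, params)

  # synaptic conductance and drives (scenario-level forms; see stimulus module)
  g_exc <- inputs$g_exc %||% ((inputs$N_exc %||% 1500) * (inputs$g_bar %||% 7.8e-6) * f_exc)
  I_syn <- g_exc * ((inputs$E_AMPA %||% 0) - s$psi_n)
  Jstim_n <- ifelse(stim_on,
                    params$SmVn / params$Faraday * (2 / 3 * I_syn - hh$I_Na), 0)
  Jstim_g <- 3 * (inputs$delta_glut %||% 2.25e-5) * (inputs$N_exc %||% 1500) * f_exc

  F_out <- balloon_outflow_resolved(s$Vv, F_in, params)

  tibble::tibble(
    ADP_n = aden_n$ADP, ADP_g = aden_g$ADP,
    dAMP_dATP_n = aden_n$dAMP_dATP, dAMP_dATP_g = aden_g$dAMP_dATP,
    J_pump_n = pl_n$J_pump, J_pump_g = pl_g$J_pump,
    J_leak_Na_n = pl_n$J_leak_Na, J_leak_Na_g = pl_g$J_leak_Na,
    J_GLC_en = carrier_flux(s$GLC_e, s$GLC_n, params$Tmax_GLC_en, params$Kt_GLC_en),
    J_GLC_eg = carrier_flux(s$GLC_e, s$GLC_g, params$Tmax_GLC_eg, params$Kt_GLC_eg),
    J_GLC_cg = carrier_flux(s$GLC_c, s$GLC_g, params$Tmax_GLC_cg, params$Kt_GLC_cg),
    J_GLC_ce = carrier_flux(s$GLC_c, s$GLC_e, params$Tmax_GLC_ce, params$Kt_GLC_ce),
    J_HKPFK_n = gly_n$J_HKPFK, J_HKPFK_g = gly_g$J_HKPFK,
    J_PGK_n = gly_n$J_PGK, J_PGK_g = gly_g$J_PGK,
    J_PK_n = gly_n$J_PK, J_PK_g = gly_g$J_PK,
    J_LDH_n = ldh_flux(s$PYR_n, s$LAC_n, s$NADH_cyto_n, params, "neuron"),
    J_LDH_g = ldh_flux(s$PYR_g, s$LAC_g, s$NADH_cyto_g, params, "astrocyte"),
    J_LAC_ne = carrier_flux(s$LAC_n, s$LAC_e, params$Tmax_LAC_ne, params$Kt_LAC_ne),
    J_LAC_ge = carrier_flux(s$LAC_g, s$LAC_e, params$Tmax_LAC_ge, params$Kt_LAC_ge),
    J_LAC_gc = carrier_flux(s$LAC_g, s$LAC_c, params$Tmax_LAC_gc, params$Kt_LAC_gc),
    J_LAC_ec = carrier_flux(s$LAC_e, s$LAC_c, params$Tmax_LAC_ec, params$Kt_LAC_ec),
    J_mito_in_n = mito_n$J_mito_in, J_mito_in_g = mito_g$J_mito_in,
    J_mito_out_n = mito_n$J_mito_out, J_mito_out_g = mito_g$J_mito_out,
    J_shuttle_n = nadh_shuttle_flux(s$NADH_cyto_n, s$NADH_mito_n, params, "neuron"),
    J_shuttle_g = nadh_shuttle_flux(s$NADH_cyto_g, s$NADH_mito_g, params, "astrocyte"),
    J_CK_n = creatine_kinase_flux(aden_n$ADP, s$ATP_n, s$PCr_n, params, "neuron"),
    J_CK_g = creatine_kinase_flux(aden_g$ADP, s$ATP_g, s$PCr_g, params, "astrocyte"),
    J_O2mc_n = oxygen_exchange_flux(s$O2_n, s$O2_c, params, "neuron"),
    J_O2mc_g = oxygen_exchange_flux(s$O2_g, s$O2_c, params, "astrocyte"),
    J_O2_c = cap$J_O2_c, J_GLC_c = cap$J_GLC_c, J_LAC_c = cap$J_LAC_c,
    O2c_bar = cap$O2c_bar,
    I_L = hh$I_L, I_Na = hh$I_Na, I_K = hh$I_K, I_Ca = hh$I_Ca,
    I_mAHP = hh$I_mAHP, I_pump = hh$I_pump, I_syn = I_syn,
    g_exc = g_exc, f_exc = f_exc + 0 * s$psi_n,
    Jstim_n = Jstim_n, Jstim_g = Jstim_g,
    F_in = F_in + 0 * s$psi_n, F_out = F_out
  )
}

#' Assemble the full right-hand side
#'
#' Evaluates every governing equation of the model at a state, applying
#' volume-ratio factors between compartments, the NADH sub-volume factors
#' 1/(1-xi) and 1/xi, the adenylate correction 1/(1 - dAMP/dATP), and the
#' extra astrocytic pump stoichiometry of the glutamate-cycling ATP cost.
#' Entries selected by `clamp` return a zero derivative.
#'
#' @param t Time, s (only relayed to `inputs` bookkeeping; the RHS itself is
#'   autonomous given the inputs).
#' @param state Named numeric vector over [state_names()].
#' @param params An [ngv_params()] list.
#' @param inputs As in [compute_fluxes()].
#' @param clamp Character vector of state names whose derivative is zeroed
#'   (e.g. the capillary/vascular states in the in vitro scenario).
#' @return Named numeric vector of derivatives (per second).
#' @export
compute_derivatives <- function(t, state, params = ngv_params(),
                                inputs = list(f_exc = 0, F_in = params$F_0),
                                clamp = character()) {
  s <- .state_cols(state)
  fl <- compute_fluxes(state, params, inputs)
  r_en <- params$V_e / params$V_n; r_eg <- params$V_e / params$V_g
  r_ce <- params$V_cap / params$V_e
  r_cg <- params$V_cap / params$V_g; r_cn <- params$V_cap / params$V_n
  xi <- params$xi

  d <- c(
    Na_n = fl$J_leak_Na_n - 3 * fl$J_pump_n + fl$Jstim_n,
    Na_g = fl$J_leak_Na_g - 3 * fl$J_pump_g + fl$Jstim_g,
    GLC_n = fl$J_GLC_en - fl$J_HKPFK_n,
    GLC_g = fl$J_GLC_cg + fl$J_GLC_eg - fl$J_HKPFK_g,
    GAP_n = 2 * fl$J_HKPFK_n - fl$J_PGK_n,
    GAP_g = 2 * fl$J_HKPFK_g - fl$J_PGK_g,
    PEP_n = fl$J_PGK_n - fl$J_PK_n,
    PEP_g = fl$J_PGK_g - fl$J_PK_g,
    PYR_n = fl$J_PK_n - fl$J_LDH_n - fl$J_mito_in_n,
    PYR_g = fl$J_PK_g - fl$J_LDH_g - fl$J_mito_in_g,
    LAC_n = fl$J_LDH_n - fl$J_LAC_ne,
    LAC_g = fl$J_LDH_g - fl$J_LAC_ge - fl$J_LAC_gc,
    NADH_cyto_n = (fl$J_PGK_n - fl$J_LDH_n - fl$J_shuttle_n) / (1 - xi),
    NADH_cyto_g = (fl$J_PGK_g - fl$J_LDH_g - fl$J_shuttle_g) / (1 - xi),
    NADH_mito_n = (4 * fl$J_mito_in_n - fl$J_mito_out_n + fl$J_shuttle_n) / xi,
    NADH_mito_g = (4 * fl$J_mito_in_g - fl$J_mito_out_g + fl$J_shuttle_g) / xi,
    ATP_n = (-2 * fl$J_HKPFK_n + fl$J_PGK_n + fl$J_PK_n - params$JATPases_n -
               fl$J_pump_n + 3.6 * fl$J_mito_out_n + fl$J_CK_n) /
      (1 - fl$dAMP_dATP_n),
    ATP_g = (-2 * fl$J_HKPFK_g + fl$J_PGK_g + fl$J_PK_g - params$JATPases_g -
               7 / 4 * fl$J_pump_g + 3 / 4 * params$Jpump0_g +
               3.6 * fl$J_mito_out_g + fl$J_CK_g) / (1 - fl$dAMP_dATP_g),
    PCr_n = -fl$J_CK_n,
    PCr_g = -fl$J_CK_g,
    O2_n = fl$J_O2mc_n - 0.6 * fl$J_mito_out_n,
    O2_g = fl$J_O2mc_g - 0.6 * fl$J_mito_out_g,
    O2_c = fl$J_O2_c - fl$J_O2mc_n / r_cn - fl$J_O2mc_g / r_cg,
    GLC_c = fl$J_GLC_c - fl$J_GLC_ce / r_ce - fl$J_GLC_cg / r_cg,
    LAC_c = fl$J_LAC_c + fl$J_LAC_ec / r_ce + fl$J_LAC_gc / r_cg,
    GLC_e = fl$J_GLC_ce - fl$J_GLC_eg / r_eg - fl$J_GLC_en / r_en,
    LAC_e = fl$J_LAC_ne / r_en + fl$J_LAC_ge / r_eg - fl$J_LAC_ec,
    Vv = fl$F_in - fl$F_out,
    dHb = fl$F_in * (params$O2_a - fl$O2c_bar) - fl$F_out * s$dHb / s$Vv,
    psi_n = (-fl$I_L - fl$I_Na - fl$I_K - fl$I_Ca - fl$I_mAHP - fl$I_pump +
               fl$I_syn) / params$C_m,
    h = NA_real_, n_gate = NA_real_,
    Ca = -params$SmVn / params$Faraday * fl$I_Ca -
      (s$Ca - params$Ca_0) / params$tau_Ca
  )
  g <- gate_kinetics(s$psi_n)
  d[["h"]] <- params$phi_h * (g$h_inf - s$h) / g$tau_h
  d[["n_gate"]] <- params$phi_n * (g$n_inf - s$n_gate) / g$tau_n

  if (length(clamp)) d[clamp] <- 0
  d[.state_names]
}
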