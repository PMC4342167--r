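# External drives: presynaptic glutamatergic input and cerebral blood flow,
# and the three experimental scenarios built from them.

#' Stimulus specification
#'
#' A rate-coded presynaptic population of `N_exc` excitatory neurons firing at
#' a frequency that decays exponentially from `f_0` to `f_inf` during the
#' stimulation window.
#'
#' @param N_exc Number of presynaptic neurons.
#' @param g_bar Surface under the conductance evoked by one event,
#'   mS cm^-2 s.
#' @param f_0,f_inf Initial and asymptotic presynaptic rates, Hz.
#' @param tau_f Rate decay time constant, s.
#' @param delta_glut Glutamate released per presynaptic spike scaled by the
#'   synaptic/astrocytic volume ratio, mM.
#' @param t_0,t_end Stimulation onset and offset, s.
#' @param E_AMPA AMPA reversal potential, mV.
#' @return A list of class `ngv_stimulus`.
#' @export
stimulus_spec <- function(N_exc = 1500, g_bar = 7.8e-6, f_0 = 3.2,
                          f_inf = 0.5, tau_f = 2.5, delta_glut = 2.25e-5,
                          t_0 = 0, t_end = 20, E_AMPA = 0) {
  stopifnot(f_0 >= f_inf, f_inf >= 0, tau_f > 0, t_end > t_0)
  structure(list(N_exc = N_exc, g_bar = g_bar, f_0 = f_0, f_inf = f_inf,
                 tau_f = tau_f, delta_glut = delta_glut, t_0 = t_0,
                 t_end = t_end, E_AMPA = E_AMPA),
            class = c("ngv_stimulus", "list"))
}

#' Flow specification
#'
#' Piecewise double-exponential functional hyperemia: baseline `F_0` until a
#' hemodynamic delay `t_1` after stimulus onset, then
#' `F_0 * (plateau + amp * (exp(-(t-t_1)/tau_a) - exp(-(t-t_1)/tau_b)))`
#' during stimulation, relaxing back to baseline with `recovery_tau` after
#' `t_end`. `profile_kind = "constant"` keeps `F_0` throughout (in vitro).
#'
#' @param F_0 Baseline flow, 1/s.
#' @param t_1 Hemodynamic delay after stimulus onset, s.
#' @param rise_tau,fall_tau Double-exponential time constants, s.
#' @param recovery_tau Post-stimulus relaxation time constant, s.
#' @param plateau Sustained flow elevation factor during stimulation.
#' @param amp Amplitude of the transient double-exponential term.
#' @param profile_kind `"rodent"`, `"human"` or `"constant"`.
#' @return A list of class `ngv_flow`.
#' @export
flow_spec <- function(F_0 = 0.012, t_1 = 1, rise_tau = 5, fall_tau = 2,
                      recovery_tau = 5, plateau = 1.1, amp = 1.5,
                      profile_kind = c("rodent", "human", "constant")) {
  profile_kind <- match.arg(profile_kind)
  stopifnot(F_0 > 0, rise_tau > 0, fall_tau > 0, recovery_tau > 0)
  structure(list(F_0 = F_0, t_1 = t_1, rise_tau = rise_tau,
                 fall_tau = fall_tau, recovery_tau = recovery_tau,
                 plateau = plateau, amp = amp, profile_kind = profile_kind),
            class = c("ngv_flow", "list"))
}

#' Presynaptic excitatory rate
#'
#' @param t Time, s (vectorized).
#' @param spec A [stimulus_spec()].
#' @return Rate, Hz; zero outside the stimulation window.
#' @export
#' @examples
#' excitatory_rate(0, stimulus_spec())    # 3.2 Hz at onset
excitatory_rate <- function(t, spec = stimulus_spec()) {
  inside <- t >= spec$t_0 & t <= spec$t_end
  ifelse(inside,
         spec$f_inf + (spec$f_0 - spec$f_inf) * exp(-(t - spec$t_0) / spec$tau_f),
         0)
}

#' Synaptic conductance, current and neuronal sodium drive
#'
#' The excitatory conductance is `g_exc = N_exc * g_bar * f_exc(t)`; the AMPA
#' current `I_syn = g_exc * (E_AMPA - psi)` (depolarizing positive); about two
#' thirds of it is carried by sodium, and voltage-gated sodium entry during
#' action potentials adds `-I_Na`, giving the drive
#' `Jstim_n = SmVn/F * (2/3 * I_syn - I_Na)`.
#'
#' @param t Time, s. @param psi Membrane voltage, mV.
#' @param I_Na Voltage-gated sodium current, uA cm^-2.
#' @param spec A [stimulus_spec()].
#' @param params An [ngv_params()] list.
#' @return A tibble with `g_exc` (mS cm^-2), `I_syn` (uA cm^-2), `Jstim_n` (mM/s).
#' @export
synaptic_drive <- function(t, psi, I_Na = 0, spec = stimulus_spec(),
                           params = ngv_params()) {
  f <- excitatory_rate(t, spec)
  g_exc <- spec$N_exc * spec$g_bar * f
  I_syn <- g_exc * (spec$E_AMPA - psi)
  # the drive (including its voltage-gated -I_Na term) is active only while
  # the presynaptic population actually fires
  Jstim <- ifelse(f > 0,
                  params$SmVn / params$Faraday * (2 / 3 * I_syn - I_Na), 0)
  tibble::tibble(g_exc = g_exc, I_syn = I_syn, Jstim_n = Jstim)
}

#' Astrocytic sodium drive from glutamate uptake
#'
#' Excitatory amino acid transporters co-transport 3 Na+ per glutamate:
#' `Jstim_g = 3 * delta_glut * N_exc * f_exc(t)`.
#'
#' @param t Time, s.
#' @param spec A [stimulus_spec()].
#' @return Drive, mM/s.
#' @export
astrocytic_drive <- function(t, spec = stimulus_spec()) {
  3 * spec$delta_glut * spec$N_exc * excitatory_rate(t, spec)
}

#' Cerebral blood flow time course
#'
#' @param t Time, s (vectorized).
#' @param spec A [flow_spec()].
#' @param t_end Stimulation offset, s.
#' @return Inflow, 1/s. Continuous everywhere except for the onset step to
#'   `plateau * F_0` at `t_1`.
#' @export
cbf <- function(t, spec = flow_spec(), t_end = 60) {
  if (spec$profile_kind == "constant") return(rep(spec$F_0, length(t)))
  stim_shape <- function(tt) {
    spec$F_0 * (spec$plateau + spec$amp *
                  (exp(-(tt - spec$t_1) / spec$rise_tau) -
                     exp(-(tt - spec$t_1) / spec$fall_tau)))
  }
  Fend <- if (t_end >= spec$t_1) stim_shape(t_end) else spec$F_0
  out <- rep(spec$F_0, length(t))
  mid <- t >= spec$t_1 & t <= t_end
  out[mid] <- stim_shape(t[mid])
  late <- t > t_end
  out[late] <- spec$F_0 + (Fend - spec$F_0) * exp(-(t[late] - t_end) / spec$recovery_tau)
  out
}

# states clamped in the in vitro preparation (perfused slice: capillary and
# vascular variables held at rest)
.invitro_clamp <- c("O2_c", "GLC_c", "LAC_c", "Vv", "dHb")

#' Build an experimental scenario
#'
#' * `in_vitro`: 20 s stimulation, constant flow, capillary/vascular states
#'   (`O2_c`, `GLC_c`, `LAC_c`, `Vv`, `dHb`) clamped at their resting values,
#'   mimicking a perfused acute slice.
#' * `in_vivo_rodent`: 60 s stimulation, functional hyperemia with a 1 s
#'   delay, nothing clamped.
#' * `in_vivo_human`: 900 s stimulation, same hyperemia shape (the human
#'   profile constants are configurable via `overrides`), nothing clamped.
#'
#' @param kind Scenario name.
#' @param stim_duration Stimulation length override, s.
#' @param overrides Named list applied over the scenario fields, e.g.
#'   `list(flow = list(t_1 = 2))`.
#' @return A list of class `ngv_scenario` with fields `kind`, `stimulus`,
#'   `flow`, `clamped_states`, `total_duration`.
#' @export
#' @examples
#' make_scenario("in_vitro")$clamped_states
make_scenario <- function(kind = c("in_vitro", "in_vivo_rodent", "in_vivo_human"),
                          stim_duration = NULL, overrides = list()) {
  kind <- match.arg(kind)
  dur <- switch(kind, in_vitro = 20, in_vivo_rodent = 60, in_vivo_human = 900)
  if (!is.null(stim_duration)) dur <- stim_duration
  stim <- stimulus_spec(t_0 = 0, t_end = dur)
  flow <- switch(kind,
    in_vitro = flow_spec(profile_kind = "constant"),
    in_vivo_rodent = flow_spec(profile_kind = "rodent", t_1 = 1),
    in_vivo_human = flow_spec(profile_kind = "human", t_1 = 1)
  )
  clamp <- if (kind == "in_vitro") .invitro_clamp else character()
  total <- switch(kind, in_vitro = dur + 70, in_vivo_rodent = dur + 140,
                  in_vivo_human = dur + 300)
  sc <- list(kind = kind, stimulus = stim, flow = flow,
             clamped_states = clamp, total_duration = total)
  for (field in names(overrides)) {
    if (!field %in% names(sc)) stop("unknown scenario field: ", field)
    if (is.list(overrides[[field]])) {
      for (k in names(overrides[[field]])) {
        if (!k %in% names(sc[[field]])) {
          stop("unknown ", field, " field: ", k)
        }
        sc[[field]][[k]] <- overrides[[field]][[k]]
      }
    } else {
      sc[[field]] <- overrides[[field]]
    }
  }
  structure(sc, class = c("ngv_scenario", "list"))
}

#' @export
print.ngv_scenario <- function(x, ...) {
  cat("<ngv_scenario> ", x$kind, ": stimulation ",
      x$stimulus$t_0, "-", x$stimulus$t_end, " s, flow profile ",
      x$flow$profile_kind,
      if (length(x$clamped_states)) paste0(", clamped: ",
        paste(x$clamped_states, collapse = ", ")) else "",
      ", total ", x$total_duration, " s\n", sep = "")
  invisible(x)
}
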