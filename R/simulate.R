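# Stiff integration of the full system under a scenario, steady-state
# solving and linear stability analysis.

# parameter names in the exact order expected by the compiled code
.c_param_names <- c(
  "V_e", "V_cap", "V_g", "V_n", "xi", "SmVn", "SmVg", "RTF", "Faraday",
  "psi_g", "Na_e",
  "Kt_GLC_en", "Kt_GLC_eg", "Kt_GLC_cg", "Kt_GLC_ce",
  "Kt_LAC_ne", "Kt_LAC_ge", "Kt_LAC_gc", "Kt_LAC_ec",
  "K_I_ATP", "nH", "K_g", "K_O2", "HbOP", "nh", "K_O2_mito",
  "C_m", "g_L", "g_Na", "g_K", "g_Ca", "g_mAHP", "K_D", "tau_Ca", "Ca_0",
  "E_K", "E_Ca", "phi_n", "phi_h", "tau_v", "alpha_v", "O2_a", "GLC_a",
  "gNa_n", "gNa_g", "gKpas", "k_pump_n", "k_pump_g", "Jpump0_g", "K_m_pump",
  "Ctot", "Ntot", "Atot", "q_AK", "K_m_mito", "F_0", "Vv_0", "k1", "k2", "k3",
  "Na0_n",
  "kLDHp_n", "kLDHp_g", "M_cyto_n", "M_cyto_g", "M_mito_n", "M_mito_g",
  "K_m_ADP_n", "K_m_ADP_g", "K_m_NADH_n", "K_m_NADH_g",
  "kCKp_n", "kCKp_g", "K_m_NAD_n", "K_m_NAD_g",
  "Tmax_GLC_en", "Tmax_GLC_ce", "Tmax_GLC_eg", "Tmax_GLC_cg",
  "Tmax_LAC_gc", "Tmax_LAC_ne", "Tmax_LAC_ge", "Tmax_LAC_ec",
  "kHKPFK_n", "kHKPFK_g", "kLDHm_n", "kLDHm_g", "PScapVn", "PScapVg",
  "Vmax_out_n", "Vmax_out_g", "Vmax_in_n", "Vmax_in_g",
  "kPGK_n", "kPGK_g", "kPK_n", "kPK_g", "JATPases_n", "JATPases_g",
  "kCKm_n", "kCKm_g", "TNADH_n", "TNADH_g", "LAC_a"
)

# full parameter vector for the compiled RHS: model parameters, scenario
# scalars, clamp mask
.build_parms <- function(params, scenario = NULL, quiescent = FALSE,
                         clamp = NULL) {
  base <- unlist(params[.c_param_names])
  if (is.null(scenario)) {
    stim <- c(stim_t0 = 0, stim_tend = 1, f0 = 0, finf = 0, tauf = 2.5,
              Nexc = 1500, gbar = 7.8e-6, dglut = 2.25e-5, EAMPA = 0)
    flow <- c(flow_kind = 0, flow_t1 = 1, flow_plateau = 1.1, flow_amp = 1.5,
              flow_tau_a = 5, flow_tau_b = 2, flow_tau_rec = 5)
    cl <- clamp %||% character()
  } else {
    st <- scenario$stimulus; fw <- scenario$flow
    f0 <- if (quiescent) 0 else st$f_0
    finf <- if (quiescent) 0 else st$f_inf
    stim <- c(stim_t0 = st$t_0, stim_tend = st$t_end, f0 = f0, finf = finf,
              tauf = st$tau_f, Nexc = st$N_exc, gbar = st$g_bar,
              dglut = st$delta_glut, EAMPA = st$E_AMPA)
    flow <- c(flow_kind = if (fw$profile_kind == "constant" || quiescent) 0 else 1,
              flow_t1 = fw$t_1, flow_plateau = fw$plateau, flow_amp = fw$amp,
              flow_tau_a = fw$rise_tau, flow_tau_b = fw$fall_tau,
              flow_tau_rec = fw$recovery_tau)
    cl <- clamp %||% scenario$clamped_states
  }
  mask <- as.numeric(.state_names %in% cl)
  c(base, stim, flow, mask)
}

# fast compiled RHS evaluation (dual code path to compute_derivatives())
.rhs_c <- function(t, y, parms) {
  .Call("ngv_rhs_call", as.numeric(t), as.numeric(y[.state_names]),
        as.numeric(parms), PACKAGE = "ngvmet")
}

# default per-state absolute tolerances scaled to resting magnitudes
.default_atol <- function(scale = 1e-8) {
  pmax(abs(resting_state()), 1e-4) * scale
}

.ode_phase <- function(y, t_from, t_to, dt, parms, rtol, atol, hmax) {
  times <- seq(t_from, t_to, by = dt)
  if (times[length(times)] < t_to) times <- c(times, t_to)
  out <- deSolve::ode(y = y, times = times, func = "ngv_derivs",
                      parms = parms, dllname = "ngvmet",
                      initfunc = "ngv_initmod", method = "lsoda",
                      rtol = rtol, atol = atol, hmax = hmax,
                      maxsteps = 5e5)
  if (attr(out, "istate")[1] < 0) {
    stop("integration failed near t = ", max(out[, 1]), " s", call. = FALSE)
  }
  out
}

#' Simulate the model under a scenario
#'
#' Integrates the stiff 33-state system with an adaptive implicit solver.
#' The spiking epoch (stimulation, while the membrane is excitable) is
#' resolved with a step cap of `hmax_spike`; afterwards the step is released
#' to the slow metabolic timescale. Output is sampled densely (`fine_dt`)
#' while spikes can occur and sparsely later.
#'
#' @param scenario An [make_scenario()] scenario.
#' @param params An [ngv_params()] list.
#' @param init Initial state; defaults to the computed steady state
#'   ([find_steady_state()]).
#' @param t_max Simulation end, s (default `scenario$total_duration`).
#' @param rtol,atol Solver tolerances (atol is a per-state vector scaled to
#'   resting magnitudes by default).
#' @param fine_dt Output step during the excitable epoch, s.
#' @param hmax_spike Integrator step cap during the excitable epoch, s.
#' @param spike_window Duration from stimulus onset treated as potentially
#'   spiking, s.
#' @param with_fluxes Annotate the trajectory with all fluxes and currents.
#' @return A tibble of class `ngv_traj`: `time`, the 33 states, input traces
#'   (`f_exc`, `F_in`) and, if requested, every flux/current. Attributes:
#'   `scenario`, `params`, `baseline` (initial state), `spikes` (upward
#'   0 mV crossing times, s).
#' @export
#' @examples
#' \donttest{
#' traj <- simulate_ngv(make_scenario("in_vitro"), t_max = 25)
#' }
simulate_ngv <- function(scenario, params = ngv_params(), init = NULL,
                         t_max = scenario$total_duration,
                         rtol = 1e-8, atol = .default_atol(),
                         fine_dt = 5e-4, hmax_spike = 2.5e-4,
                         spike_window = 30, with_fluxes = TRUE) {
  validate_params(params)
  if (is.null(init)) {
    # the full (unclamped) fixed point; in vitro clamping then holds the
    # capillary/vascular states constant at exactly these values
    init <- find_steady_state(params)$state
  }
  y0 <- init[.state_names]
  parms <- .build_parms(params, scenario)
  st <- scenario$stimulus
  t0 <- st$t_0; tend <- st$t_end
  stopifnot(t_max > tend)

  cut1 <- min(tend, t0 + spike_window)
  segs <- list(list(from = t0, to = cut1, dt = fine_dt, hmax = hmax_spike))
  if (tend > cut1) {
    segs <- c(segs, list(list(from = cut1, to = tend, dt = 0.05, hmax = 0.01)))
  }
  segs <- c(segs, list(list(from = tend, to = min(tend + 1, t_max),
                            dt = 0.01, hmax = 0.01)))
  if (t_max > tend + 1) {
    segs <- c(segs, list(list(from = tend + 1, to = t_max, dt = 0.1, hmax = 1)))
  }

  pieces <- vector("list", length(segs))
  y <- y0
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    out <- .ode_phase(y, s$from, s$to, s$dt, parms, rtol, atol, s$hmax)
    y <- out[nrow(out), -1]
    if (i > 1) out <- out[-1, , drop = FALSE]  # drop duplicated boundary row
    pieces[[i]] <- out
  }
  m <- do.call(rbind, pieces)
  colnames(m) <- c("time", .state_names)
  traj <- tibble::as_tibble(as.data.frame(m))

  traj$f_exc <- excitatory_rate(traj$time, st)
  traj$F_in <- cbf(traj$time, scenario$flow, t_end = tend)

  if (with_fluxes) {
    fl <- compute_fluxes(traj, params,
                         inputs = list(f_exc = traj$f_exc, F_in = traj$F_in,
                                       N_exc = st$N_exc, g_bar = st$g_bar,
                                       delta_glut = st$delta_glut,
                                       E_AMPA = st$E_AMPA))
    fl <- fl[setdiff(names(fl), names(traj))]
    traj <- dplyr::bind_cols(traj, fl)
  }

  spikes <- .detect_spikes(traj$time, traj$psi_n)
  structure(traj,
            class = c("ngv_traj", class(tibble::tibble())),
            scenario = scenario, params = params, baseline = y0,
            spikes = spikes)
}

# upward crossings of psi through 0 mV, linearly interpolated
.detect_spikes <- function(time, psi, threshold = 0) {
  n <- length(psi)
  if (n < 2) return(numeric())
  up <- which(psi[-n] <= threshold & psi[-1] > threshold)
  time[up] + (threshold - psi[up]) / (psi[up + 1] - psi[up]) *
    (time[up + 1] - time[up])
}

#' Spike times of a trajectory
#' @param traj An `ngv_traj`.
#' @return Numeric vector of spike times, s.
#' @export
spike_times <- function(traj) attr(traj, "spikes")

#' Solve for the resting steady state
#'
#' Damped Newton iteration on the (unclamped) right-hand side with a central
#' finite-difference Jacobian using per-state relative steps, seeded from the
#' literature resting state after a quiescent relaxation integration.
#'
#' @param params An [ngv_params()] list.
#' @param clamp Character vector of clamped state names (their values are
#'   frozen at the seed).
#' @param seed Named state vector to start from.
#' @param relax Length of the relaxation integration before Newton, s.
#' @param tol Convergence threshold on the scaled residual norm.
#' @param max_iter Newton iteration cap.
#' @return A list of class `ngv_steady`: `state`, `residual_norm` (max |dy|
#'   scaled by state magnitude, 1/s), `jacobian`, `jacobian_eigenvalues`
#'   (clamped directions excluded), `stable`, `converged`, `clamp`.
#' @export
find_steady_state <- function(params = ngv_params(), clamp = character(),
                              seed = resting_state(), relax = 300,
                              tol = 1e-10, max_iter = 50) {
  validate_params(params)
  parms <- .build_parms(params, NULL, clamp = clamp)
  y <- seed[.state_names]
  scale <- pmax(abs(y), 1e-4)

  free <- which(!.state_names %in% clamp)
  # residuals scaled to the magnitude of the state itself (floored at the
  # seed scale) so that states settling far from their seeds are judged fairly
  res_norm <- function(y) {
    sc <- pmax(abs(y), scale)
    max(abs(.rhs_c(0, y, parms)[free]) / sc[free])
  }

  # Newton works in transformed coordinates: the four NADH states are
  # logit-mapped onto the open pool interval (0, Ntot) so that the pool
  # boundaries (where the shuttle ratios blow up) are unreachable and the
  # residual is mildly nonlinear even for fixed points close to them.
  nadh_idx <- match(c("NADH_cyto_n", "NADH_cyto_g", "NADH_mito_n", "NADH_mito_g"),
                    .state_names)
  N <- params$Ntot
  to_z <- function(y) {
    z <- y
    z[nadh_idx] <- log(y[nadh_idx] / (N - y[nadh_idx]))
    z
  }
  from_z <- function(z) {
    y <- z
    y[nadh_idx] <- N / (1 + exp(-z[nadh_idx]))
    y
  }

  jac_free_z <- function(z) {
    J <- matrix(0, length(free), length(free))
    f0 <- function(z) .rhs_c(0, from_z(z), parms)[free]
    for (jj in seq_along(free)) {
      j <- free[jj]
      dx <- if (j %in% nadh_idx) 1e-6 * max(abs(z[j]), 1) else
        1e-7 * max(abs(z[j]), scale[j])
      zp <- z; zm <- z
      zp[j] <- zp[j] + dx; zm[j] <- zm[j] - dx
      J[, jj] <- (f0(zp) - f0(zm)) / (2 * dx)
    }
    J
  }

  newton <- function(y) {
    z <- to_z(y)
    for (it in seq_len(max_iter)) {
      y <- from_z(z)
      if (res_norm(y) < tol) return(y)
      f <- .rhs_c(0, y, parms)[free]
      J <- jac_free_z(z)
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) return(y)
      lambda <- 1
      repeat {
        z_try <- z
        z_try[free] <- z[free] + lambda * step
        y_try <- from_z(z_try)
        ok <- state_valid(y_try, params) &&
          all(is.finite(.rhs_c(0, y_try, parms)))
        if (ok && res_norm(y_try) < res_norm(y)) break
        lambda <- lambda / 2
        if (lambda < 1e-6) { z_try <- z; break }
      }
      if (identical(z_try, z)) return(from_z(z))
      z <- z_try
    }
    from_z(z)
  }

  # relax towards the attractor, polish with damped Newton; if the slow
  # modes have not entered Newton's basin yet, relax longer and retry
  relax_T <- max(relax, 1)
  for (round in 1:4) {
    out <- .ode_phase(y, 0, relax_T, relax_T / 4, parms, 1e-10,
                      .default_atol(1e-10), 5)
    y <- out[nrow(out), -1]
    names(y) <- .state_names
    y <- newton(y)
    if (res_norm(y) < tol) break
    relax_T <- relax_T * 8
  }
  converged <- res_norm(y) < tol
  if (!converged && res_norm(y) > 1e-6) {
    stop("steady-state solve did not converge; best scaled residual ",
         signif(res_norm(y), 3), call. = FALSE)
  }

  # stability is judged in the physical coordinates
  J <- matrix(0, length(free), length(free))
  for (jj in seq_along(free)) {
    j <- free[jj]
    dx <- 1e-7 * max(abs(y[j]), scale[j])
    yp <- y; ym <- y
    yp[j] <- yp[j] + dx; ym[j] <- ym[j] - dx
    J[, jj] <- (.rhs_c(0, yp, parms)[free] - .rhs_c(0, ym, parms)[free]) / (2 * dx)
  }
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(state = y, residual_norm = res_norm(y), jacobian = J,
                 jacobian_eigenvalues = ev,
                 stable = all(Re(ev) < 0), converged = converged || res_norm(y) < tol,
                 clamp = clamp),
            class = c("ngv_steady", "list"))
}

#' Linear stability verdict
#'
#' Stable iff every eigenvalue of the Jacobian (clamped directions excluded)
#' has a strictly negative real part; marginal spectra (zero real parts) are
#' flagged not stable by convention.
#'
#' @param x An `ngv_steady` report, or a Jacobian matrix.
#' @return A list with `stable` (logical) and `eigenvalues`.
#' @export
stability_check <- function(x) {
  ev <- if (is.matrix(x)) eigen(x, only.values = TRUE)$values
        else x$jacobian_eigenvalues
  list(stable = all(Re(ev) < 0), eigenvalues = ev)
}

#' @export
print.ngv_steady <- function(x, ...) {
  cat("<ngv_steady> scaled residual ", signif(x$residual_norm, 3),
      if (x$stable) ", stable" else ", NOT stable",
      if (length(x$clamp)) paste0(" (clamped: ", paste(x$clamp, collapse = ", "), ")"),
      "\n  psi_n = ", signif(x$state[["psi_n"]], 4), " mV, GLC_e = ",
      signif(x$state[["GLC_e"]], 4), " mM\n", sep = "")
  invisible(x)
}

#' @importFrom tibble tibble
#' @export
tidy.ngv_steady <- function(x, ...) {
  tibble::tibble(variable = names(x$state), value = unname(x$state))
}

#' @export
glance.ngv_steady <- function(x, ...) {
  tibble::tibble(residual_norm = x$residual_norm, stable = x$stable,
                 converged = x$converged,
                 max_re_eigenvalue = max(Re(x$jacobian_eigenvalues)),
                 n_clamped = length(x$clamp))
}

#' @export
glance.ngv_traj <- function(x, ...) {
  sp <- spike_times(x)
  tibble::tibble(
    kind = attr(x, "scenario")$kind,
    duration = max(x$time),
    n_samples = nrow(x),
    n_spikes = length(sp),
    last_spike = if (length(sp)) max(sp) else NA_real_
  )
}

#' Broom-style generics
#'
#' `tidy()` and `glance()` methods are provided for steady-state reports,
#' trajectories and calibration fits.
#' @param x Object. @param ... Unused.
#' @name ngv-broom
#' @export
tidy <- function(x, ...) UseMethod("tidy")
#' @rdname ngv-broom
#' @export
glance <- function(x, ...) UseMethod("glance")
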