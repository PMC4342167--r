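# Shared, lazily computed simulation products reused across test files.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

base_steady <- function() cached("steady", find_steady_state())

traj_invitro <- function() cached("invitro", {
  simulate_ngv(make_scenario("in_vitro"), init = base_steady()$state)
})

traj_rodent <- function() cached("rodent", {
  simulate_ngv(make_scenario("in_vivo_rodent"), init = base_steady()$state)
})

traj_human <- function() cached("human", {
  simulate_ngv(make_scenario("in_vivo_human"), init = base_steady()$state)
})

# no presynaptic input, constant baseline flow
traj_quiescent <- function() cached("quiescent", {
  sc <- make_scenario("in_vivo_rodent",
                      overrides = list(stimulus = list(f_0 = 0, f_inf = 0),
                                       flow = list(profile_kind = "constant")))
  simulate_ngv(sc, init = base_steady()$state, t_max = 101, with_fluxes = FALSE)
})

# self-consistent calibration inputs: relative-NADH targets simulated from a
# fully constrained parameter set (the recovery truth)
selfconsistent_params <- function() cached("sc_params", {
  steady_state_constrain(params = ngv_params())
})

selfconsistent_targets <- function() cached("sc_targets", {
  p0 <- selfconsistent_params()
  ss <- find_steady_state(p0)
  traj <- simulate_ngv(make_scenario("in_vitro"), p0, init = ss$state,
                       t_max = 41, fine_dt = 0.01, with_fluxes = FALSE)
  nadh <- nadh_transients(traj, p0)
  grid <- seq(0, 40, 0.5)
  tgt <- tibble::tibble(time_s = grid)
  for (nm in c("astro_cyto", "neuron_mito", "tissue")) {
    sub <- nadh[nadh$name == nm, ]
    tgt[[paste0(nm, "_pct")]] <- stats::approx(sub$time, sub$value, grid,
                                               rule = 2)$y
  }
  tgt
})

# random valid states around rest for property-style loops
random_states <- function(n, seed = 42) {
  set.seed(seed)
  rest <- resting_state()
  out <- vector("list", n)
  for (i in seq_len(n)) {
    y <- rest * stats::runif(length(rest), 0.9, 1.1)
    names(y) <- names(rest)
    # keep ATP inside the adenine pool
    y[["ATP_n"]] <- rest[["ATP_n"]] * stats::runif(1, 0.8, 1.0)
    y[["ATP_g"]] <- rest[["ATP_g"]] * stats::runif(1, 0.8, 1.0)
    y[["psi_n"]] <- stats::runif(1, -90, -20)
    y[["h"]] <- stats::runif(1, 0.1, 0.99)
    y[["n_gate"]] <- stats::runif(1, 0.01, 0.9)
    out[[i]] <- y
  }
  out
}
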