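# Integration, steady-state solving and stability analysis.

test_that("steady state reproduces the imposed resting values and is stable", {
  ss <- base_steady()
  expect_lt(ss$residual_norm, 1e-9)
  expect_true(ss$converged)
  expect_true(ss$stable)
  expect_equal(ss$state[["psi_n"]], -73, tolerance = 0.02)
  expect_equal(ss$state[["GLC_e"]], 2.48, tolerance = 0.02)
  # the remaining states stay close to their literature seeds
  rest <- resting_state()
  big <- c("Na_n", "Na_g", "GLC_n", "GLC_g", "LAC_e", "O2_c", "GLC_c", "ATP_n",
           "ATP_g", "PCr_n", "PCr_g", "Vv")
  expect_lt(max(abs(ss$state[big] / rest[big] - 1)), 0.05)
})

test_that("steady-state solve is well posed under an enlarged NAD pool", {
  # a half-larger pool still has a finite, stable fixed point with every
  # NADH state strictly inside the pool
  p <- ngv_params(Ntot = 1.5 * 0.212)
  ss <- find_steady_state(p)
  expect_lt(ss$residual_norm, 1e-9)
  expect_true(ss$stable)
  nadh <- ss$state[c("NADH_cyto_n", "NADH_cyto_g", "NADH_mito_n", "NADH_mito_g")]
  expect_true(all(nadh > 0 & nadh < p$Ntot))
  # doubling the pool saturates the astrocytic cytosolic redox state (GAP
  # accumulates without bound); the solver reports this clearly instead of
  # returning a spurious fixed point
  expect_error(find_steady_state(ngv_params(Ntot = 2 * 0.212)), "residual")
})

test_that("stability verdicts follow the Jacobian spectrum", {
  expect_true(base_steady()$stable)
  rot <- matrix(c(0, -1, 1, 0), 2, 2)   # pure rotation: marginal
  expect_false(stability_check(rot)$stable)
  expect_true(stability_check(diag(c(-1, -2)))$stable)
  ev <- stability_check(rot)$eigenvalues
  expect_equal(sort(Im(ev)), c(-1, 1))
})

test_that("integration is deterministic and clamps hold to machine precision", {
  sc <- make_scenario("in_vitro")
  ss <- base_steady()
  a <- simulate_ngv(sc, init = ss$state, t_max = 25, with_fluxes = FALSE)
  b <- simulate_ngv(sc, init = ss$state, t_max = 25, with_fluxes = FALSE)
  expect_identical(as.data.frame(a), as.data.frame(b))
  for (v in sc$clamped_states) {
    expect_lt(max(abs(a[[v]] - a[[v]][1])), 1e-14)
  }
})

test_that("headline observables and spike count are invariant under tolerance refinement", {
  ss <- base_steady()
  sc <- make_scenario("in_vitro")
  run <- function(rtol, scale, hmax) {
    simulate_ngv(sc, init = ss$state, rtol = rtol,
                 atol = ngvmet:::.default_atol(scale), hmax_spike = hmax)
  }
  a <- run(1e-8, 1e-8, 2.5e-4)
  b <- run(5e-9, 5e-9, 1.25e-4)
  dip <- function(tr) min(nadh_transients(tr)$value)
  lac <- function(tr) {
    v <- tissue_mix(tr, "LAC")$value
    mean(v[tr$time >= 13 & tr$time <= 20])
  }
  expect_equal(dip(a), dip(b), tolerance = 0.005)
  expect_equal(lac(a), lac(b), tolerance = 0.005)
  expect_equal(length(spike_times(a)), length(spike_times(b)))
})

test_that("in vitro stimulation: early spiking and the sodium signatures", {
  tr <- traj_invitro()
  sp <- spike_times(tr)
  expect_gt(length(sp), 10)
  expect_lt(max(sp), 7)          # firing stops well before the stimulus ends
  # neuronal sodium: fast rise, recovery under way by 40 s
  t <- tr$time
  peak_n <- max(tr$Na_n); tp_n <- t[which.max(tr$Na_n)]
  expect_lt(tp_n, 10)
  na40 <- tr$Na_n[which.min(abs(t - 40))]
  expect_lt(na40 - tr$Na_n[1], 0.4 * (peak_n - tr$Na_n[1]))
  # astrocytic sodium: smaller but sustained response, delayed recovery
  peak_g <- max(tr$Na_g); tp_g <- t[which.max(tr$Na_g)]
  expect_lt(peak_g - tr$Na_g[1], peak_n - tr$Na_n[1])
  expect_gt(tp_g, tp_n)
  nag40 <- tr$Na_g[which.min(abs(t - 40))]
  expect_gt(nag40 - tr$Na_g[1], 0.6 * (peak_g - tr$Na_g[1]))
})

test_that("trajectories report errors for unsolvable inputs", {
  expect_error(simulate_ngv(make_scenario("in_vitro"), t_max = 10), "t_max")
})
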