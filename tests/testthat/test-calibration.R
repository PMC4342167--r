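# Two-tier parameter determination and reference-curve handling.

test_that("constrained parameters reproduce the published capacities from resting balances", {
  p <- steady_state_constrain(params = ngv_params())
  # the capillary lactate balance pins the extracellular-to-capillary export
  # capacity near its published value (0.25 mM/s)
  expect_equal(p$Tmax_LAC_ec, 0.25, tolerance = 0.05)
  # glucose transport capacities land on the published values within 1%
  expect_equal(p$Tmax_GLC_en, 0.041, tolerance = 0.01)
  expect_equal(p$Tmax_GLC_eg, 0.147, tolerance = 0.01)
  expect_equal(p$Tmax_GLC_ce, 0.239, tolerance = 0.01)
  # every balance that owns a solved parameter vanishes at the rest targets
  d <- compute_derivatives(0, resting_state(), p)
  owned <- c("GLC_n", "GLC_g", "GLC_e", "GAP_n", "GAP_g", "PEP_n", "PEP_g",
             "PYR_n", "PYR_g", "NADH_cyto_n", "NADH_cyto_g", "NADH_mito_n",
             "NADH_mito_g", "ATP_n", "ATP_g", "PCr_n", "PCr_g", "O2_n", "O2_g")
  expect_lt(max(abs(d[owned])), 1e-10)
})

test_that("constraining is idempotent and local to the perturbed balance", {
  p1 <- steady_state_constrain(params = ngv_params())
  p2 <- steady_state_constrain(params = p1)
  expect_identical(unlist(p1), unlist(p2))
  # perturbing a neuron-only rest target leaves astrocytic parameters alone
  rest <- resting_state()
  rest[["GAP_n"]] <- rest[["GAP_n"]] * 1.1
  p3 <- steady_state_constrain(rest, params = ngv_params())
  astro <- c("kPGK_g", "kPK_g", "Vmax_in_g", "TNADH_g", "Vmax_out_g",
             "PScapVg", "JATPases_g", "kCKm_g", "Tmax_GLC_eg")
  expect_identical(unlist(p1[astro]), unlist(p3[astro]))
  expect_false(p3$kPGK_n == p1$kPGK_n)
  # inconsistent targets (no positive solution) are reported with the balance
  rest2 <- resting_state()
  rest2[["PYR_n"]] <- 20   # LDH runs forward so fast the TCA flux turns negative
  expect_error(steady_state_constrain(rest2, params = ngv_params()), "pyruvate")
})

test_that("sums of exponentials recover generating curves and degrade gracefully", {
  t <- seq(0, 60, 0.5)
  y <- 2.5 - 8 * exp(-t / 3) + 5.5 * exp(-t / 25)
  pts <- tibble::tibble(time_s = t, curve = y)
  sm <- smooth_reference_curves(pts, n_terms = 2)
  yhat <- eval_target_curves(sm, t)$curve
  expect_lt(max(abs(yhat - y)), 0.01 * diff(range(y)))
  expect_lt(glance(sm)$rss, 1e-10)
  # constant series reduce to the offset term with zero residual
  sm2 <- smooth_reference_curves(tibble::tibble(time_s = t, flat = rep(3, length(t))))
  expect_equal(eval_target_curves(sm2, c(0, 10))$flat, c(3, 3))
  expect_error(smooth_reference_curves(tibble::tibble(time_s = 1:3, y = 1:3)),
               "6 points")
})

test_that("the synthetic fixture keeps its declared structure through smoothing", {
  fx <- generate_nadh_fixture()
  gt <- attr(fx, "ground_truth")
  expect_equal(min(fx$neuron_mito_pct), -10, tolerance = 0.01)
  expect_equal(fx$time_s[which.min(fx$neuron_mito_pct)], 5, tolerance = 0.1)
  sm <- smooth_reference_curves(fx, n_terms = 3)
  grid <- seq(0, 60, 0.1)
  yy <- eval_target_curves(sm, grid)$neuron_mito_pct
  expect_equal(min(yy), min(fx$neuron_mito_pct), tolerance = 0.05)
})

test_that("fitting with targets equal to the model output gives zero error at the start", {
  p0 <- selfconsistent_params()
  tgt <- selfconsistent_targets()
  # empty free set echoes the starting parameters and scores them
  fit0 <- fit_free_parameters(tgt, character(), init = p0,
                              scenario = make_scenario("in_vitro"))
  expect_identical(unlist(fit0$params), unlist(p0))
  expect_lt(fit0$sse, 1e-6)
  expect_true(fit0$converged)
})

test_that("moderate parameter fluctuations preserve the qualitative behaviour", {
  # the free kinetic constants fluctuate by up to +-10%; the constrained
  # block is re-derived from the resting balances, as it is not independent
  set.seed(202)
  g <- param_groups()
  opt <- g$name[g$group == "optimized"]
  for (draw in 1:3) {
    p <- ngv_params()
    for (nm in opt) p[[nm]] <- p[[nm]] * stats::runif(1, 0.9, 1.1)
    p <- steady_state_constrain(params = p)
    ss <- find_steady_state(p)
    expect_lt(ss$residual_norm, 1e-9)
    expect_true(ss$stable)
    tr <- simulate_ngv(make_scenario("in_vitro"), p, init = ss$state,
                       t_max = 45, fine_dt = 0.01, with_fluxes = FALSE)
    met <- attr(nadh_transients(tr, p), "metrics")
    expect_lt(met$dip[met$name == "neuron_mito"], -2)   # dip persists
    expect_gt(met$peak[met$name == "astro_cyto"], 1)    # astrocytic rise persists
  }
})
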