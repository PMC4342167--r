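# Reaction, transport and current expressions, and right-hand-side assembly.

test_that("adenylate closure matches an independent equilibrium solve and conserves the pool", {
  p <- ngv_params()
  # independent oracle: solve the adenylate-kinase equilibrium
  # ADP^2 = q * ATP * AMP with AMP = A - ATP - ADP by bisection
  oracle_adp <- function(ATP) {
    f <- function(ADP) p$q_AK * (p$Atot - ATP - ADP) * ATP - ADP^2
    stats::uniroot(f, c(0, p$Atot - ATP), tol = 1e-14)$root
  }
  for (ATP in c(0.5, 1.2, 2.0, 2.2, 2.21)) {
    ad <- adenylate_closure(ATP, p)
    expect_equal(ad$ADP, oracle_adp(ATP), tolerance = 1e-9)
    expect_equal(ATP + ad$ADP + ad$AMP, p$Atot, tolerance = 1e-12)
    expect_gte(ad$ADP, 0)
  }
  # frozen value at the resting ATP (bisection oracle gives 0.0119297)
  expect_equal(adenylate_closure(2.2, p)$ADP, 0.0119297, tolerance = 1e-5)
  # full pool held as ATP leaves no ADP or AMP
  ad <- adenylate_closure(p$Atot, p)
  expect_equal(ad$ADP, 0, tolerance = 1e-12)
  expect_equal(ad$AMP, 0, tolerance = 1e-12)
  # analytic dAMP/dATP agrees with numerical differentiation of the closure
  h <- 1e-6
  num <- (adenylate_closure(2.2 + h, p)$AMP - adenylate_closure(2.2 - h, p)$AMP) / (2 * h)
  expect_equal(adenylate_closure(2.2, p)$dAMP_dATP, num, tolerance = 1e-6)
  expect_error(adenylate_closure(-1, p), "ATP")
  expect_error(adenylate_closure(3, p), "ATP")
})

test_that("carrier flux saturates, vanishes at equal concentrations and is antisymmetric", {
  expect_equal(carrier_flux(1.3, 1.3, 2, 0.5), 0)
  expect_equal(carrier_flux(1e9, 0, 2, 0.5), 2, tolerance = 1e-8)
  expect_equal(carrier_flux(0.5, 0, 2, 0.5), 1)  # half saturation
  set.seed(7)
  for (i in 1:50) {
    a <- stats::runif(1, 0, 10); b <- stats::runif(1, 0, 10)
    Tm <- stats::runif(1, 0.01, 100); Kt <- stats::runif(1, 0.1, 10)
    expect_equal(carrier_flux(a, b, Tm, Kt), -carrier_flux(b, a, Tm, Kt),
                 tolerance = 1e-14)
    if (a > b) expect_gt(carrier_flux(a, b, Tm, Kt), 0)
  }
  expect_error(carrier_flux(-1, 0, 1, 1), "negative")
})

test_that("glycolytic fluxes vanish without substrate and respect the NAD pool", {
  p <- ngv_params()
  g <- glycolysis_fluxes(GLC = 0, GAP = 0.005, PEP = 0.015, ATP = 2.2,
                         ADP = 0.012, NADH_cyto = 0.006, p, "neuron")
  expect_equal(g$J_HKPFK, 0)
  g <- glycolysis_fluxes(1.2, GAP = 0, PEP = 0.015, ATP = 2.2, ADP = 0,
                         NADH_cyto = 0.006, p, "neuron")
  expect_equal(g$J_PGK, 0)
  expect_equal(g$J_PK, 0)
  # NAD+ exhausted stops the PGK step
  g <- glycolysis_fluxes(1.2, 0.005, 0.015, 2.2, 0.012,
                         NADH_cyto = p$Ntot, p, "neuron")
  expect_equal(g$J_PGK, 0)
  expect_error(glycolysis_fluxes(1.2, 0.005, 0.015, 2.2, 0.012, 0, p, "neuron"),
               "singular")
})

test_that("LDH flux: zero points and frozen resting values", {
  p <- ngv_params()
  expect_equal(ldh_flux(0, 0, 0.006, p, "neuron"), 0)
  # equilibrium NADH where forward and reverse terms balance (PYR = LAC)
  Neq <- p$Ntot * p$kLDHm_n / (p$kLDHp_n + p$kLDHm_n)
  expect_equal(ldh_flux(0.3, 0.3, Neq, p, "neuron"), 0, tolerance = 1e-14)
  # resting values, independent arithmetic:
  # 72.3*0.17*0.006 - 0.72*0.6*(0.212-0.006) = -0.0152748 (net lactate uptake)
  expect_equal(ldh_flux(0.17, 0.6, 0.006, p, "neuron"),
               72.3 * 0.17 * 0.006 - 0.72 * 0.6 * 0.206, tolerance = 1e-12)
  expect_equal(ldh_flux(0.17, 0.6, 0.006, p, "neuron"), -0.015246,
               tolerance = 1e-6)
  # astrocyte produces lactate at rest
  expect_gt(ldh_flux(0.17, 0.6, 0.1, p, "astrocyte"), 0)
})

test_that("mitochondrial fluxes: substrate limits and saturation ceiling", {
  p <- ngv_params()
  m <- mito_fluxes(PYR = 0.17, O2 = 0, ADP = 0.012, NADH_mito = 0.12, p, "neuron")
  expect_equal(m$J_mito_out, 0)
  m <- mito_fluxes(0.17, 0.028, 0.012, NADH_mito = p$Ntot, p, "neuron")
  expect_equal(m$J_mito_in, 0)
  # saturating oxygen, ADP and the NADH pool approaches the ceiling set by
  # the pool-limited NADH saturation
  m <- mito_fluxes(1e6, 1e6, 1e6, NADH_mito = p$Ntot * (1 - 1e-9), p, "neuron")
  expect_equal(m$J_mito_out, p$Vmax_out_n * p$Ntot / (p$Ntot + p$K_m_NADH_n),
               tolerance = 1e-6)
})

test_that("NADH shuttle saturates and vanishes at pool boundaries", {
  p <- ngv_params()
  expect_equal(nadh_shuttle_flux(1e-13, 0.12, p, "neuron"), 0, tolerance = 1e-6)
  expect_equal(nadh_shuttle_flux(0.006, p$Ntot * (1 - 1e-12), p, "neuron"), 0,
               tolerance = 1e-6)
  # strongly saturated ratios approach the transport ceiling
  p2 <- ngv_params(M_cyto_n = 1e-12, M_mito_n = 1e-12)
  expect_equal(nadh_shuttle_flux(0.1, 0.1, p2, "neuron"), p2$TNADH_n,
               tolerance = 1e-6)
  expect_error(nadh_shuttle_flux(0, 0.12, p, "neuron"), "singular")
})

test_that("creatine kinase flux vanishes at equilibrium and matches direct arithmetic", {
  p <- ngv_params()
  expect_equal(creatine_kinase_flux(0, 2.2, p$Ctot, p, "neuron"), 0)
  # equilibrium: k+ ADP PCr = k- ATP (C - PCr)
  ADP <- 0.012; ATP <- 2.2
  PCr_eq <- p$kCKm_n * ATP * p$Ctot / (p$kCKp_n * ADP + p$kCKm_n * ATP)
  expect_equal(creatine_kinase_flux(ADP, ATP, PCr_eq, p, "neuron"), 0,
               tolerance = 1e-14)
  # rest: direct arithmetic with the closure ADP
  ADP <- adenylate_closure(2.2, p)$ADP
  expect_equal(creatine_kinase_flux(ADP, 2.2, 4.9, p, "neuron"),
               p$kCKp_n * ADP * 4.9 - p$kCKm_n * 2.2 * (10 - 4.9),
               tolerance = 1e-14)
})

test_that("pump and leak: resting pump magnitude, Nernst zero, no fuel no pump", {
  p <- ngv_params()
  pl <- pump_and_leak(8, 2.2, -73, p, "neuron")
  # 2.5e4 * 2.2e-6 * 2.2 * 8 / (1 + 2.2/0.5) = 0.17926 mM/s
  expect_equal(pl$J_pump, 2.5e4 * 2.2e-6 * 2.2 * 8 / (1 + 2.2 / 0.5),
               tolerance = 1e-12)
  expect_equal(pl$J_pump, 0.17926, tolerance = 1e-4)
  # leak vanishes exactly at the sodium Nernst potential
  psi <- -65
  Na_nernst <- p$Na_e * exp(-psi / p$RTF)
  expect_equal(pump_and_leak(Na_nernst, 2.2, psi, p, "neuron")$J_leak_Na, 0,
               tolerance = 1e-10)
  expect_equal(pump_and_leak(8, 0 + 1e-300, -73, p, "neuron")$J_pump, 0,
               tolerance = 1e-12)
  expect_error(pump_and_leak(-1, 2.2, -73, p, "neuron"), "positive")
})

test_that("oxygen exchange: hemoglobin half saturation and resting influx", {
  p <- ngv_params()
  # at half hemoglobin occupancy the equilibrium term equals K_O2
  j <- oxygen_exchange_flux(0, p$HbOP / 2, p, "neuron")
  expect_equal(j, p$PScapVn * p$K_O2, tolerance = 1e-12)
  # small positive influx at rest
  expect_gt(oxygen_exchange_flux(0.028, 7, p, "neuron"), 0)
  expect_lt(oxygen_exchange_flux(0.028, 7, p, "neuron"), 0.1)
  expect_error(oxygen_exchange_flux(0.028, 9, p, "neuron"), "saturation")
})

test_that("capillary flows scale with inflow and vanish at arterial equilibrium", {
  p <- ngv_params()
  cf <- capillary_flows(p$O2_a, 4.5, 0.55, 0.012, p)
  expect_equal(cf$J_O2_c, 0)
  cf <- capillary_flows(7, 4.5, 0.55, 0, p)
  expect_equal(cf$J_O2_c, 0)
  expect_equal(cf$J_GLC_c, 0)
  expect_equal(cf$J_LAC_c, 0)
  # rest: 2 * 0.012 / 0.0055 * (8.35 - 7) = 5.8909 mM/s
  cf <- capillary_flows(7, 4.5, 0.55, 0.012, p)
  expect_equal(cf$J_O2_c, 2 * 0.012 / 0.0055 * 1.35, tolerance = 1e-12)
  expect_equal(cf$J_O2_c, 5.891, tolerance = 1e-3)
  expect_equal(cf$O2c_bar, 2 * 7 - 8.35)
})

test_that("gate kinetics reproduce resting activations and handle removable singularities", {
  g <- gate_kinetics(-73)
  expect_equal(g$n_inf, 0.02, tolerance = 0.01)
  expect_equal(g$h_inf, 0.99, tolerance = 0.01)
  expect_equal(gate_kinetics(-20)$m_Ca, 0.5, tolerance = 1e-12)
  # analytic limits at the singular voltages agree with nearby evaluations
  expect_equal(gate_kinetics(-33)$m_inf, gate_kinetics(-33 + 1e-4)$m_inf,
               tolerance = 1e-4)
  expect_equal(gate_kinetics(-34)$n_inf, gate_kinetics(-34 + 1e-4)$n_inf,
               tolerance = 1e-4)
  expect_true(all(is.finite(unlist(gate_kinetics(seq(-120, 60, by = 0.5))))))
})

test_that("membrane currents: pump zero at resting sodium, potassium currents zero at E_K", {
  p <- ngv_params()
  hh <- hh_currents(psi = -73, h = 0.99, n_gate = 0.02, Na_n = p$Na0_n,
                    ATP_n = 2.2, Ca = 5e-5, p)
  expect_equal(hh$I_pump, 0)
  hh <- hh_currents(p$E_K, 0.99, 0.02, 8, 2.2, 5e-5, p)
  expect_equal(hh$I_K, 0)
  expect_equal(hh$I_mAHP, 0)
  # at Ca = K_D the mAHP current is at half its conductance ceiling
  hh1 <- hh_currents(-60, 0.99, 0.02, 8, 2.2, Ca = p$K_D, p)
  hh2 <- hh_currents(-60, 0.99, 0.02, 8, 2.2, Ca = 1e12, p)
  expect_equal(hh1$I_mAHP, hh2$I_mAHP / 2, tolerance = 1e-9)
})

test_that("balloon outflow: baseline balance, power law, resolved fixed point", {
  p <- ngv_params()
  expect_equal(balloon_outflow(p$Vv_0, 0, p), p$F_0)
  expect_equal(balloon_outflow(p$Vv_0 * 2^p$alpha_v, 0, p), 2 * p$F_0,
               tolerance = 1e-12)
  # the algebraic resolution is a fixed point of the implicit pair
  Fout <- balloon_outflow_resolved(p$Vv_0, p$F_0, p)
  expect_equal(Fout, p$F_0, tolerance = 1e-12)
  Vv <- 0.025; Fin <- 0.015
  Fout <- balloon_outflow_resolved(Vv, Fin, p)
  expect_equal(balloon_outflow(Vv, Fin - Fout, p), Fout, tolerance = 1e-12)
  expect_error(balloon_outflow(-0.01, 0, p), "positive")
})

test_that("derivative assembly: clamping, creatine coupling, adenine conservation", {
  p <- ngv_params()
  y <- resting_state()
  d <- compute_derivatives(0, y, p, clamp = c("O2_c", "GLC_c", "LAC_c", "Vv", "dHb"))
  expect_equal(unname(d[c("O2_c", "GLC_c", "LAC_c", "Vv", "dHb")]), rep(0, 5))
  # phosphocreatine depletion is exactly the creatine kinase flux
  fl <- compute_fluxes(y, p)
  d <- compute_derivatives(0, y, p)
  expect_equal(d[["PCr_n"]], -fl$J_CK_n)
  expect_equal(d[["PCr_g"]], -fl$J_CK_g)
  # adenine pool conserved to 1e-12 at every evaluated state
  for (y2 in random_states(20)) {
    ad <- adenylate_closure(y2[["ATP_n"]], p)
    expect_equal(y2[["ATP_n"]] + ad$ADP + ad$AMP, p$Atot, tolerance = 1e-12)
  }
})

test_that("compiled and transcribed right-hand sides agree on random states", {
  p <- ngv_params()
  set.seed(11)
  states <- random_states(100, seed = 11)
  for (y in states) {
    f <- stats::runif(1, 0, 3.2)
    Fin <- stats::runif(1, 0.012, 0.02)
    dR <- compute_derivatives(0, y, p, inputs = list(f_exc = f, F_in = Fin))
    parms <- ngvmet:::.build_parms(
      p, make_scenario("in_vivo_rodent",
                       overrides = list(stimulus = list(f_0 = f, f_inf = f),
                                        flow = list(t_1 = -1e6, plateau = Fin / p$F_0,
                                                    amp = 0))))
    dC <- ngvmet:::.rhs_c(1, y, parms)
    expect_equal(unname(dR), dC, tolerance = 1e-10)
  }
})
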