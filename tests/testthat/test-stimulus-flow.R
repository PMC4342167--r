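# Presynaptic drive, cerebral blood flow and scenario definitions.

test_that("excitatory rate decays between the stated bounds", {
  sp <- stimulus_spec()
  expect_equal(excitatory_rate(0, sp), 3.2)
  expect_equal(excitatory_rate(19.9, sp), 0.5 + 2.7 * exp(-19.9 / 2.5),
               tolerance = 1e-12)
  expect_lt(abs(excitatory_rate(19.9, sp) - 0.5), 0.002)
  # one decay constant in: f_inf + (f_0 - f_inf)/e = 0.5 + 2.7/e = 1.4933 Hz
  expect_equal(excitatory_rate(2.5, sp), 0.5 + 2.7 * exp(-1), tolerance = 1e-12)
  expect_equal(excitatory_rate(-0.1, sp), 0)
  expect_equal(excitatory_rate(20.1, sp), 0)
})

test_that("synaptic drive: conductance product, reversal zero, inactive without input", {
  sp <- stimulus_spec()
  d <- synaptic_drive(0, psi = -73, I_Na = 0, sp)
  expect_equal(d$g_exc, 1500 * 7.8e-6 * 3.2, tolerance = 1e-12)  # 0.03744
  expect_gt(d$Jstim_n, 0)  # inward sodium raises Na_n
  expect_equal(synaptic_drive(0, psi = 0, I_Na = 0, sp)$I_syn, 0)
  expect_equal(synaptic_drive(30, psi = -73, I_Na = 0, sp)$Jstim_n, 0)
})

test_that("astrocytic drive follows the glutamate uptake stoichiometry", {
  sp <- stimulus_spec()
  expect_equal(astrocytic_drive(0, sp), 3 * 2.25e-5 * 1500 * 3.2)  # 0.324
  expect_equal(astrocytic_drive(0, sp), 0.324, tolerance = 1e-12)
  sp2 <- stimulus_spec(f_0 = 0.5, f_inf = 0.5)
  expect_equal(astrocytic_drive(1, sp2), 0.050625, tolerance = 1e-12)
  expect_equal(astrocytic_drive(30, sp), 0)
})

test_that("blood flow: baseline, transient peak, plateau and recovery", {
  fs <- flow_spec(profile_kind = "rodent")
  expect_equal(cbf(0.5, fs, t_end = 60), 0.012)
  # plateau well into a long stimulation is 1.1 * F_0
  expect_equal(cbf(59, fs, t_end = 60), 1.1 * 0.012, tolerance = 1e-3)
  # transient peak near t_1 + 3 s, roughly +59%
  tt <- seq(1, 10, by = 0.01)
  Fmax <- max(cbf(tt, fs, t_end = 60))
  expect_equal(Fmax / 0.012, 1.589, tolerance = 0.01)
  # recovery relaxes back to baseline and is continuous at t_end
  expect_equal(cbf(1000, fs, t_end = 60), 0.012, tolerance = 1e-9)
  expect_equal(cbf(60 - 1e-9, fs, t_end = 60), cbf(60 + 1e-9, fs, t_end = 60),
               tolerance = 1e-6)
  # constant profile ignores the pulse
  expect_equal(cbf(c(0, 5, 100), flow_spec(profile_kind = "constant"), 60),
               rep(0.012, 3))
  # drives are non-negative
  expect_true(all(cbf(seq(0, 200, 0.1), fs, 60) > 0))
})

test_that("scenarios define the three experiments", {
  sv <- make_scenario("in_vitro")
  expect_setequal(sv$clamped_states, c("O2_c", "GLC_c", "LAC_c", "Vv", "dHb"))
  expect_equal(sv$stimulus$t_end, 20)
  expect_equal(sv$flow$profile_kind, "constant")
  sr <- make_scenario("in_vivo_rodent")
  expect_equal(sr$stimulus$t_end, 60)
  expect_equal(sr$flow$t_1, 1)
  expect_length(sr$clamped_states, 0)
  sh <- make_scenario("in_vivo_human")
  expect_equal(sh$stimulus$t_end, 900)
  expect_error(make_scenario("in_situ"))
  expect_error(make_scenario("in_vitro", overrides = list(bogus = 1)), "unknown")
  sc <- make_scenario("in_vivo_rodent", overrides = list(flow = list(t_1 = 2)))
  expect_equal(sc$flow$t_1, 2)
})

test_that("without input the model rests at its fixed point (drift < 1e-6 over 100 s)", {
  tr <- traj_quiescent()
  y0 <- unlist(tr[1, state_names()])
  yT <- unlist(tr[nrow(tr), state_names()])
  scale <- pmax(abs(y0), 1e-4)
  expect_lt(max(abs(yT - y0) / scale), 1e-6)
})
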