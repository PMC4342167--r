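# Derived read-outs: BOLD, tissue mixtures, NADH transients, metabolic rates,
# lactate transports and firing rate.

test_that("BOLD is zero at baseline and positive when deoxyhemoglobin falls", {
  tr <- traj_rodent()
  b <- bold_signal(tr)
  expect_equal(b$value[1], 0)
  # washed-out deoxyhemoglobin with baseline volume raises the signal
  fake <- tr[1:2, ]
  fake$dHb[2] <- fake$dHb[1] * 0.9
  expect_gt(bold_signal(fake)$value[2], 0)
  # quiescent run: identically zero
  bq <- bold_signal(traj_quiescent())
  expect_lt(max(abs(bq$value)), 1e-9)
})

test_that("tissue mixtures are normalized, bounded by compartments, and linear", {
  tr <- traj_invitro()
  p <- ngv_params()
  for (q in c("NADH", "LAC", "O2")) {
    w <- ngvmet:::.mix_weights(q, p)
    expect_true(all(w > 0))
    m <- tissue_mix(tr, q)
    expect_equal(m$value[1], 0)
    # mixture lies within the envelope of compartment relative series
    rel <- sapply(names(w), function(v) 100 * (tr[[v]] / tr[[v]][1] - 1))
    expect_true(all(m$value <= apply(rel, 1, max) + 1e-9))
    expect_true(all(m$value >= apply(rel, 1, min) - 1e-9))
  }
  # equal +10% deviation in every compartment gives a +10% mixture
  fake <- tr[1:2, ]
  for (v in names(ngvmet:::.mix_weights("LAC", p))) fake[[v]][2] <- fake[[v]][1] * 1.1
  expect_equal(tissue_mix(fake, "LAC")$value[2], 10, tolerance = 1e-9)
})

test_that("NADH transients have the evoked in vitro structure", {
  tr <- traj_invitro()
  nadh <- nadh_transients(tr)
  met <- attr(nadh, "metrics")
  nm <- met[met$name == "neuron_mito", ]
  ac <- met[met$name == "astro_cyto", ]
  # neuronal mitochondria: early dip, recovery towards baseline, late overshoot
  expect_lt(nm$dip, -5)
  expect_lt(nm$dip_time, 10)
  expect_gt(nm$peak, 0)
  expect_gt(nm$peak_time, 20)
  # astrocytic cytosol: delayed, slower, monophasic rise
  expect_gt(ac$peak, 2)
  expect_gt(ac$peak_time, 15)
  ac_curve <- nadh[nadh$name == "astro_cyto", ]
  at10 <- ac_curve$value[which.min(abs(ac_curve$time - 10))]
  expect_lt(at10, 0.4 * ac$peak)
  # zero-stimulus run: transients identically zero
  nq <- nadh_transients(traj_quiescent())
  expect_lt(max(abs(nq$value)), 1e-6)
})

test_that("metabolic rates: resting partition and degenerate OGI flagging", {
  tr <- traj_invitro()
  mr <- metabolic_rates(tr)
  # astrocytes take the larger glucose share, neurons the larger oxygen share
  expect_gt(mr$CMRglc_g[1], mr$CMRglc_n[1])
  expect_gt(mr$CMRO2_n[1], mr$CMRO2_g[1])
  expect_equal(mr$OGI[1], mr$CMRO2[1] / mr$CMRglc[1])
  expect_gt(mr$OGI[1], 4); expect_lt(mr$OGI[1], 6.5)
  fake <- tr[1:2, ]
  fake$J_HKPFK_n[2] <- 0; fake$J_HKPFK_g[2] <- 0; fake$J_mito_out_n[2] <- 0
  fake$J_mito_out_g[2] <- 0
  mr2 <- metabolic_rates(fake)
  expect_equal(mr2$CMRglc[2], 0)
  expect_equal(mr2$CMRO2[2], 0)
  expect_true(is.na(mr2$OGI[2]))
})

test_that("lactate transports carry the documented sign conventions", {
  tr <- traj_invitro()
  lt <- lactate_transports(tr)
  at0 <- function(nm) lt$value[lt$name == nm][1]
  expect_gt(at0("J_LAC_ge"), 0)   # astrocyte exports to extracellular space
  expect_lt(at0("J_LAC_ne"), 0)   # neuron net import is negative
  expect_lt(at0("J_LDH_n"), 0)    # neuronal lactate-to-pyruvate conversion
  expect_gt(at0("J_LDH_g"), 0)    # astrocytic pyruvate-to-lactate conversion
  # symmetric concentrations: all net carrier transports vanish
  p <- ngv_params()
  y <- resting_state()
  y[c("LAC_n", "LAC_g", "LAC_e", "LAC_c")] <- 0.6
  fl <- compute_fluxes(y, p)
  expect_equal(fl$J_LAC_ne, 0)
  expect_equal(fl$J_LAC_ge, 0)
  expect_equal(fl$J_LAC_gc, 0)
  expect_equal(fl$J_LAC_ec, 0)
})

test_that("firing rate series reflects the decelerating spike train", {
  tr <- traj_invitro()
  fr <- firing_rate(tr)
  expect_gt(nrow(fr), 5)
  # deceleration: early rates exceed late rates
  half <- stats::median(fr$time)
  expect_gt(stats::median(fr$value[fr$time < half]),
            stats::median(fr$value[fr$time >= half]))
  # no spikes -> empty series
  expect_equal(nrow(firing_rate(traj_quiescent())), 0)
  # uniform train at interval delta has rate 1/delta
  fake <- traj_quiescent()[1:2, ]
  attr(fake, "spikes") <- seq(0, 1, by = 0.25)
  expect_equal(unique(firing_rate(fake)$value), 4)
})
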