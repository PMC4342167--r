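# Derived read-outs: BOLD, volume-weighted tissue mixtures, NADH transients,
# metabolic rates (CMRglc, CMRO2, OGI), lactate transports and firing rate.
# All take a trajectory tibble first and return tidy tibbles; relative series
# are percent deviations from the trajectory's own baseline (first sample,
# i.e. the computed steady state).

.baseline_row <- function(traj) {
  traj[1, , drop = FALSE]
}

.relative_pct <- function(x, x0) 100 * (x / x0 - 1)

#' BOLD signal
#'
#' Forward BOLD from deoxyhemoglobin and venous volume:
#' `BOLD = Vv0 * ((k1+k2)(1 - dHb/dHb0) - (k2+k3)(1 - Vv/Vv0))`, with
#' baselines taken from the trajectory's resting state.
#'
#' @param traj An `ngv_traj` from [simulate_ngv()].
#' @param params An [ngv_params()] list (BOLD weights `k1`, `k2`, `k3`).
#' @return A tibble `time`, `name` (`"BOLD"`), `value` (fractional signal
#'   change; multiply by 100 for percent).
#' @export
bold_signal <- function(traj, params = attr(traj, "params") %||% ngv_params()) {
  b <- .baseline_row(traj)
  dHb0 <- b$dHb; Vv0 <- b$Vv
  v <- Vv0 * ((params$k1 + params$k2) * (1 - traj$dHb / dHb0) -
                (params$k2 + params$k3) * (1 - traj$Vv / Vv0))
  tibble::tibble(time = traj$time, name = "BOLD", value = v,
                 baseline = 0)
}

# tissue mixture weights for a quantity
.mix_weights <- function(quantity, params) {
  switch(quantity,
    NADH = c(NADH_cyto_n = params$V_n * (1 - params$xi),
             NADH_mito_n = params$V_n * params$xi,
             NADH_cyto_g = params$V_g * (1 - params$xi),
             NADH_mito_g = params$V_g * params$xi),
    LAC = c(LAC_n = params$V_n, LAC_g = params$V_g,
            LAC_e = params$V_e, LAC_c = params$V_cap),
    O2 = c(O2_n = params$V_n, O2_g = params$V_g),
    stop("unknown tissue quantity: ", quantity)
  )
}

#' Volume-weighted tissue mixture
#'
#' Mixes compartment concentrations into a tissue average: NADH over the four
#' cytosolic/mitochondrial sub-compartments (cell volume further split by the
#' mitochondrial fraction xi), lactate over neuron/astrocyte/extracellular/
#' capillary, oxygen over neuron/astrocyte (the model carries no extracellular
#' oxygen state).
#'
#' @param traj An `ngv_traj`.
#' @param quantity `"NADH"`, `"LAC"` or `"O2"`.
#' @param params An [ngv_params()] list.
#' @param relative Return percent deviation from baseline (default) or the
#'   absolute mixture (mM).
#' @return A tibble `time`, `name`, `value`, `baseline` (resting mixture, mM).
#' @export
tissue_mix <- function(traj, quantity = c("NADH", "LAC", "O2"),
                       params = attr(traj, "params") %||% ngv_params(),
                       relative = TRUE) {
  quantity <- match.arg(quantity)
  w <- .mix_weights(quantity, params)
  missing <- setdiff(names(w), names(traj))
  if (length(missing)) stop("trajectory lacks series: ", paste(missing, collapse = ", "))
  w <- w / sum(w)
  mix <- as.matrix(traj[names(w)]) %*% w
  mix <- as.numeric(mix)
  base <- mix[1]
  tibble::tibble(time = traj$time,
                 name = paste0("tissue_", quantity, if (relative) "_pct" else ""),
                 value = if (relative) .relative_pct(mix, base) else mix,
                 baseline = base)
}

#' Relative NADH transients
#'
#' Percent deviations from rest of the NADH concentration in the neuronal
#' mitochondria, the astrocytic cytosol and the whole-tissue average, plus
#' characteristic metrics of each curve (dip depth/time, peak, final value).
#'
#' @param traj An `ngv_traj`.
#' @param params An [ngv_params()] list.
#' @return A tibble `time`, `name` (`neuron_mito`, `astro_cyto`, `tissue`),
#'   `value` (percent). Attribute `metrics` holds a per-curve summary tibble.
#' @export
nadh_transients <- function(traj, params = attr(traj, "params") %||% ngv_params()) {
  b <- .baseline_row(traj)
  tis <- tissue_mix(traj, "NADH", params)
  out <- dplyr::bind_rows(
    tibble::tibble(time = traj$time, name = "neuron_mito",
                   value = .relative_pct(traj$NADH_mito_n, b$NADH_mito_n),
                   baseline = b$NADH_mito_n),
    tibble::tibble(time = traj$time, name = "astro_cyto",
                   value = .relative_pct(traj$NADH_cyto_g, b$NADH_cyto_g),
                   baseline = b$NADH_cyto_g),
    tibble::tibble(time = traj$time, name = "tissue",
                   value = tis$value, baseline = tis$baseline)
  )
  metrics <- out |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(
      dip = min(.data$value),
      dip_time = .data$time[which.min(.data$value)],
      peak = max(.data$value),
      peak_time = .data$time[which.max(.data$value)],
      final = .data$value[dplyr::n()],
      .groups = "drop"
    )
  attr(out, "metrics") <- metrics
  out
}

#' Metabolic rates
#'
#' Tissue-volume-weighted cerebral metabolic rates: glucose consumption at
#' the committed hexokinase-phosphofructokinase step,
#' `CMRglc = V_n J_HKPFK_n + V_g J_HKPFK_g`; oxygen consumption from the
#' electron transport chain, `CMRO2 = 0.6 (V_n J_mito_out_n + V_g J_mito_out_g)`;
#' and their ratio, the oxygen-glucose index `OGI = CMRO2 / CMRglc`
#' (flagged `NA` where CMRglc vanishes). Per-cell-type contributions are
#' retained.
#'
#' @param traj An `ngv_traj` carrying fluxes.
#' @param params An [ngv_params()] list.
#' @return A tibble with `time`, `CMRglc`, `CMRglc_n`, `CMRglc_g`, `CMRO2`,
#'   `CMRO2_n`, `CMRO2_g`, `OGI` (mM/s per tissue volume; OGI unitless).
#' @export
metabolic_rates <- function(traj, params = attr(traj, "params") %||% ngv_params()) {
  need <- c("J_HKPFK_n", "J_HKPFK_g", "J_mito_out_n", "J_mito_out_g")
  if (!all(need %in% names(traj))) {
    stop("trajectory lacks flux columns; run simulate_ngv(with_fluxes = TRUE)")
  }
  glc_n <- params$V_n * traj$J_HKPFK_n
  glc_g <- params$V_g * traj$J_HKPFK_g
  o2_n <- 0.6 * params$V_n * traj$J_mito_out_n
  o2_g <- 0.6 * params$V_g * traj$J_mito_out_g
  cmrglc <- glc_n + glc_g
  cmro2 <- o2_n + o2_g
  tibble::tibble(
    time = traj$time,
    CMRglc = cmrglc, CMRglc_n = glc_n, CMRglc_g = glc_g,
    CMRO2 = cmro2, CMRO2_n = o2_n, CMRO2_g = o2_g,
    OGI = ifelse(cmrglc > 0, cmro2 / cmrglc, NA_real_)
  )
}

#' Net lactate transports
#'
#' Net carrier fluxes between compartments with the model's sign convention:
#' `J_LAC_ne` is positive for neuron-to-extracellular transport, so net
#' neuronal import appears negative; `J_LAC_ge` is the astrocytic export,
#' `J_LAC_ec` the extracellular-to-capillary export, `J_LAC_gc` the direct
#' astrocyte-to-capillary route. LDH activity per compartment is included
#' (neuronal lactate-to-pyruvate conversion is negative).
#'
#' @param traj An `ngv_traj` carrying fluxes.
#' @return A long tibble `time`, `name`, `value` (mM/s).
#' @export
lactate_transports <- function(traj) {
  need <- c("J_LAC_ne", "J_LAC_ge", "J_LAC_ec", "J_LAC_gc", "J_LDH_n", "J_LDH_g")
  if (!all(need %in% names(traj))) {
    stop("trajectory lacks flux columns; run simulate_ngv(with_fluxes = TRUE)")
  }
  traj |>
    dplyr::select(dplyr::all_of(c("time", need))) |>
    tidyr::pivot_longer(-"time", names_to = "name", values_to = "value")
}

#' Instantaneous firing rate
#'
#' Inverse inter-spike-interval series from the detected spike times; empty
#' when fewer than two spikes occurred.
#'
#' @param traj An `ngv_traj`.
#' @param window Unused smoothing window placeholder kept for API symmetry, s.
#' @return A tibble `time` (midpoint of each inter-spike interval), `name`,
#'   `value` (Hz).
#' @export
firing_rate <- function(traj, window = NULL) {
  sp <- spike_times(traj)
  if (length(sp) < 2) {
    return(tibble::tibble(time = numeric(), name = character(), value = numeric()))
  }
  isi <- diff(sp)
  tibble::tibble(time = sp[-1] - isi / 2, name = "firing_rate", value = 1 / isi)
}

#' Summary metrics of the evoked transients
#'
#' Scalar metrics used for reporting and acceptance: tissue-oxygen dip,
#' overshoot, late-stimulation plateau and post-stimulus undershoot; tissue
#' and extracellular lactate changes; NADH dip; metabolic-rate plateau
#' changes; BOLD extrema; lactate-export change after stimulation.
#'
#' @param traj An `ngv_traj` carrying fluxes.
#' @param params An [ngv_params()] list.
#' @return A one-row tibble of named metrics (percent unless noted).
#' @export
transient_metrics <- function(traj, params = attr(traj, "params") %||% ngv_params()) {
  sc <- attr(traj, "scenario")
  tend <- sc$stimulus$t_end
  t <- traj$time
  stim <- t >= 0 & t <= tend
  post <- t > tend

  o2 <- tissue_mix(traj, "O2", params)$value
  lac <- tissue_mix(traj, "LAC", params)$value
  lac_e <- .relative_pct(traj$LAC_e, traj$LAC_e[1])
  nadh <- nadh_transients(traj, params)
  nm <- nadh$value[nadh$name == "neuron_mito"]
  bold <- bold_signal(traj, params)$value * 100

  mr <- metabolic_rates(traj, params)
  plateau_win <- stim & t >= max(0, tend - pmin(tend / 3, 100))
  late20 <- stim & t >= tend - 20

  lac_ec0 <- traj$J_LAC_ec[1]
  lac_ec_post_peak <- if (any(post)) max(traj$J_LAC_ec[post]) else NA_real_

  tibble::tibble(
    o2_dip = min(o2[t <= 5]),
    o2_dip_time = t[which.min(replace(o2, t > 5, Inf))],
    o2_peak = max(o2[stim]),
    o2_plateau = mean(o2[late20]),
    o2_undershoot = if (any(post)) min(o2[post]) else NA_real_,
    lac_tissue_plateau = mean(lac[plateau_win]),
    lac_e_plateau = mean(lac_e[plateau_win]),
    nadh_neuron_mito_dip = min(nm),
    nadh_neuron_mito_dip_time = t[which.min(nm)],
    cmrglc_plateau_pct = .relative_pct(mean(mr$CMRglc[plateau_win]), mr$CMRglc[1]),
    cmro2_plateau_pct = .relative_pct(mean(mr$CMRO2[plateau_win]), mr$CMRO2[1]),
    ogi_plateau_pct = .relative_pct(mean(mr$OGI[plateau_win]), mr$OGI[1]),
    bold_dip = min(bold[t <= 20]),
    bold_peak = max(bold),
    lac_export_increase_pct = 100 * (lac_ec_post_peak - lac_ec0) / lac_ec0,
    n_spikes = length(spike_times(traj)),
    last_spike = if (length(spike_times(traj))) max(spike_times(traj)) else NA_real_
  )
}
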