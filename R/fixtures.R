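# Synthetic NADH reference-curve generator. Stands in for digitized
# experimental fluorescence transients as the default calibration target;
# file names and docs mark it synthetic.

#' Generate synthetic NADH target curves
#'
#' Builds three relative-NADH curves with the canonical evoked structure:
#' a biphasic neuronal-mitochondrial curve (dip, recovery, late overshoot,
#' built from two normalized exponential differences), a delayed monophasic
#' astrocytic-cytosolic rise, and a tissue curve that is the declared
#' weighted mix of the two cellular curves (weights follow the resting NADH
#' pools per compartment volume). Optional Gaussian noise is reproducible
#' from `seed`. The generating parameters are attached as attribute
#' `ground_truth` for recovery tests.
#'
#' @param duration Curve length, s. @param dt Sampling step, s.
#' @param dip_pct Neuronal mitochondrial dip depth, percent (positive number).
#' @param dip_time Time of the dip minimum, s.
#' @param overshoot_pct Late neuronal overshoot amplitude, percent.
#' @param astro_rise_pct Astrocytic rise amplitude, percent.
#' @param astro_delay Astrocytic onset delay, s.
#' @param noise_sd Gaussian noise standard deviation, percent.
#' @param seed Integer seed for the noise.
#' @param params An [ngv_params()] list (tissue mixing weights).
#' @return A tibble `time_s`, `astro_cyto_pct`, `neuron_mito_pct`,
#'   `tissue_pct`, with attributes `ground_truth` and `provenance`
#'   (`"fixture"`).
#' @export
#' @examples
#' fx <- generate_nadh_fixture()
#' min(fx$neuron_mito_pct)   # ~ -10% near 5 s
generate_nadh_fixture <- function(duration = 60, dt = 0.5,
                                  dip_pct = 10, dip_time = 5,
                                  overshoot_pct = 3,
                                  astro_rise_pct = 15, astro_delay = 8,
                                  noise_sd = 0, seed = 1L,
                                  params = ngv_params()) {
  if (abs(dip_pct) > 50 || abs(overshoot_pct) > 50 || abs(astro_rise_pct) > 50) {
    stop("dip/overshoot amplitudes outside +-50% are nonphysical", call. = FALSE)
  }
  t <- seq(0, duration, by = dt)

  # dip component: difference of exponentials with its minimum at dip_time;
  # the extremum of exp(-t/a) - exp(-t/b) sits at ln(a/b)/(1/b - 1/a)
  tau_b <- dip_time / 2.3
  peak_at <- function(a) log(a / tau_b) / (1 / tau_b - 1 / a)
  tau_a <- stats::uniroot(function(a) peak_at(a) - dip_time,
                          c(tau_b * 1.01, 1000 * dip_time))$root
  d <- exp(-t / tau_a) - exp(-t / tau_b)
  d <- d / max(d)
  # overshoot component, slower and delayed past the dip so the dip minimum
  # keeps its declared depth and time
  to <- pmax(t - 2 * dip_time, 0)
  o <- (exp(-to / 60) - exp(-to / 25)) * (t >= 2 * dip_time)
  o <- o / max(o)
  neuron <- -dip_pct * d + overshoot_pct * o

  ts <- pmax(t - astro_delay, 0)
  a <- exp(-ts / 70) - exp(-ts / 10)
  a <- a / max(a)
  astro <- astro_rise_pct * a * (t >= astro_delay)

  # tissue weights: resting NADH pool per sub-compartment volume
  w_nm <- params$V_n * params$xi * 0.12
  w_ac <- params$V_g * (1 - params$xi) * 0.1
  w_tot <- w_nm + w_ac +
    params$V_n * (1 - params$xi) * 0.006 + params$V_g * params$xi * 0.12
  tissue <- (w_nm * neuron + w_ac * astro) / w_tot

  if (noise_sd > 0) {
    set.seed(seed)
    neuron <- neuron + stats::rnorm(length(t), 0, noise_sd)
    astro <- astro + stats::rnorm(length(t), 0, noise_sd)
    tissue <- tissue + stats::rnorm(length(t), 0, noise_sd)
  }

  out <- tibble::tibble(time_s = t, astro_cyto_pct = astro,
                        neuron_mito_pct = neuron, tissue_pct = tissue)
  attr(out, "ground_truth") <- list(
    dip_pct = dip_pct, dip_time = dip_time, overshoot_pct = overshoot_pct,
    astro_rise_pct = astro_rise_pct, astro_delay = astro_delay,
    noise_sd = noise_sd, seed = seed,
    tissue_weights = c(neuron_mito = w_nm / w_tot, astro_cyto = w_ac / w_tot)
  )
  attr(out, "provenance") <- "fixture"
  out
}

#' Read / write target-curve CSV files
#'
#' Columns: `time_s`, `astro_cyto_pct`, `neuron_mito_pct`, `tissue_pct`.
#'
#' @param path CSV path. @param curves A target-curves tibble.
#' @return `read_target_curves()` returns the tibble (provenance `"user"`);
#'   `write_target_curves()` returns `path` invisibly.
#' @export
read_target_curves <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  need <- c("time_s", "astro_cyto_pct", "neuron_mito_pct", "tissue_pct")
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    stop("target curves lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  attr(out, "provenance") <- "user"
  out
}

#' @rdname read_target_curves
#' @export
write_target_curves <- function(curves, path) {
  utils::write.csv(curves, path, row.names = FALSE)
  invisible(path)
}
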