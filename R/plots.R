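# ggplot2 quick-look figures for trajectories and derived observables.

#' Plot a trajectory
#'
#' Faceted time courses of selected state variables.
#'
#' @param object An `ngv_traj`.
#' @param vars State/flux columns to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ngv_traj <- function(object,
                              vars = c("psi_n", "Na_n", "Na_g", "ATP_n",
                                       "PCr_n", "NADH_mito_n", "NADH_cyto_g",
                                       "LAC_e"),
                              ...) {
  vars <- intersect(vars, names(object))
  long <- tidyr::pivot_longer(object[c("time", vars)], -"time",
                              names_to = "variable", values_to = "value")
  long$variable <- factor(long$variable, levels = vars)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot relative NADH transients
#'
#' @param traj An `ngv_traj`.
#' @return A ggplot of the astrocytic-cytosolic, neuronal-mitochondrial and
#'   tissue relative NADH curves.
#' @export
plot_nadh_transients <- function(traj) {
  nadh <- nadh_transients(traj)
  ggplot2::ggplot(nadh, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$name)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "NADH change from rest (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot metabolic rates with cell-type contributions
#'
#' @param traj An `ngv_traj` with fluxes.
#' @return A ggplot of CMRglc and CMRO2 split by cell type.
#' @export
plot_metabolic_rates <- function(traj) {
  mr <- metabolic_rates(traj)
  long <- tidyr::pivot_longer(
    mr[c("time", "CMRglc_n", "CMRglc_g", "CMRO2_n", "CMRO2_g")],
    -"time", names_to = "series", values_to = "value")
  long$rate <- ifelse(grepl("glc", long$series), "CMRglc", "CMRO2")
  long$cell <- ifelse(grepl("_n$", long$series), "neuron", "astrocyte")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     fill = .data$cell)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::facet_wrap(~rate, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "rate (mM/s tissue)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the BOLD signal
#'
#' @param traj An `ngv_traj`.
#' @return A ggplot of the forward BOLD time course (percent).
#' @export
plot_bold <- function(traj) {
  b <- bold_signal(traj)
  ggplot2::ggplot(b, ggplot2::aes(x = .data$time, y = 100 * .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "BOLD (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
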