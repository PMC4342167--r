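# Two-tier parameter determination: algebraic steady-state constraints for
# the "constrained" parameter block, then downhill-simplex least-squares
# fitting of the "optimized" block against relative-NADH reference curves.

# mapping from each constrained parameter to the resting balance that
# determines it (documentation; the solve order is fixed in the code below)
.constrain_order <- c(
  "kCKm_n", "kCKm_g",            # creatine kinase equilibrium
  "kPGK_n", "kPGK_g",            # GAP balance
  "kPK_n", "kPK_g",              # PEP balance
  "Vmax_in_n", "Vmax_in_g",      # pyruvate balance
  "TNADH_n", "TNADH_g",          # cytosolic NADH balance
  "Vmax_out_n", "Vmax_out_g",    # mitochondrial NADH balance
  "PScapVn", "PScapVg",          # intracellular oxygen balance
  "JATPases_n", "JATPases_g",    # ATP balance
  "Tmax_GLC_en",                 # neuronal glucose balance
  "Tmax_GLC_eg",                 # astrocytic glucose balance
  "Tmax_GLC_ce",                 # extracellular glucose balance
  "Tmax_LAC_ec"                  # capillary lactate balance
)

#' Solve constrained parameters from resting flux balances
#'
#' Each parameter in `free_subset` is solved so that the governing resting
#' balance it appears in vanishes exactly at the imposed resting
#' concentrations, holding fixed and optimized parameters at their current
#' values. Solves are sequential (each is a scalar linear solve; the three
#' glucose capacities `Tmax_GLC_eg/cg/ce` come from a 3x3 linear system over
#' the astrocytic, capillary and extracellular glucose balances).
#'
#' The lactate carrier capacities `Tmax_LAC_ne/ge/gc`, the LDH reverse
#' constants and the arterial lactate are not solvable from the rounded
#' resting targets (the corresponding concentration gradients vanish there,
#' making the balances degenerate in the capacity) and are left at their
#' input values.
#'
#' @param rest_targets Named resting state vector (defaults to
#'   [resting_state()]).
#' @param free_subset Constrained parameter names to solve (default: all
#'   solvable ones, in dependency order).
#' @param params An [ngv_params()] list supplying every other value.
#' @return An updated `ngv_params` list.
#' @export
steady_state_constrain <- function(rest_targets = resting_state(),
                                   free_subset = .constrain_order,
                                   params = ngv_params()) {
  bad <- setdiff(free_subset, .constrain_order)
  if (length(bad)) {
    stop("not solvable from resting balances: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p <- params
  s <- as.list(rest_targets[.state_names])
  aden <- list(n = adenylate_closure(s$ATP_n, p), g = adenylate_closure(s$ATP_g, p))
  want <- function(nm) nm %in% free_subset
  set <- function(p, nm, value, balance) {
    if (!is.finite(value) || value <= 0) {
      stop("constraint for ", nm, " violated at the ", balance,
           " balance (solved value ", signif(value, 4), ")", call. = FALSE)
    }
    p[[nm]] <- value
    p
  }

  for (x in c("n", "g")) {
    ADP <- aden[[x]]$ADP
    ATP <- s[[paste0("ATP_", x)]]
    PCr <- s[[paste0("PCr_", x)]]
    GLC <- s[[paste0("GLC_", x)]]; GAP <- s[[paste0("GAP_", x)]]
    PEP <- s[[paste0("PEP_", x)]]; PYR <- s[[paste0("PYR_", x)]]
    LAC <- s[[paste0("LAC_", x)]]
    NADHc <- s[[paste0("NADH_cyto_", x)]]; NADHm <- s[[paste0("NADH_mito_", x)]]
    O2x <- s[[paste0("O2_", x)]]
    comp <- if (x == "n") "neuron" else "astrocyte"
    sfx <- function(base) paste0(base, "_", x)

    # creatine kinase equilibrium at rest
    if (want(sfx("kCKm"))) {
      kCKp <- p[[sfx("kCKp")]]
      p <- set(p, sfx("kCKm"), kCKp * ADP * PCr / (ATP * (p$Ctot - PCr)),
               "phosphocreatine")
    }

    J_HK <- p[[sfx("kHKPFK")]] * ATP * GLC / (GLC + p$K_g) /
      (1 + (ATP / p$K_I_ATP)^p$nH)

    if (want(sfx("kPGK"))) {
      p <- set(p, sfx("kPGK"),
               2 * J_HK / (GAP * ADP * (p$Ntot - NADHc) / NADHc),
               "glyceraldehyde-3-phosphate")
    }
    J_PGK <- p[[sfx("kPGK")]] * GAP * ADP * (p$Ntot - NADHc) / NADHc

    if (want(sfx("kPK"))) {
      p <- set(p, sfx("kPK"), J_PGK / (PEP * ADP), "phosphoenolpyruvate")
    }
    J_PK <- p[[sfx("kPK")]] * PEP * ADP

    J_LDH <- ldh_flux(PYR, LAC, NADHc, p, comp)

    if (want(sfx("Vmax_in"))) {
      NADm <- p$Ntot - NADHm
      sat <- PYR / (PYR + p$K_m_mito) *
        NADm / (NADm + p[[paste0("K_m_NAD_", x)]])
      p <- set(p, sfx("Vmax_in"), (J_PK - J_LDH) / sat, "pyruvate")
    }
    J_mi <- mito_fluxes(PYR, O2x, ADP, NADHm, p, comp)$J_mito_in

    if (want(sfx("TNADH"))) {
      Rm <- NADHc / (p$Ntot - NADHc)
      Rp <- (p$Ntot - NADHm) / NADHm
      sat <- Rm / (Rm + p[[paste0("M_cyto_", x)]]) *
        Rp / (Rp + p[[paste0("M_mito_", x)]])
      p <- set(p, sfx("TNADH"), (J_PGK - J_LDH) / sat, "cytosolic NADH")
    }
    J_sh <- nadh_shuttle_flux(NADHc, NADHm, p, comp)

    if (want(sfx("Vmax_out"))) {
      sat <- O2x / (O2x + p$K_O2_mito) *
        ADP / (ADP + p[[paste0("K_m_ADP_", x)]]) *
        NADHm / (NADHm + p[[paste0("K_m_NADH_", x)]])
      p <- set(p, sfx("Vmax_out"), (4 * J_mi + J_sh) / sat, "mitochondrial NADH")
    }
    J_mo <- mito_fluxes(PYR, O2x, ADP, NADHm, p, comp)$J_mito_out

    if (want(if (x == "n") "PScapVn" else "PScapVg")) {
      O2eq <- p$K_O2 * (p$HbOP / s$O2_c - 1)^(-1 / p$nh)
      nm <- if (x == "n") "PScapVn" else "PScapVg"
      p <- set(p, nm, 0.6 * J_mo / (O2eq - O2x), "intracellular oxygen")
    }

    if (want(sfx("JATPases"))) {
      pump <- pump_and_leak(s[[sfx("Na")]], ATP,
                            if (x == "n") s$psi_n else p$psi_g, p, comp)$J_pump
      J_CK <- creatine_kinase_flux(ADP, ATP, PCr, p, comp)
      val <- if (x == "n") {
        -2 * J_HK + J_PGK + J_PK - pump + 3.6 * J_mo + J_CK
      } else {
        -2 * J_HK + J_PGK + J_PK - 7 / 4 * pump + 3 / 4 * p$Jpump0_g +
          3.6 * J_mo + J_CK
      }
      p <- set(p, sfx("JATPases"), val, "ATP")
    }
  }

  # glucose transport capacities
  dsat <- function(a, b, Kt) a / (a + Kt) - b / (b + Kt)
  J_HK_n <- p$kHKPFK_n * s$ATP_n * s$GLC_n / (s$GLC_n + p$K_g) /
    (1 + (s$ATP_n / p$K_I_ATP)^p$nH)
  J_HK_g <- p$kHKPFK_g * s$ATP_g * s$GLC_g / (s$GLC_g + p$K_g) /
    (1 + (s$ATP_g / p$K_I_ATP)^p$nH)
  if (want("Tmax_GLC_en")) {
    p <- set(p, "Tmax_GLC_en",
             J_HK_n / dsat(s$GLC_e, s$GLC_n, p$Kt_GLC_en), "neuronal glucose")
  }
  # The four glucose balances are linearly dependent (their volume-weighted
  # sum is total supply = total consumption), so only two capacities are
  # solvable beyond Tmax_GLC_en: the astrocytic balance gives Tmax_GLC_eg
  # (holding the minor direct capillary route Tmax_GLC_cg at its input
  # value) and the extracellular balance then gives Tmax_GLC_ce; the small
  # residual of the capillary balance is absorbed by the fixed arterial
  # supply, like the balances that own no constrained parameter.
  if (want("Tmax_GLC_eg")) {
    J_cg <- carrier_flux(s$GLC_c, s$GLC_g, p$Tmax_GLC_cg, p$Kt_GLC_cg)
    p <- set(p, "Tmax_GLC_eg",
             (J_HK_g - J_cg) / dsat(s$GLC_e, s$GLC_g, p$Kt_GLC_eg),
             "astrocytic glucose")
  }
  if (want("Tmax_GLC_ce")) {
    r_en <- p$V_e / p$V_n; r_eg <- p$V_e / p$V_g
    J_eg <- carrier_flux(s$GLC_e, s$GLC_g, p$Tmax_GLC_eg, p$Kt_GLC_eg)
    J_en <- carrier_flux(s$GLC_e, s$GLC_n, p$Tmax_GLC_en, p$Kt_GLC_en)
    p <- set(p, "Tmax_GLC_ce",
             (J_eg / r_eg + J_en / r_en) / dsat(s$GLC_c, s$GLC_e, p$Kt_GLC_ce),
             "extracellular glucose")
  }

  if (want("Tmax_LAC_ec")) {
    r_ce <- p$V_cap / p$V_e; r_cg <- p$V_cap / p$V_g
    J_LAC_cap <- 2 * p$F_0 / p$V_cap * (p$LAC_a - s$LAC_c)
    J_gc <- carrier_flux(s$LAC_g, s$LAC_c, p$Tmax_LAC_gc, p$Kt_LAC_gc)
    J_ec <- (-J_LAC_cap - J_gc / r_cg) * r_ce
    p <- set(p, "Tmax_LAC_ec",
             J_ec / dsat(s$LAC_e, s$LAC_c, p$Kt_LAC_ec), "capillary lactate")
  }
  p
}

#' Smooth sampled reference curves with sums of exponentials
#'
#' Fits each relative-NADH curve with `y = c0 + sum_i a_i exp(-t/tau_i)`
#' (Levenberg-Marquardt least squares, 2 or 3 terms) to obtain continuous
#' curves that can be evaluated on an arbitrary grid. Constant series
#' degenerate gracefully to the offset term.
#'
#' @param points A target-curves tibble with column `time_s` and one column
#'   per curve (e.g. `astro_cyto_pct`, `neuron_mito_pct`, `tissue_pct`).
#' @param n_terms Number of exponential terms (2 or 3).
#' @return An object of class `ngv_smoothed`; use [eval_target_curves()] to
#'   evaluate it, `glance()` for per-curve residuals.
#' @export
smooth_reference_curves <- function(points, n_terms = 3) {
  stopifnot("time_s" %in% names(points), n_terms %in% 2:3)
  curves <- setdiff(names(points), "time_s")
  t <- points$time_s
  if (length(t) < 6) stop("need at least 6 points per curve", call. = FALSE)
  span <- diff(range(t)) + 1e-9
  tau_starts <- list(span / c(8, 2), span / c(20, 4), span / c(3, 1),
                     span / c(40, 8))
  if (n_terms == 3) {
    tau_starts <- list(span / c(8, 2, 0.5), span / c(20, 4, 1),
                       span / c(30, 6, 1.5), span / c(4, 1.3, 0.4))
  }
  terms <- paste(sprintf("a%d * exp(-time_s / exp(ltau%d))",
                         seq_len(n_terms), seq_len(n_terms)), collapse = " + ")
  form <- stats::as.formula(paste("y ~ c0 +", terms))
  fits <- lapply(curves, function(cn) {
    y <- points[[cn]]
    if (stats::sd(y) < 1e-12) {
      return(list(kind = "constant", c0 = mean(y), rss = 0))
    }
    dat <- data.frame(time_s = t, y = y)
    best <- NULL
    for (taus0 in tau_starts) {
      # amplitude starts from the linear least-squares solution at fixed taus
      basis <- sapply(taus0, function(tau) exp(-t / tau))
      co <- tryCatch(stats::coef(stats::lm(y ~ basis)), error = function(e) NULL)
      if (is.null(co) || anyNA(co)) next
      start <- c(list(c0 = unname(co[1])),
                 stats::setNames(as.list(unname(co[-1])),
                                 paste0("a", seq_len(n_terms))),
                 stats::setNames(as.list(log(taus0)),
                                 paste0("ltau", seq_len(n_terms))))
      fit <- tryCatch(
        minpack.lm::nlsLM(form, data = dat, start = start,
                          control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::resid(fit)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
      }
    }
    if (is.null(best)) {
      stop("rank-deficient or non-convergent exponential fit for curve ", cn,
           call. = FALSE)
    }
    list(kind = "expsum", fit = best$fit, rss = best$rss)
  })
  names(fits) <- curves
  structure(list(fits = fits, curves = curves, range = range(t)),
            class = c("ngv_smoothed", "list"))
}

#' Evaluate smoothed reference curves on a grid
#'
#' @param smoothed An `ngv_smoothed` object.
#' @param times Evaluation grid, s.
#' @return A tibble with `time_s` and one column per curve.
#' @export
eval_target_curves <- function(smoothed, times) {
  out <- tibble::tibble(time_s = times)
  for (cn in smoothed$curves) {
    f <- smoothed$fits[[cn]]
    out[[cn]] <- if (f$kind == "constant") rep(f$c0, length(times))
                 else stats::predict(f$fit, newdata = data.frame(time_s = times))
  }
  out
}

#' @export
glance.ngv_smoothed <- function(x, ...) {
  tibble::tibble(curve = x$curves,
                 rss = vapply(x$fits, function(f) f$rss, numeric(1)))
}

# relative NADH curves of a simulation interpolated on a grid
.sim_nadh_on_grid <- function(traj, grid, params) {
  nadh <- nadh_transients(traj, params)
  out <- list()
  for (nm in c("astro_cyto", "neuron_mito", "tissue")) {
    sub <- nadh[nadh$name == nm, ]
    out[[nm]] <- stats::approx(sub$time, sub$value, xout = grid, rule = 2)$y
  }
  out
}

#' Fit free parameters to NADH reference curves
#'
#' Nelder-Mead (downhill simplex) minimization, in log-space to enforce
#' positivity, of the summed squared distance between the simulated and the
#' target relative-NADH curves (astrocytic cytosol, neuronal mitochondria,
#' tissue) on a common grid. Every candidate is evaluated after re-deriving
#' the constrained parameters via [steady_state_constrain()] and re-solving
#' the steady state; candidates whose simulation fails receive a large
#' penalty. The returned fit reports the post-fit steady state and its
#' stability.
#'
#' @param targets A target-curves tibble (`time_s`, `astro_cyto_pct`,
#'   `neuron_mito_pct`, `tissue_pct`), e.g. from [generate_nadh_fixture()] or
#'   [read_target_curves()].
#' @param free_names Names of optimized parameters to fit (subset of the
#'   `optimized` group).
#' @param init An [ngv_params()] list giving the starting point.
#' @param scenario Scenario used for candidate simulations (in vitro).
#' @param grid_dt Comparison grid spacing, s.
#' @param maxit Simplex iteration cap.
#' @param reltol Simplex convergence tolerance.
#' @return A list of class `ngv_fit`: `params`, `par` (fitted values), `sse`,
#'   `counts`, `converged`, `steady`, `stable`.
#' @export
fit_free_parameters <- function(targets, free_names, init = ngv_params(),
                                scenario = make_scenario("in_vitro"),
                                grid_dt = 0.5, maxit = 300, reltol = 1e-6) {
  opt_names <- .param_group_names()$optimized
  bad <- setdiff(free_names, opt_names)
  if (length(bad)) {
    stop("not optimized parameters: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  grid <- seq(0, max(targets$time_s), by = grid_dt)
  tgt <- list(
    astro_cyto = stats::approx(targets$time_s, targets$astro_cyto_pct, grid, rule = 2)$y,
    neuron_mito = stats::approx(targets$time_s, targets$neuron_mito_pct, grid, rule = 2)$y,
    tissue = stats::approx(targets$time_s, targets$tissue_pct, grid, rule = 2)$y
  )
  t_max <- max(grid) + 1

  sim_sse <- function(p) {
    p2 <- steady_state_constrain(params = p)
    ss <- find_steady_state(p2, relax = 300)
    traj <- simulate_ngv(scenario, p2, init = ss$state, t_max = t_max,
                         fine_dt = 0.01, with_fluxes = FALSE)
    sim <- .sim_nadh_on_grid(traj, grid, p2)
    sum((sim$astro_cyto - tgt$astro_cyto)^2) +
      sum((sim$neuron_mito - tgt$neuron_mito)^2) +
      sum((sim$tissue - tgt$tissue)^2)
  }

  objective <- function(theta) {
    p <- init
    p[free_names] <- as.list(exp(theta))
    tryCatch(sim_sse(p), error = function(e) 1e8)
  }

  if (length(free_names) == 0) {
    sse0 <- sim_sse(init)
    ss <- find_steady_state(steady_state_constrain(params = init))
    return(structure(list(params = init, par = numeric(), sse = sse0,
                          counts = c(`function` = 1L), converged = TRUE,
                          steady = ss, stable = ss$stable),
                     class = c("ngv_fit", "list")))
  }
  theta0 <- log(unlist(init[free_names]))
  opt <- stats::optim(theta0, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  p_fit <- init
  p_fit[free_names] <- as.list(exp(opt$par))
  p_fit <- steady_state_constrain(params = p_fit)
  ss <- find_steady_state(p_fit)
  structure(list(params = p_fit,
                 par = stats::setNames(exp(opt$par), free_names),
                 sse = opt$value, counts = opt$counts,
                 converged = opt$convergence == 0,
                 steady = ss, stable = ss$stable),
            class = c("ngv_fit", "list"))
}

#' @export
tidy.ngv_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @export
glance.ngv_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, converged = x$converged, stable = x$stable,
                 n_evals = unname(x$counts[1]))
}

#' @export
print.ngv_fit <- function(x, ...) {
  cat("<ngv_fit> SSE ", signif(x$sse, 4),
      if (x$converged) ", converged" else ", NOT converged",
      if (x$stable) ", steady state stable" else ", steady state NOT stable",
      "\n", sep = "")
  if (length(x$par)) {
    print(tidy(x))
  }
  invisible(x)
}
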