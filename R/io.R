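# Run configuration, trajectory serialization and run manifests.

.config_defaults <- function() {
  list(
    scenario = "in_vitro",
    stim_duration = NULL,
    flow_delay = NULL,
    param_file = NULL,
    param_overrides = list(),
    rtol = 1e-8,
    atol_scale = 1e-8,
    t_max = NULL,
    fine_dt = 5e-4,
    out_dir = ".",
    fixture = list(dip_pct = 10, dip_time = 5, overshoot_pct = 3,
                   astro_rise_pct = 15, astro_delay = 8,
                   noise_sd = 0, seed = 1)
  )
}

#' Load a run configuration
#'
#' Reads a YAML or JSON run configuration, validates it strictly (unknown
#' keys are an error naming the key and its nearest valid name) and resolves
#' it into a scenario and a parameter set.
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`).
#' @return A list of class `ngv_config` with the validated settings plus
#'   resolved `$scenario_spec` and `$params`.
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported config extension: ", ext)
  )
  defaults <- .config_defaults()
  known <- names(defaults)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    hints <- vapply(unknown, function(k) {
      d <- utils::adist(k, known)
      known[which.min(d)]
    }, character(1))
    stop("unknown config key(s): ",
         paste0(unknown, " (did you mean '", hints, "'?)", collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$fixture)) {
    fk <- names(.config_defaults()$fixture)
    bad <- setdiff(names(raw$fixture), fk)
    if (length(bad)) stop("unknown fixture key(s): ", paste(bad, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, raw, keep.null = TRUE)

  sc_kind <- switch(cfg$scenario,
    in_vitro = , invitro = "in_vitro",
    in_vivo_rodent = , rodent = "in_vivo_rodent",
    in_vivo_human = , human = "in_vivo_human",
    stop("unknown scenario: ", cfg$scenario)
  )
  overrides <- list()
  if (!is.null(cfg$flow_delay)) overrides$flow <- list(t_1 = cfg$flow_delay)
  cfg$scenario_spec <- make_scenario(sc_kind, stim_duration = cfg$stim_duration,
                                     overrides = overrides)
  params <- if (!is.null(cfg$param_file)) read_params(cfg$param_file) else ngv_params()
  if (length(cfg$param_overrides)) {
    params <- do.call(ngv_params, cfg$param_overrides)
  }
  cfg$params <- params
  structure(cfg, class = c("ngv_config", "list"))
}

#' @rdname load_config
#' @param config A config list to write.
#' @export
save_config <- function(config, path) {
  keep <- intersect(names(config), names(.config_defaults()))
  out <- config[keep]
  out <- out[!vapply(out, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    yaml = ,
    yml  = yaml::write_yaml(out, path),
    stop("unsupported config extension: ", ext)
  )
  invisible(path)
}

#' Write / read a trajectory
#'
#' The trajectory is written as a tidy CSV (one row per sample) with a JSON
#' run manifest alongside (`<stem>_manifest.json`) carrying the scenario, a
#' hash of the parameter set, the spike times and package version, so that
#' the run is reproducible from the manifest alone. Reading restores the
#' `ngv_traj` attributes; numeric round-trip is exact (values are written
#' with full precision).
#'
#' @param traj An `ngv_traj`. @param path CSV path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns the restored tibble.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  cols <- names(df)
  txt <- vapply(df, function(col) format(col, digits = 17, trim = TRUE,
                                         scientific = NA),
                character(nrow(df)))
  if (nrow(df) == 1) txt <- matrix(txt, nrow = 1, dimnames = list(NULL, cols))
  utils::write.table(txt, path, sep = ",", row.names = FALSE,
                     col.names = cols, quote = FALSE)
  manifest <- list(
    scenario = unclass(attr(traj, "scenario")),
    params_hash = rlang::hash(attr(traj, "params")),
    params = unclass(attr(traj, "params")),
    baseline = as.list(attr(traj, "baseline")),
    spikes = attr(traj, "spikes"),
    n_rows = nrow(df),
    package_version = as.character(utils::packageVersion("ngvmet")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, .manifest_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

.manifest_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_manifest.json")
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  traj <- tibble::as_tibble(df)
  mf_path <- .manifest_path(path)
  if (file.exists(mf_path)) {
    mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
    sc <- mf$scenario
    sc$stimulus <- structure(as.list(sc$stimulus), class = c("ngv_stimulus", "list"))
    sc$flow <- structure(as.list(sc$flow), class = c("ngv_flow", "list"))
    sc$clamped_states <- as.character(unlist(sc$clamped_states))
    attr(traj, "scenario") <- structure(sc, class = c("ngv_scenario", "list"))
    attr(traj, "params") <- structure(as.list(mf$params),
                                      class = c("ngv_params", "list"))
    attr(traj, "baseline") <- unlist(mf$baseline)
    attr(traj, "spikes") <- as.numeric(unlist(mf$spikes))
    class(traj) <- c("ngv_traj", class(tibble::tibble()))
  }
  traj
}

#' Save a full set of run outputs
#'
#' Writes the trajectory CSV (+ manifest), an observables CSV (tissue
#' mixtures, NADH transients, metabolic rates, BOLD) and a summary-metrics
#' JSON.
#'
#' @param traj An `ngv_traj` with fluxes.
#' @param out_dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Invisibly, the named vector of written paths.
#' @export
save_outputs <- function(traj, out_dir = ".", stem = "ngv_run") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- attr(traj, "params")
  paths <- c(
    trajectory = file.path(out_dir, paste0(stem, "_trajectory.csv")),
    observables = file.path(out_dir, paste0(stem, "_observables.csv")),
    metrics = file.path(out_dir, paste0(stem, "_metrics.json"))
  )
  write_trajectory(traj, paths[["trajectory"]])
  obs <- dplyr::bind_rows(
    tissue_mix(traj, "NADH", params),
    tissue_mix(traj, "LAC", params),
    tissue_mix(traj, "O2", params),
    nadh_transients(traj, params),
    bold_signal(traj, params)
  )
  utils::write.csv(as.data.frame(obs), paths[["observables"]], row.names = FALSE)
  jsonlite::write_json(as.list(transient_metrics(traj, params)),
                       paths[["metrics"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
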