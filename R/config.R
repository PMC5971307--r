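# Run-configuration files: a flat list of overrides for geometry, material,
# activation and solver settings, read from YAML (if available) or JSON.

#' Read a run configuration file
#'
#' Reads a JSON (or, when the `yaml` package is installed, YAML) file with
#' any of the fields `dims` (arguments of [lv_dimensions()]), `mesh`
#' (`n_circ`, `n_long`, `n_layers`, `target_volume_ml`), `material`
#' ([passive_params()] arguments), `active` ([active_params()] arguments),
#' `scenario` ([scenario_spec()] arguments), `solver` ([solver_config()]
#' arguments), `p_ed`, `p_ao`. Missing fields keep the package defaults.
#'
#' @param path configuration file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configurations requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = c("run_config", class(cfg)))
}

#' Build model components from a run configuration
#'
#' @param cfg a [read_run_config()] result (or plain list).
#' @return List with `mesh`, `material` (rate-adjusted), `active`, `solver`,
#'   `scenario`, `p_ed`, `p_ao`.
#' @export
config_to_model_args <- function(cfg = list()) {
  dims <- do.call(lv_dimensions, as.list(cfg$dims %||% list()))
  mesh <- do.call(build_lv_mesh, c(list(dims = dims),
                                   as.list(cfg$mesh %||% list())))
  material <- apply_rate_factor(do.call(passive_params,
                                        as.list(cfg$material %||% list())))
  active <- do.call(active_params, as.list(cfg$active %||% list()))
  solver <- do.call(solver_config, as.list(cfg$solver %||% list()))
  scenario <- do.call(scenario_spec, as.list(cfg$scenario %||% list()))
  list(mesh = mesh, material = material, active = active, solver = solver,
       scenario = scenario, p_ed = cfg$p_ed %||% 1.3, p_ao = cfg$p_ao %||% 10.7)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
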