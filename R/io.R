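#' Load and validate a run configuration
#'
#' Run configurations are YAML files tying the pipeline stages together.
#' Recognized top-level keys (unknown keys are rejected with an error naming
#' the offender):
#' \describe{
#'   \item{`protocols`}{list of entries with `name` (a preset) and optional
#'     `field_kV_per_cm` override.}
#'   \item{`concentrations_uM`}{numeric vector of concentrations.}
#'   \item{`parameters`}{named overrides of [model_parameters()] fields
#'     (SI units).}
#'   \item{`solver`}{`rtol`, `atol`, `gap_switch_tau`, `t_end_reference`,
#'     `method` for [solver_config()].}
#'   \item{`synthetic`}{overrides of [synthetic_config()] arguments.}
#'   \item{`t_end_min`}{simulation horizon in minutes (default 25).}
#'   \item{`out_dir`}{output directory for the `cmd_*` drivers.}
#'   \item{`seed`}{integer seed for the synthetic generators.}
#'   \item{`log_level`}{`"quiet"`, `"info"` or `"debug"`.}
#' }
#'
#' @param path YAML file path.
#' @return A validated `run_config` list with elements `trains` (named list
#'   of `pulse_train`), `concentrations_uM`, `params`, `solver`, `synth`,
#'   `t_end_min`, `out_dir`, `seed`, `log_level`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("protocols", "concentrations_uM", "parameters", "solver",
             "synthetic", "t_end_min", "out_dir", "seed", "log_level")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }

  protos <- raw$protocols
  if (is.null(protos)) {
    protos <- lapply(preset_names(), function(n) list(name = n))
  }
  trains <- lapply(protos, function(entry) {
    bad <- setdiff(names(entry), c("name", "field_kV_per_cm"))
    if (length(bad) > 0) {
      stop("unknown protocol key(s): ", paste(bad, collapse = ", "))
    }
    if (is.null(entry$name)) stop("protocol entry is missing `name`")
    field <- if (!is.null(entry$field_kV_per_cm)) entry$field_kV_per_cm * 1e5
    preset_train(entry$name, field = field)
  })
  names(trains) <- vapply(trains, function(tr) tr$name, character(1))

  params <- do.call(model_parameters, as.list(raw$parameters))
  solver <- do.call(solver_config, as.list(raw$solver))

  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  conc <- if (is.null(raw$concentrations_uM)) c(0, 10, 30, 50) else as.numeric(raw$concentrations_uM)
  synth_args <- as.list(raw$synthetic)
  if (is.null(synth_args$protocols)) synth_args$protocols <- names(trains)
  if (is.null(synth_args$concentrations_uM)) synth_args$concentrations_uM <- conc
  if (is.null(synth_args$seed)) synth_args$seed <- seed
  if (!is.null(synth_args$distortion)) synth_args$distortion <- unlist(synth_args$distortion)
  synth <- do.call(synthetic_config, synth_args)

  log_level <- if (is.null(raw$log_level)) "info" else
    match.arg(raw$log_level, c("quiet", "info", "debug"))

  structure(list(trains = trains, concentrations_uM = conc, params = params,
                 solver = solver, synth = synth,
                 t_end_min = if (is.null(raw$t_end_min)) 25 else raw$t_end_min,
                 out_dir = if (is.null(raw$out_dir)) "poreflux_out" else raw$out_dir,
                 seed = seed, log_level = log_level,
                 config_path = normalizePath(path)),
            class = "run_config")
}

.pf_log <- function(cfg, level, ...) {
  ranks <- c(quiet = 0, info = 1, debug = 2)
  if (ranks[[cfg$log_level]] >= ranks[[level]]) {
    message("[poreflux] ", ...)
  }
}

# run manifest: config digest, seed, package version (no timestamp, so
# reruns of the same configuration are byte-identical)
.write_manifest <- function(cfg, out_dir) {
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg$config_path)),
    seed = cfg$seed,
    package = "poreflux",
    version = as.character(utils::packageVersion("poreflux")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Pipeline drivers
#'
#' Thin command-style drivers over the package functions, used by the
#' `inst/cli/poreflux.R` script and callable directly. Each writes its
#' outputs plus a `manifest.json` (config digest, seed, package version)
#' into the configured output directory; rerunning with an unchanged
#' configuration reproduces the outputs byte-identically.
#'
#' `cmd_simulate()` integrates one protocol and writes the trajectory TSV
#' and a per-concentration summary CSV. `cmd_grid()` writes the full
#' protocol-by-concentration prediction grid. `cmd_synth()` generates the
#' synthetic uptake and colony-count CSVs. `cmd_compare()` reduces a
#' measurement CSV (baseline subtraction) and writes the model/measurement
#' comparison and per-protocol ratio CSVs.
#'
#' @param config_path path to a YAML run configuration
#'   (see [load_run_config()]).
#' @param protocol protocol name to simulate (must be configured).
#' @param out_dir output directory override; defaults to the configured one.
#' @return The main result of each driver, invisibly: the trajectory, the
#'   grid, the list of generated tables, or the comparison table.
#' @export
cmd_simulate <- function(config_path, protocol, out_dir = NULL) {
  cfg <- load_run_config(config_path)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!protocol %in% names(cfg$trains)) {
    stop("protocol '", protocol, "' is not in the configuration (have: ",
         paste(names(cfg$trains), collapse = ", "), ")")
  }
  tr <- cfg$trains[[protocol]]
  .pf_log(cfg, "info", "simulating ", protocol, " (", nrow(tr$segments),
          " segments)")
  traj <- simulate_train(tr, p = cfg$params, solver = cfg$solver,
                         t_end_min = cfg$t_end_min)
  write_trajectory(traj, file.path(out_dir, paste0(protocol, "_trajectory.tsv")))
  fin <- final_state(traj)
  summary <- data.frame(protocol = protocol,
                        E_applied = attr(traj, "E_applied"),
                        X_e_uM = cfg$concentrations_uM,
                        X_final = fin[["X"]],
                        molecules = molecules_per_cell(
                          fin[["X"]], cfg$concentrations_uM * 1e-6, r = cfg$params$r),
                        t_end_s = fin[["t_s"]])
  utils::write.csv(summary, file.path(out_dir, paste0(protocol, "_summary.csv")),
                   row.names = FALSE, quote = FALSE)
  .write_manifest(cfg, out_dir)
  invisible(traj)
}

#' @rdname cmd_simulate
#' @export
cmd_grid <- function(config_path, out_dir = NULL) {
  cfg <- load_run_config(config_path)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .pf_log(cfg, "info", "running prediction grid over ",
          length(cfg$trains), " protocols x ",
          length(cfg$concentrations_uM), " concentrations")
  grid <- run_protocol_grid(cfg$trains, cfg$concentrations_uM,
                            p = cfg$params, solver = cfg$solver,
                            t_end_min = cfg$t_end_min)
  utils::write.csv(grid, file.path(out_dir, "model_grid.csv"),
                   row.names = FALSE, quote = FALSE)
  .write_manifest(cfg, out_dir)
  invisible(grid)
}

#' @rdname cmd_simulate
#' @export
cmd_synth <- function(config_path, out_dir = NULL) {
  cfg <- load_run_config(config_path)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .pf_log(cfg, "info", "generating synthetic measurements (seed ", cfg$seed, ")")
  truth <- run_protocol_grid(cfg$trains[cfg$synth$protocols],
                             cfg$synth$concentrations_uM,
                             p = cfg$params, solver = cfg$solver,
                             t_end_min = cfg$t_end_min)
  uptake <- generate_uptake_measurements(cfg$synth, truth)
  write_measurements(uptake, file.path(out_dir, "synthetic_uptake.csv"))
  means <- subtract_baseline(uptake)
  counts <- generate_clonogenic_counts(cfg$synth, means)
  utils::write.csv(counts, file.path(out_dir, "synthetic_colonies.csv"),
                   row.names = FALSE, quote = FALSE)
  .write_manifest(cfg, out_dir)
  invisible(list(uptake = uptake, colonies = counts, truth = truth))
}

#' @rdname cmd_simulate
#' @param model_csv path to a prediction grid CSV (from [cmd_grid()]).
#' @param measurements_csv path to a replicate-level measurement CSV.
#' @export
cmd_compare <- function(config_path, model_csv, measurements_csv,
                        out_dir = NULL) {
  cfg <- load_run_config(config_path)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- utils::read.csv(model_csv, stringsAsFactors = FALSE)
  measured <- subtract_baseline(read_measurements(measurements_csv))
  cmp <- model_vs_measurement(model, measured)
  utils::write.csv(cmp, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(protocol_ratios(cmp),
                   file.path(out_dir, "protocol_ratios.csv"),
                   row.names = FALSE, quote = FALSE)
  .write_manifest(cfg, out_dir)
  invisible(cmp)
}
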