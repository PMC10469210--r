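## Run configuration: defaults, schema validation, YAML round-trip, fixture
## generation and output writing.

.config_schema <- function() list(
  scenario = c("ph", "ar"),
  seed = NULL, J = NULL, output_dir = NULL,
  geometry = c("outer_axes", "inner_axes", "trunc_height", "target_edge"),
  circulation = setdiff(names(formals(circulation_params)),
                        c("dt", "beats")),
  darcy = names(formals(darcy_params)),
  network = c("R_total_parallel", "alpha_share", "R_ostium_factor"),
  coupling = names(formals(coupling_config)),
  ar = c("orifice_fraction", "systolic_scale", "diastolic_scale"))

#' Default run configuration
#'
#' Two sizes are provided: `"tiny"` (coarse mesh, 4 territories; an
#' end-to-end run takes seconds) and `"small"` (the default study size:
#' finer mesh, 20 territories).
#'
#' @param scenario `"ph"` or `"ar"`.
#' @param level `"tiny"` or `"small"`.
#' @param seed RNG seed for the heterogeneity draw.
#' @param ... named overrides of the nested sections (`geometry`,
#'   `circulation`, `darcy`, `network`, `coupling`, `ar`) or of the scalar
#'   fields.
#' @return object of class `run_config`.
#' @export
default_config <- function(scenario = "ph", level = c("small", "tiny"),
                           seed = 1L, ...) {
  level <- match.arg(level)
  cfg <- list(
    scenario = scenario,
    seed = as.integer(seed),
    J = if (level == "tiny") 4L else 20L,
    geometry = list(outer_axes = c(40, 40, 60), inner_axes = c(29, 29, 51),
                    trunc_height = 18,
                    target_edge = if (level == "tiny") 12 else 7),
    circulation = list(),
    darcy = list(),
    network = list(),
    coupling = coupling_config(),
    ar = list(orifice_fraction = 0.045, systolic_scale = 1.2,
              diastolic_scale = 0.8),
    output_dir = NULL)
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(.config_schema())) {
      stop(sprintf("unknown config field '%s'", nm))
    }
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  validate_config(cfg)
}

#' Validate a run configuration against the schema
#'
#' Rejects unknown keys (naming the offending key), checks positivity of the
#' physical parameters, and returns the config with class `run_config`.
#'
#' @param cfg a (possibly bare-list) configuration.
#' @return validated `run_config`.
#' @export
validate_config <- function(cfg) {
  schema <- .config_schema()
  for (nm in names(cfg)) {
    if (!nm %in% names(schema)) {
      stop(sprintf("unknown config field '%s'", nm))
    }
    sub <- schema[[nm]]
    if (nm %in% c("geometry", "circulation", "darcy", "network",
                  "coupling", "ar")) {
      bad <- setdiff(names(cfg[[nm]]), sub)
      if (length(bad)) {
        stop(sprintf("unknown config field '%s.%s'", nm, bad[1]))
      }
    }
  }
  if (!cfg$scenario %in% schema$scenario) {
    stop("config field 'scenario' must be \"ph\" or \"ar\"")
  }
  if (!is.null(cfg$darcy$gamma) && cfg$darcy$gamma <= 0) {
    stop("config field 'gamma' must be positive")
  }
  for (f in c("beta12", "beta23", "beta13")) {
    if (!is.null(cfg$darcy[[f]]) && cfg$darcy[[f]] < 0) {
      stop(sprintf("config field '%s' must be non-negative", f))
    }
  }
  if (!is.null(cfg$J) && cfg$J < 1) stop("config field 'J' must be >= 1")
  # constructors enforce the remaining physical constraints
  do.call(darcy_params, cfg$darcy)
  do.call(circulation_params, cfg$circulation)
  cp <- cfg$coupling
  if (!inherits(cp, "coupling_config")) {
    cfg$coupling <- do.call(coupling_config, as.list(cp))
  }
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run configuration: scenario %s, J = %d territories, seed %d\n",
              toupper(x$scenario), x$J, x$seed))
  cat(sprintf("  mesh target edge %.1f mm; dt %.0e s, %d beats\n",
              x$geometry$target_edge, x$coupling$dt, x$coupling$beats))
  invisible(x)
}

#' Load a run configuration from a YAML file
#'
#' Missing sections take the documented defaults; unknown keys are rejected
#' with a message naming the key.
#'
#' @param path YAML file path.
#' @return validated `run_config`.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  level <- raw$level
  raw$level <- NULL
  args <- c(list(scenario = raw$scenario %||% "ph",
                 level = level %||% "small",
                 seed = raw$seed %||% 1L),
            raw[setdiff(names(raw), c("scenario", "seed"))])
  do.call(default_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration as YAML
#'
#' @param cfg a `run_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$coupling <- unclass(out$coupling)
  out$output_dir <- NULL
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Build a complete small test case on disk
#'
#' Generates the mesh, territories and a fully defaulted configuration,
#' writes the mesh (legacy VTK, with region labels as the `"region"` cell
#' array) and the configuration (YAML) into `dir`, and returns the config.
#' Deterministic given `seed`.
#'
#' @param level `"tiny"` (solves end-to-end in seconds) or `"small"`.
#' @param seed RNG seed.
#' @param dir output directory (created if needed).
#' @param scenario scenario tag stored in the config.
#' @return the `run_config`, with `output_dir` set to `dir`.
#' @export
make_fixture <- function(level = c("tiny", "small"), seed = 1L,
                         dir = tempfile("perfusim_fixture_"),
                         scenario = "ph") {
  level <- match.arg(level)
  cfg <- default_config(scenario = scenario, level = level, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- cfg$geometry
  mesh <- generate_biventricle(g$outer_axes, g$inner_axes, g$trunc_height,
                               g$target_edge)
  cs <- coronary_seeds(cfg$J, g$outer_axes, g$trunc_height)
  regions <- partition_regions(mesh, cs$seeds)
  write_vtk(mesh, file.path(dir, "mesh.vtk"),
            cell_data = list(region = as.integer(regions$labels)))
  save_config(cfg, file.path(dir, "config.yaml"))
  cfg$output_dir <- dir
  cfg
}

#' Write all scenario outputs to a directory
#'
#' Stable, documented filenames: `transients.csv` (one row per time step),
#' `convergence.csv`, `biomarkers.json`, `mbf_regions.csv` (per-territory
#' MBF at the diastolic peak) and `fields_peak.vtu` (point arrays `p1_Pa`,
#' `p2_Pa`, `p3_Pa`, `MBF_mL_min_100mL`; cell arrays `region`, `MBF_cell`).
#'
#' @param result a `scenario_result`.
#' @param dir output directory (created if needed).
#' @return character vector of paths written, invisibly.
#' @export
write_outputs <- function(result, dir) {
  stopifnot(inherits(result, "scenario_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "transients.csv")
  utils::write.csv(as.data.frame(result$transients), p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "convergence.csv")
  utils::write.csv(result$convergence, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "biomarkers.json")
  bio <- c(result$biomarkers,
           list(scenario = result$scenario,
                Q_cor_diastolic_peak_mL_s = result$peak$Q_total_mL_s,
                Q_cor_systolic_peak_mL_s = result$peak$Q_systolic_peak_mL_s,
                MBF_mean_mL_min_100mL = result$mbf$mean,
                diastolic_peak_time_s = result$peak$time_s))
  jsonlite::write_json(bio, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  p <- file.path(dir, "mbf_regions.csv")
  utils::write.csv(data.frame(region = seq_along(result$mbf$region_means),
                              volume_mL = result$regions$region_volumes / 1000,
                              MBF_mL_min_100mL = result$mbf$region_means),
                   p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "fields_peak.vtu")
  st <- result$state_peak
  write_vtu(result$mesh, p,
            point_data = list(
              p1_Pa = st$p1, p2_Pa = st$p2, p3_Pa = st$p3,
              MBF_mL_min_100mL = cell_to_node(result$mesh, result$mbf$mbf)),
            cell_data = list(
              region = as.integer(result$regions$labels),
              MBF_cell = result$mbf$mbf))
  paths <- c(paths, p)
  invisible(paths)
}
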