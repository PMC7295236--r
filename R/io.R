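.config_schema <- c("shape", "r_eq_mm", "lambda", "antenna_kind",
                    "L_over_b", "power_W", "frequency_GHz", "duration_s",
                    "dt_s", "T_init_C", "Ds", "monitor_mode",
                    "lesion_threshold", "cadence_s", "res", "ex_vivo",
                    "em_resolve_tol", "materials", "domain")

#' Parse and validate a YAML scenario configuration
#'
#' Reads a YAML file whose keys mirror the arguments of
#' [scenario_config()]; unknown keys are rejected with the offending path,
#' missing keys take the package defaults (logged with provenance when
#' `verbose`), and values pass through the same validation as
#' [scenario_config()]. An optional `materials:` block (the structure
#' written by [materials_to_list()]) overrides the packaged constants; an
#' optional `domain:` block overrides the domain cylinder.
#'
#' @param path Path to a YAML file.
#' @param verbose Print a provenance line per key (default vs file)?
#' @return A validated [scenario_config()].
#' @export
parse_config <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .config_schema)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$materials))
    raw$materials <- materials_from_list(raw$materials)
  if (!is.null(raw$domain))
    raw$domain <- do.call(domain_spec, raw$domain)
  if (verbose) {
    for (k in .config_schema) {
      src <- if (k %in% names(raw)) "file" else "default"
      message(sprintf("config %-16s <- %s", k, src))
    }
  }
  do.call(scenario_config, raw)
}

#' Write a scenario configuration to YAML
#'
#' @param config A [scenario_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  x <- unclass(config)
  x$materials <- materials_to_list(x$materials)
  x$domain <- unclass(x$domain)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Write a field snapshot in legacy VTK format
#'
#' Structured-grid ASCII VTK of the (r,z) cell centers with any number of
#' per-cell scalar fields, for inspection in ParaView or similar.
#'
#' @param mesh An `axi_mesh`.
#' @param fields Named list of nr x nz matrices (or vectors).
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, fields, path) {
  stopifnot(is.list(fields), length(names(fields)) == length(fields))
  con <- file(path, "w")
  on.exit(close(con))
  nr <- mesh$nr; nz <- mesh$nz
  writeLines(c("# vtk DataFile Version 3.0",
               "axisymmetric field snapshot (r,z half-plane)",
               "ASCII", "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", nr, nz),
               sprintf("POINTS %d float", nr * nz)), con)
  pts <- cbind(rep(mesh$rc, nz), rep(mesh$zc, each = nr), 0)
  writeLines(apply(pts, 1, function(p)
    sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])), con)
  writeLines(sprintf("POINT_DATA %d", nr * nz), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", as.numeric(fields[[nm]])), con)
  }
  invisible(path)
}

#' Write scenario outputs and a run manifest
#'
#' Emits the metric time series as CSV (UTF-8, header row, unit-suffixed
#' column names), optional VTK field snapshots of the final state, and a
#' JSON manifest recording the configuration hash, parameter provenance,
#' package version and output inventory. Re-running with identical inputs
#' reproduces identical tables.
#'
#' @param result A `scenario_result` from [run_until_side_effect()].
#' @param out_dir Output directory (created if needed).
#' @param snapshots Write a VTK snapshot of the final fields?
#' @return The manifest, invisibly (class `run_manifest`).
#' @export
write_outputs <- function(result, out_dir, snapshots = TRUE) {
  stopifnot(inherits(result, "scenario_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  traj <- result$trajectory
  ren <- c(time_s = "time_s", T_max_C = "T_max_C",
           tumor_A = "tumor_mean_alive_frac",
           tumor_V = "tumor_mean_vulnerable_frac",
           tumor_D = "tumor_mean_dead_frac",
           shell_D = "shell_mean_dead_frac", point_D = "point_dead_frac",
           monitor_D = "monitor_dead_frac")
  names(traj) <- ifelse(names(traj) %in% names(ren),
                        ren[names(traj)], names(traj))
  csv <- file.path(out_dir, "metrics.csv")
  write.csv(traj, csv, row.names = FALSE)
  sumfile <- file.path(out_dir, "summary.csv")
  write.csv(data.frame(stop_reason = result$stop_reason,
                       stop_time_s = result$stop_time_s,
                       tumor_dead_pct = result$tumor_dead_pct,
                       monitor_dead_pct = result$monitor_dead_pct,
                       long_axis_cm = result$long_axis_cm,
                       short_axis_cm = result$short_axis_cm,
                       contraction_pct = result$contraction_pct),
            sumfile, row.names = FALSE)
  files <- c(csv, sumfile)
  if (snapshots) {
    vf <- viability_fields(result$final$cells)
    vtk <- file.path(out_dir, "final_fields.vtk")
    write_vtk(result$final$mesh,
              list(temperature_C = result$final$thermal$T,
                   alive_frac = matrix(vf$A, result$final$mesh$nr),
                   dead_frac = matrix(vf$D, result$final$mesh$nr),
                   lesion_VplusD = matrix(vf$lesion, result$final$mesh$nr),
                   Q_ext_W_m3 = result$final$Q), vtk)
    files <- c(files, vtk)
  }
  manifest <- list(
    config_hash = config_hash(result$config),
    package_version = as.character(packageVersion("mwablate")),
    snapshots = snapshots,
    outputs = basename(files))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  manifest$path <- mf
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' Stable hash of a scenario configuration
#'
#' Platform-independent hex digest of the configuration's deparsed value
#' (a 32-bit FNV-1a over the serialized key/value text), used for run
#' provenance and determinism checks.
#'
#' @param config A [scenario_config()].
#' @return Character scalar, 8 hex digits.
#' @export
config_hash <- function(config) {
  base <- unclass(config)
  base$materials <- materials_to_list(config$materials)
  base$domain <- unclass(base$domain)
  txt <- paste(deparse(base, control = c("keepNA", "niceNames", "showAttributes")),
               collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
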