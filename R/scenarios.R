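#' Scenario configuration
#'
#' Bundles everything one treatment simulation needs: tumor geometry,
#' antenna layout, domain, physics (power, frequency, duration, time step,
#' initial temperature), the collateral-damage stopping rule and metric
#' settings.
#'
#' @param shape Tumor shape: `"sphere"`, `"prolate"`, `"oblate"`, or
#'   `"none"` for homogeneous tissue.
#' @param r_eq_mm Equivalent tumor radius (mm).
#' @param lambda Major-to-minor aspect ratio (>= 1).
#' @param antenna_kind `"single_slot"` or `"double_slot"`.
#' @param L_over_b Slot-to-slot distance as a multiple of the tumor
#'   semi-major axis (double slot only).
#' @param power_W Input power (W), >= 0.
#' @param frequency_GHz Operating frequency (GHz), > 0.
#' @param duration_s Treatment duration cap (s); the stopping rule may end
#'   the run earlier.
#' @param dt_s Time step (s).
#' @param T_init_C Initial tissue temperature (deg C).
#' @param Ds Allowable mean dead-cell fraction in the monitored healthy
#'   region, in (0, 1).
#' @param monitor_mode `"shell_8x"` (mean dead fraction over the healthy
#'   shell of eight tumor volumes) or `"point_2p5mm"` (dead fraction at the
#'   fixed point 2.5 mm outside the tumor border). Ignored without a tumor.
#' @param lesion_threshold Contour level on V + D delimiting the ablation
#'   zone.
#' @param cadence_s Metric recording interval (s).
#' @param res Mesh resolution multiplier (see [build_mesh()]).
#' @param ex_vivo Excised-tissue mode: perfusion and metabolism off and the
#'   boundary bulk temperature tied to `T_init_C`.
#' @param em_resolve_tol Conductivity drift triggering an EM re-solve.
#' @param materials A [material_model()]; defaults to [default_materials()].
#' @param domain A [domain_spec()].
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(shape = "sphere", r_eq_mm = 5, lambda = 1,
                            antenna_kind = "single_slot", L_over_b = 1,
                            power_W = 20, frequency_GHz = 2.45,
                            duration_s = 1200, dt_s = 0.1, T_init_C = 37,
                            Ds = 0.10,
                            monitor_mode = c("shell_8x", "point_2p5mm"),
                            lesion_threshold = 0.5, cadence_s = 1,
                            res = 1, ex_vivo = FALSE, em_resolve_tol = 0.02,
                            materials = NULL, domain = domain_spec()) {
  monitor_mode <- match.arg(monitor_mode)
  if (!shape %in% c("sphere", "prolate", "oblate", "none"))
    stop("unknown tumor shape '", shape, "'", call. = FALSE)
  if (shape %in% c("prolate", "oblate") && lambda < 1)
    stop("lambda is major/minor and must be >= 1", call. = FALSE)
  if (power_W < 0) stop("power_W must be nonnegative", call. = FALSE)
  if (frequency_GHz <= 0) stop("frequency_GHz must be positive", call. = FALSE)
  if (Ds <= 0 || Ds >= 1) stop("Ds must lie in (0,1)", call. = FALSE)
  stopifnot(duration_s > 0, dt_s > 0, r_eq_mm > 0)
  if (is.null(materials)) {
    amb <- ambient_params(T0 = if (ex_vivo) T_init_C else 37)
    materials <- default_materials(ambient = amb)
  }
  structure(list(shape = shape, r_eq_mm = r_eq_mm, lambda = lambda,
                 antenna_kind = antenna_kind, L_over_b = L_over_b,
                 power_W = power_W, frequency_GHz = frequency_GHz,
                 duration_s = duration_s, dt_s = dt_s, T_init_C = T_init_C,
                 Ds = Ds, monitor_mode = monitor_mode,
                 lesion_threshold = lesion_threshold, cadence_s = cadence_s,
                 res = res, ex_vivo = ex_vivo,
                 em_resolve_tol = em_resolve_tol,
                 materials = materials, domain = domain),
            class = "scenario_config")
}

# materialize mesh + monitor handles from a config
.scenario_setup <- function(config) {
  tumor <- if (config$shape == "none") NULL
           else make_tumor(config$shape, config$r_eq_mm * 1e-3, config$lambda)
  ant <- if (config$antenna_kind == "double_slot") {
    if (is.null(tumor))
      stop("double_slot layout requires a tumor (L scales with b)",
           call. = FALSE)
    antenna_layout("double_slot", L = config$L_over_b * tumor$semi_z)
  } else antenna_layout("single_slot")
  mesh <- build_mesh(tumor, ant, config$domain, res = config$res)
  mon <- if (!is.null(tumor)) monitor_regions(mesh) else NULL
  list(tumor = tumor, antenna = ant, mesh = mesh, monitor = mon)
}

#' Run a treatment scenario under the side-effect stopping rule
#'
#' Runs the coupled electromagnetic-bioheat-cell-death loop and terminates
#' at the first recording instant where the monitored healthy-tissue dead
#' fraction reaches the allowable level `Ds` (mean over the 8x-volume
#' healthy shell, or the fixed point 2.5 mm outside the tumor border,
#' per `monitor_mode`), or at the duration cap. Without a tumor the run
#' lasts the full duration.
#'
#' @param config A [scenario_config()].
#' @return An object of class `scenario_result`: the metric time series
#'   (`trajectory`), stopping time and reason, final tumor/monitor dead
#'   fractions (%), ablation-zone long/short axes (cm), volumetric
#'   contraction (%), and the final states/mesh for inspection.
#' @export
run_until_side_effect <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set <- .scenario_setup(config)
  mesh <- set$mesh; mon <- set$monitor
  mat <- config$materials
  if (config$ex_vivo) {
    mat$ambient$T0 <- config$T_init_C
    mat$ambient$Qm <- 0
  }
  control <- bioheat_control(perfusion = !config$ex_vivo)
  # metrics weight: tumor membership restricted to actual tissue cells
  tumor_w <- mesh$frac_tumor * (mesh$region <= REG[["tumor"]])
  homog <- is.null(set$tumor)

  # fixed radial thermometry probes at the slot level (validation runs
  # monitor temperature 4.5 and 7 mm from the antenna slot)
  jp <- which.min(abs(mesh$zc - mesh$z_slots[1]))
  ip <- vapply(c(4.5e-3, 7e-3), function(r0) which.min(abs(mesh$rc - r0)), 0L)

  monitor_fn <- function(sim) {
    vf <- viability_fields(sim$cells)
    Tm <- sim$thermal$T
    out <- c(T_max_C = max(Tm[mesh$region <= REG[["tumor"]]]),
             T_probe_4p5mm_C = Tm[ip[1], jp],
             T_probe_7mm_C = Tm[ip[2], jp])
    if (!homog) {
      out <- c(out,
        tumor_A = region_mean(vf$A, tumor_w, mesh$vol),
        tumor_V = region_mean(vf$V, tumor_w, mesh$vol),
        tumor_D = region_mean(vf$D, tumor_w, mesh$vol),
        shell_D = region_mean(vf$D, mon$frac_shell, mesh$vol),
        point_D = matrix(vf$D, mesh$nr, mesh$nz)[mon$point_index])
      out["monitor_D"] <- if (config$monitor_mode == "shell_8x")
        out[["shell_D"]] else out[["point_D"]]
    }
    out
  }
  stop_fn <- if (homog) NULL else function(row) {
    row[["monitor_D"]] >= config$Ds
  }

  run <- run_coupled(mesh, mat, P_in = config$power_W,
                     f = config$frequency_GHz * 1e9,
                     t_end = config$duration_s, dt = config$dt_s,
                     T_init = config$T_init_C, control = control,
                     em_resolve_tol = config$em_resolve_tol,
                     cadence = config$cadence_s,
                     monitor = monitor_fn, stop_when = stop_fn)

  vf <- viability_fields(run$cells)
  axes <- ablation_axes(vf$lesion, mesh, config$lesion_threshold)
  tissue_w <- (mesh$region <= REG[["tumor"]]) * 1
  shrep <- shrinkage_report(run$shrink, as.numeric(run$thermal$T),
                            as.numeric((if (homog) tissue_w else tumor_w) *
                                         mesh$vol))
  last <- run$trajectory[nrow(run$trajectory), ]
  structure(list(
    config = config, trajectory = run$trajectory,
    stop_reason = if (run$stop_reason == "stopped") "side_effect_reached"
                  else "cap_reached",
    stop_time_s = run$stop_time,
    tumor_dead_pct = if (homog) NA_real_ else 100 * last[["tumor_D"]],
    monitor_dead_pct = if (homog) NA_real_ else 100 * last[["monitor_D"]],
    long_axis_cm = 100 * axes[["long_axis_m"]],
    short_axis_cm = 100 * axes[["short_axis_m"]],
    lesion_empty = isTRUE(attr(axes, "empty")),
    contraction_pct = 100 * shrep$contraction,
    final = run), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("scenario_result:", x$config$shape,
      sprintf("r_eq %.1f mm lambda %.1f | %g W %g GHz | %s at %.0f s",
              x$config$r_eq_mm, x$config$lambda, x$config$power_W,
              x$config$frequency_GHz, x$stop_reason, x$stop_time_s), "\n")
  if (!is.na(x$tumor_dead_pct))
    cat(sprintf("  tumor mean dead %.1f%% | monitor %.1f%%\n",
                x$tumor_dead_pct, x$monitor_dead_pct))
  cat(sprintf("  ablation zone %.2f x %.2f cm | contraction %.1f%%\n",
              x$long_axis_cm, x$short_axis_cm, x$contraction_pct))
  invisible(x)
}

.preset_table <- function(name, res, dt_s) {
  base <- list(res = res, dt_s = dt_s)
  mk <- function(label, ...) c(list(label = label), base, list(...))
  switch(name,
    power_size = lapply(list(
      c(r = 5, P = 25), c(r = 5, P = 50), c(r = 10, P = 25),
      c(r = 10, P = 50), c(r = 15, P = 25), c(r = 15, P = 50)),
      function(x) mk(sprintf("r%.1fcm_%gW", x[["r"]] / 10, x[["P"]]),
                     shape = "sphere", r_eq_mm = x[["r"]],
                     power_W = x[["P"]], frequency_GHz = 2.45,
                     monitor_mode = "point_2p5mm")),
    shape_lambda = lapply(list(
      list(s = "oblate", l = 2), list(s = "prolate", l = 2),
      list(s = "oblate", l = 5), list(s = "prolate", l = 5)),
      function(x) mk(sprintf("%s_lambda%d", x$s, x$l), shape = x$s,
                     lambda = x$l, r_eq_mm = 5, power_W = 20,
                     frequency_GHz = 2.45, monitor_mode = "shell_8x")),
    frequency_shape = {
      shapes <- list(list(s = "sphere", l = 1), list(s = "oblate", l = 2),
                     list(s = "oblate", l = 5), list(s = "prolate", l = 2),
                     list(s = "prolate", l = 5))
      out <- list()
      for (f in c(2.45, 6)) for (x in shapes)
        out[[length(out) + 1]] <- mk(
          sprintf("%s_lambda%d_%gGHz", x$s, x$l, f), shape = x$s,
          lambda = x$l, r_eq_mm = 5, power_W = 20, frequency_GHz = f,
          monitor_mode = "shell_8x")
      out
    },
    antenna_slots = lapply(list(
      list(k = "single_slot", L = NA, lab = "single_slot"),
      list(k = "double_slot", L = 1, lab = "double_slot_L1b"),
      list(k = "double_slot", L = 1.4, lab = "double_slot_L1.4b")),
      function(x) {
        args <- mk(x$lab, shape = "prolate", lambda = 5, r_eq_mm = 5,
                   power_W = 70, frequency_GHz = 2.45,
                   monitor_mode = "shell_8x", antenna_kind = x$k)
        if (!is.na(x$L)) args$L_over_b <- x$L
        args
      }),
    sun_validation = list(
      mk("80W_915MHz", shape = "none", power_W = 80, frequency_GHz = 0.915,
         duration_s = 600),
      mk("50W_2.45GHz", shape = "none", power_W = 50, frequency_GHz = 2.45,
         duration_s = 600)),
    yang_validation = list(
      mk("75W_2.45GHz_exvivo", shape = "none", power_W = 75,
         frequency_GHz = 2.45, duration_s = 150, T_init_C = 5,
         ex_vivo = TRUE)),
    stop("unknown preset '", name, "'", call. = FALSE))
}

#' Named scenario studies
#'
#' Materializes one of the packaged treatment studies and runs every
#' condition:
#' * `power_size` — spherical tumors of 0.5/1/1.5 cm radius at 25 and 50 W,
#'   2.45 GHz, point-monitor stopping.
#' * `shape_lambda` — oblate/prolate tumors at aspect ratios 2 and 5, all
#'   with the volume of a 0.5 cm sphere, 20 W, 2.45 GHz, shell stopping.
#' * `frequency_shape` — the five shapes at 2.45 vs 6 GHz, 20 W, shell
#'   stopping.
#' * `antenna_slots` — prolate lambda = 5 tumor at 70 W, 2.45 GHz: single
#'   slot, double slot L = b and L = 1.4 b.
#' * `sun_validation` — homogeneous liver at 80 W / 915 MHz and
#'   50 W / 2.45 GHz for 600 s (ablation-zone axes).
#' * `yang_validation` — homogeneous excised liver at 75 W / 2.45 GHz for
#'   150 s from 5 deg C.
#'
#' @param name Preset name (see above).
#' @param res Mesh resolution multiplier applied to every run.
#' @param dt_s Time step (s) applied to every run.
#' @param ... Further overrides applied to every condition's
#'   [scenario_config()] (e.g. `duration_s`, `Ds`).
#' @return A data frame with one row per condition: label, configuration
#'   summary, stopping time/reason, tumor and monitor mean dead fractions
#'   (%), ablation-zone axes (cm) and volumetric contraction (%). The
#'   individual `scenario_result` objects are attached as attribute
#'   `"results"`.
#' @export
scenario_suite <- function(name, res = 1, dt_s = 0.5, ...) {
  specs <- .preset_table(name, res, dt_s)
  overrides <- list(...)
  results <- lapply(specs, function(sp) {
    label <- sp$label; sp$label <- NULL
    sp[names(overrides)] <- overrides
    r <- run_until_side_effect(do.call(scenario_config, sp))
    r$label <- label
    r
  })
  tab <- do.call(rbind, lapply(results, function(r) data.frame(
    label = r$label, shape = r$config$shape, lambda = r$config$lambda,
    r_eq_mm = r$config$r_eq_mm, antenna = r$config$antenna_kind,
    power_W = r$config$power_W, frequency_GHz = r$config$frequency_GHz,
    stop_reason = r$stop_reason, stop_time_s = r$stop_time_s,
    tumor_dead_pct = r$tumor_dead_pct,
    monitor_dead_pct = r$monitor_dead_pct,
    long_axis_cm = r$long_axis_cm, short_axis_cm = r$short_axis_cm,
    contraction_pct = r$contraction_pct)))
  attr(tab, "results") <- results
  tab
}
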