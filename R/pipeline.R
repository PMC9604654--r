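# Config-driven orchestration of the comparison experiment grid:
# scenario x conductivity groups x {AC, IC} x amplitudes, with optional
# thermal runs and paired AC-vs-IC difference statistics.

#' Run configuration
#'
#' @param scenario a [scenario_config()]; `scenario_kind` selects the
#'   builder (`"slab"` or `"ostium"`).
#' @param scenario_kind `"slab"` or `"ostium"`.
#' @param ostium_diameter hole diameter (m), ostium scenarios only.
#' @param groups conductivity groups: integers in 1..4, or a list of
#'   [conductivity_model()] objects for custom ratios.
#' @param modes subset of `c("AC", "IC")`.
#' @param amplitudes pulse amplitudes (V), all positive.
#' @param protocol a [pulse_protocol()].
#' @param solver a [solver_settings()].
#' @param thermal logical; run the thermal comparison at `thermal_amplitude`.
#' @param thermal_mode `"GATED"` or `"DUTY_AVERAGED"`.
#' @param thermal_amplitude amplitude (V) used for the thermal runs.
#' @param threshold ablation field threshold (V/m).
#' @param field_dependent logical; solve with the electroporation sigmoid
#'   engaged (the full model). `FALSE` freezes every cell at its baseline
#'   (pre-electroporation) conductivities, which isolates the pure
#'   fiber-anisotropy effect on the field distribution.
#' @param velocity_profile `"none"`, `"plug"` or `"poiseuille"` blood flow.
#' @param u_max peak blood speed (m/s).
#' @param output_dir optional directory for CSV/VTK artifacts.
#' @param seed integer; recorded and set for reproducibility (the pipeline
#'   itself is deterministic).
#' @return list of class `run_config`.
#' @export
run_config <- function(scenario = scenario_config(),
                       scenario_kind = c("slab", "ostium"),
                       ostium_diameter = 8e-3,
                       groups = 1:4, modes = c("AC", "IC"),
                       amplitudes = c(1000, 1500, 2000),
                       protocol = pulse_protocol(),
                       solver = solver_settings(),
                       thermal = FALSE,
                       thermal_mode = c("GATED", "DUTY_AVERAGED"),
                       thermal_amplitude = 1000,
                       threshold = 1e5,
                       field_dependent = TRUE,
                       velocity_profile = c("none", "plug", "poiseuille"),
                       u_max = 0.1,
                       output_dir = NULL, seed = 1L) {
  scenario_kind <- match.arg(scenario_kind)
  thermal_mode <- match.arg(thermal_mode)
  velocity_profile <- match.arg(velocity_profile)
  if (!length(groups) || !length(modes) || !length(amplitudes))
    stop("config error: empty experiment grid")
  if (any(amplitudes <= 0)) stop("config error: amplitudes must be positive")
  if (!all(modes %in% c("AC", "IC"))) stop("config error: unknown mode")
  if (is.numeric(groups) && !all(groups %in% 1:4))
    stop("config error: integer groups must be in 1..4")
  structure(list(scenario = scenario, scenario_kind = scenario_kind,
                 ostium_diameter = ostium_diameter, groups = groups,
                 modes = modes, amplitudes = amplitudes, protocol = protocol,
                 solver = solver, thermal = thermal,
                 thermal_mode = thermal_mode,
                 thermal_amplitude = thermal_amplitude, threshold = threshold,
                 field_dependent = isTRUE(field_dependent),
                 velocity_profile = velocity_profile, u_max = u_max,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Field names mirror the [run_config()] arguments; the nested `scenario`
#' and `protocol` maps mirror [scenario_config()] and [pulse_protocol()].
#' Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config error: no such file: ", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("config error: unknown keys: ", paste(bad, collapse = ", "))
  if (!is.null(y$scenario)) y$scenario <- do.call(scenario_config, y$scenario)
  if (!is.null(y$protocol)) y$protocol <- do.call(pulse_protocol, y$protocol)
  if (!is.null(y$solver)) y$solver <- do.call(solver_settings, y$solver)
  do.call(run_config, y)
}

cell_models <- function(config) {
  if (is.list(config$groups)) {
    models <- config$groups
    labels <- vapply(models, function(m)
      sprintf("R=%.4g", m$ratio_R), character(1))
  } else {
    models <- lapply(config$groups, function(g)
      conductivity_model(group = g, mode = "AC",
                         field_dependent = config$field_dependent))
    labels <- as.character(config$groups)
  }
  list(models = models, labels = labels)
}

#' Run the AC-vs-IC comparison grid
#'
#' For every grid cell (conductivity group x mode x amplitude): build the
#' scenario and fiber field once, solve the nonlinear potential problem,
#' and compute the lesion metrics; then pair each anisotropic cell with its
#' isotropic counterpart (same amplitude; the isotropic baseline is shared
#' by all groups) and aggregate the differences. Optionally runs the gated
#' thermal protocol for the highest-ratio group and its isotropic
#' counterpart at `thermal_amplitude`.
#'
#' @param config a [run_config()].
#' @return object of class `comparison_report`: `cells` (metrics data
#'   frame), `pairs` (per group x amplitude paired differences),
#'   `aggregates` (mean and sd rows), and `thermal` (max-temperature traces
#'   and their difference, or `NULL`).
#' @export
run_comparison <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  mesh <- switch(config$scenario_kind,
                 slab = build_slab_scenario(config$scenario),
                 ostium = build_ostium_scenario(config$scenario,
                                                config$ostium_diameter))
  fibers <- make_fiber_field(mesh)
  cm <- cell_models(config)

  cells <- list()
  solutions <- list()
  add_cell <- function(group_label, mode, amplitude, model) {
    key <- paste(group_label, mode, amplitude, sep = "|")
    sol <- solve_potential(mesh, fibers, model, amplitude, config$solver)
    met <- ablation_metrics(mesh, sol, config$threshold)
    solutions[[key]] <<- sol
    cells[[key]] <<- data.frame(
      scenario = config$scenario_kind, group = group_label, mode = mode,
      amplitude_V = amplitude, area_mm2 = met$area_mm2,
      volume_mm3 = met$volume_mm3,
      extent_x_mm = unname(met$extents_mm["extent_x"]),
      extent_y_mm = unname(met$extents_mm["extent_y"]),
      extent_z_mm = unname(met$extents_mm["extent_z"]),
      picard_iterations = sol$picard_iterations)
  }

  ic_model <- conductivity_model(mode = "IC",
                                 field_dependent = config$field_dependent)
  for (amp in config$amplitudes) {
    if ("IC" %in% config$modes)
      add_cell("IC", "IC", amp, ic_model)
    if ("AC" %in% config$modes)
      for (gi in seq_along(cm$models))
        add_cell(cm$labels[gi], "AC", amp, cm$models[[gi]])
  }
  cells_df <- do.call(rbind, cells)
  rownames(cells_df) <- NULL

  pairs_df <- NULL
  if (all(c("AC", "IC") %in% config$modes)) {
    rows <- list()
    for (amp in config$amplitudes) {
      ic <- cells_df[cells_df$mode == "IC" & cells_df$amplitude_V == amp, ]
      for (gl in cm$labels) {
        ac <- cells_df[cells_df$group == gl & cells_df$mode == "AC" &
                         cells_df$amplitude_V == amp, ]
        if (!nrow(ac) || !nrow(ic)) next
        pd_vol <- paired_difference(ac$volume_mm3, ic$volume_mm3, "volume")
        pd_area <- paired_difference(ac$area_mm2, ic$area_mm2, "area")
        rows[[length(rows) + 1L]] <- data.frame(
          group = gl, amplitude_V = amp,
          d_volume_pct = pd_vol$percent, volume_significant = pd_vol$significant,
          d_area_pct = pd_area$percent, area_significant = pd_area$significant,
          d_extent_x_mm = ac$extent_x_mm - ic$extent_x_mm,
          d_extent_y_mm = ac$extent_y_mm - ic$extent_y_mm,
          d_extent_z_mm = ac$extent_z_mm - ic$extent_z_mm)
      }
    }
    pairs_df <- do.call(rbind, rows)
  }

  aggregates <- NULL
  if (!is.null(pairs_df) && nrow(pairs_df) >= 2) {
    agg_row <- function(name, v) {
      s <- aggregate_stats(v)
      data.frame(metric = name, mean = unname(s["mean"]), sd = unname(s["sd"]))
    }
    aggregates <- rbind(
      agg_row("d_volume_pct", pairs_df$d_volume_pct),
      agg_row("d_area_pct", pairs_df$d_area_pct),
      agg_row("abs_d_extent_x_mm", abs(pairs_df$d_extent_x_mm)),
      agg_row("abs_d_extent_y_mm", abs(pairs_df$d_extent_y_mm)),
      agg_row("abs_d_extent_z_mm", abs(pairs_df$d_extent_z_mm)))
  }

  thermal <- NULL
  if (isTRUE(config$thermal)) {
    vel <- if (config$velocity_profile == "none") NULL
           else velocity_field(mesh, config$velocity_profile, config$u_max)
    amp <- config$thermal_amplitude
    ac_model <- cm$models[[which.max(vapply(cm$models, `[[`, numeric(1),
                                            "ratio_R"))]]
    protocol <- config$protocol
    protocol$amplitude <- amp
    run_one <- function(model) {
      sol <- solve_potential(mesh, fibers, model, amp, config$solver)
      run_thermal_protocol(mesh, sol, protocol, velocity = vel,
                           mode = config$thermal_mode)
    }
    th_ac <- run_one(ac_model)
    th_ic <- run_one(ic_model)
    max_ac <- max(th_ac$max_T_trace$T_max)
    max_ic <- max(th_ic$max_T_trace$T_max)
    thermal <- list(
      trace_ac = th_ac$max_T_trace, trace_ic = th_ic$max_T_trace,
      max_T_ac = max_ac, max_T_ic = max_ic,
      difference = paired_difference(max_ac, max_ic, "temperature"))
  }

  report <- list(cells = cells_df, pairs = pairs_df, aggregates = aggregates,
                 thermal = thermal, config = config)
  class(report) <- "comparison_report"
  if (!is.null(config$output_dir))
    write_report(report, config$output_dir, mesh = mesh,
                 solutions = solutions)
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report:", nrow(x$cells), "cells\n")
  print(x$cells, digits = 4)
  if (!is.null(x$pairs)) {
    cat("\nAC - IC paired differences:\n")
    print(x$pairs, digits = 4)
  }
  if (!is.null(x$thermal))
    cat("\nmax myocardial T: AC", signif(x$thermal$max_T_ac, 5), "degC, IC",
        signif(x$thermal$max_T_ic, 5), "degC\n")
  invisible(x)
}

#' Write report artifacts
#'
#' Writes `cells.csv`, `pairs.csv`, `aggregates.csv` and (when present)
#' `thermal_trace_ac.csv` / `thermal_trace_ic.csv` under `dir`; when the
#' mesh and field solutions are supplied, also one `.vtu` per cell with the
#' potential and field arrays.
#'
#' @param report a `comparison_report`.
#' @param dir output directory (created if missing).
#' @param mesh,solutions optional mesh and named solution list for VTK
#'   export.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, mesh = NULL, solutions = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  if (!is.null(report$pairs))
    utils::write.csv(report$pairs, file.path(dir, "pairs.csv"),
                     row.names = FALSE)
  if (!is.null(report$aggregates))
    utils::write.csv(report$aggregates, file.path(dir, "aggregates.csv"),
                     row.names = FALSE)
  if (!is.null(report$thermal)) {
    utils::write.csv(report$thermal$trace_ac,
                     file.path(dir, "thermal_trace_ac.csv"), row.names = FALSE)
    utils::write.csv(report$thermal$trace_ic,
                     file.path(dir, "thermal_trace_ic.csv"), row.names = FALSE)
  }
  if (!is.null(mesh) && !is.null(solutions)) {
    for (key in names(solutions)) {
      sol <- solutions[[key]]
      fn <- file.path(dir, paste0("field_", gsub("[^A-Za-z0-9.=-]", "_", key),
                                  ".vtu"))
      write_vtu(mesh, fn, point_data = list(V = sol$V),
                cell_data = list(E = sol$E, E_mag = sol$e_mag, Q = sol$Q))
    }
  }
  invisible(dir)
}
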