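#' Working-heart workload sweep
#'
#' Runs the calibrated complete configuration to a cyclic steady state at a
#' series of mean workloads spanning the working-heart range, and summarises
#' oxygen uptake, CK fluxes and the PCr/ATP export partition at each.
#' Successive workloads are warm-started from the previous steady state.
#'
#' @param workloads mean ATPase rates, mmol/s/kg wm.
#' @param config a [system_config()].
#' @param params calibrated [kinetic_params()].
#' @param comp a [heart_composition()].
#' @param settings a [sim_settings()].
#' @param out_dir optional directory: writes `sweep.csv` and a JSON manifest.
#' @return list with the [sweep_summary()] (`$sweep`), the per-workload runs
#'   (`$runs`) and the manifest (`$manifest`).
#' @export
exp_williamson_sweep <- function(workloads = c(0.400, 0.678, 1.2, 1.9, 2.7, 3.52),
                                 config = config_preset("complete"),
                                 params = kinetic_params(),
                                 comp = heart_composition(),
                                 settings = sim_settings(),
                                 out_dir = NULL) {
  state <- initial_state(comp, config)
  runs <- vector("list", length(workloads))
  for (i in seq_along(workloads)) {
    runs[[i]] <- run_to_cyclic_steady_state(
      state, config, workload_protocol(workloads[i]), settings, params)
    state <- runs[[i]]$state
  }
  sweep <- sweep_summary(lapply(runs, `[[`, "summary"))
  sweep$table <- cbind(workload = workloads, sweep$table)
  manifest <- experiment_manifest("williamson_sweep", config, params, settings,
                                  list(workloads = workloads))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(sweep$table, file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "sweep_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(sweep = sweep, runs = runs, manifest = manifest)
}

#' Energy-export partition across system configurations
#'
#' Runs the four structural variants (no CK; free uncoupled CK without MOM
#' restriction; coupled MtCK without restriction; complete system) to a
#' cyclic steady state at one high workload and tabulates the PCr/ATP
#' partition of mitochondrial energy export.
#'
#' @param workload mean ATPase rate, mmol/s/kg wm.
#' @param presets preset names, in column order.
#' @param params calibrated [kinetic_params()].
#' @param comp a [heart_composition()].
#' @param settings a [sim_settings()].
#' @param out_dir optional output directory.
#' @return list with `table` (one row per configuration), `runs`, `manifest`.
#' @export
exp_config_compare <- function(workload = 2.25,
                               presets = c("no_ck", "uncoupled_free",
                                           "coupled_no_restriction",
                                           "complete"),
                               params = kinetic_params(),
                               comp = heart_composition(),
                               settings = sim_settings(),
                               out_dir = NULL) {
  runs <- lapply(presets, function(nm) {
    config <- config_preset(nm)
    st <- initial_state(comp, config)
    run_to_cyclic_steady_state(st, config, workload_protocol(workload),
                               settings, params)
  })
  names(runs) <- presets
  tab <- do.call(rbind, lapply(presets, function(nm) {
    s <- runs[[nm]]$summary
    data.frame(configuration = nm, pcr_fraction = s$pcr_fraction,
               atp_fraction = s$atp_fraction, vo2 = s$vo2,
               diastolic_pcr_cr = s$diastolic_pcr_cr)
  }))
  manifest <- experiment_manifest("config_compare", NULL, params, settings,
                                  list(workload = workload, presets = presets))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "config_compare.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(out_dir, "config_compare_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(table = tab, runs = runs, manifest = manifest)
}

#' Workload-transition table across configurations
#'
#' For each configuration, converges the system at the low workload, applies
#' the step to the medium workload at a cycle boundary, and reports the
#' fitted mitochondrial response time together with the diastolic PCr/Cr
#' ratios and PCr-export percentages before and after the transition.
#'
#' @param load_low,load_high the step, mmol/s/kg wm.
#' @param presets configurations, in row order.
#' @param params calibrated [kinetic_params()].
#' @param comp a [heart_composition()].
#' @param settings a [sim_settings()].
#' @param out_dir optional output directory.
#' @return list with `table`, `transitions`, `manifest`.
#' @export
exp_transition_table <- function(load_low = 0.400, load_high = 0.678,
                                 presets = c("complete", "system_A",
                                             "no_coupling_weak_mom",
                                             "reduced_pools"),
                                 params = kinetic_params(),
                                 comp = heart_composition(),
                                 settings = sim_settings(),
                                 out_dir = NULL) {
  transitions <- lapply(presets, function(nm) {
    config <- config_preset(nm)
    st <- initial_state(comp, config)
    low <- run_to_cyclic_steady_state(st, config, workload_protocol(load_low),
                                      settings, params)
    run_transition(low, load_high, settings, comp)
  })
  names(transitions) <- presets
  tab <- do.call(rbind, lapply(presets, function(nm) {
    tr <- transitions[[nm]]
    data.frame(configuration = nm, t_mito = tr$t_mito,
               pcr_cr_before = tr$before$diastolic_pcr_cr,
               pcr_cr_after = tr$after$diastolic_pcr_cr,
               pcr_export_before = tr$before$pcr_fraction,
               pcr_export_after = tr$after$pcr_fraction)
  }))
  manifest <- experiment_manifest("transition_table", NULL, params, settings,
                                  list(load_low = load_low,
                                       load_high = load_high,
                                       presets = presets))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "transition_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(out_dir, "transition_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(table = tab, transitions = transitions, manifest = manifest)
}

# Manifest sufficient to re-run an experiment bit-identically: all parameters
# plus a hash of the flattened numeric content.
experiment_manifest <- function(name, config, params, settings, extra) {
  payload <- list(experiment = name,
                  config = if (is.null(config)) NULL else unclass(config),
                  params = unclass(params),
                  settings = unclass(settings)[c("dt", "max_cycles",
                                                 "steady_tol", "record_stride",
                                                 "min_cycles")],
                  inputs = extra)
  vals <- unlist(payload, recursive = TRUE, use.names = FALSE)
  payload$parameter_hash <- sum(abs(as.numeric(vals[!is.na(suppressWarnings(as.numeric(vals)))])))
  payload$package_version <- as.character(utils::packageVersion("ckshuttle"))
  payload
}
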