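# Shared fixtures: moderate convergence tolerance keeps unit tests quick while
# staying far tighter than any assertion tolerance below.
fast_settings <- function(...) sim_settings(steady_tol = 1e-4, ...)
std_settings <- function(...) sim_settings(steady_tol = 1e-5, ...)

# One shared cache for expensive steady states so multiple test files can
# reuse the same converged runs.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, fun) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- fun()
  .run_cache[[key]]
}

steady_run <- function(preset, load, settings = std_settings(),
                       params = kinetic_params()) {
  key <- paste(preset, load, settings$steady_tol, sep = "_")
  cached_run(key, function() {
    config <- config_preset(preset)
    st <- initial_state(heart_composition(), config)
    run_to_cyclic_steady_state(st, config, workload_protocol(load),
                               settings, params)
  })
}

transition_run <- function(preset, load_low = 0.400, load_high = 0.678) {
  key <- paste("tr", preset, load_low, load_high, sep = "_")
  cached_run(key, function() {
    run_transition(steady_run(preset, load_low), load_high,
                   std_settings(), heart_composition())
  })
}
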