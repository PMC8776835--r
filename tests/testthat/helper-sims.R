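# Shared fixtures: simulations are expensive enough to cache per test run.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

default_enrichment_sim <- function() {
  cached("enrichment", simulate_enrichment(enrichment_scenario(noise_sd = 0)))
}

control_enrichment_sim <- function() {
  cached("control", simulate_enrichment(enrichment_scenario(
    n2o_init_ml = 0, n2o_injection_ml = 0, n0 = 0, w0 = 0,
    noise_sd = 0, t_end = 100)))
}

soil_sim <- function(nos = 1) {
  cached(paste0("soil_", nos),
         simulate_soil(soil_scenario(nos_capacity = nos, noise_sd = 0)))
}

# wide matrix view of a cumulative series
cum_wide <- function(cum) {
  sp <- unique(cum$species)
  tt <- unique(cum$time_h)
  matrix(cum$cumulative_umol, nrow = length(tt), ncol = length(sp),
         dimnames = list(NULL, sp))
}

rel_max <- function(a, b, floor = 1) max(abs(a - b) / pmax(abs(b), floor))
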