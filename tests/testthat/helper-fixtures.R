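# Deterministic parameter set: no noise, no threshold unless asked for.
quiet_params <- function(...) {
  actr_params(sigma = 0, tau = -Inf, ...)
}

# Small modified-variant sweep used by several tests.
small_modified_grid <- function(n_trials = 2000, seed = 42,
                                mapping = "decay_rate",
                                wmc_grid = c(0, 0.5, 1)) {
  pre <- actr_preset("modified", mapping)
  run_grid(simulation_config(n_trials = n_trials, wmc_grid = wmc_grid,
                             variant = "modified", mapping = pre$mapping,
                             base = pre$params, seed = seed))
}

# Tiny dataset for fast hierarchical fits.
small_spec <- function(seed = 1, n_participants = 12, n_items = 8,
                       effects = c("length" = 0.2), sigma = 0.4,
                       shift_range = c(100, 250)) {
  generator_spec(n_participants = n_participants, n_items = n_items,
                 effects = effects, sigma = sigma,
                 re_sd = list(participant = 0.1, item = 0.05,
                              sentence = 0.05),
                 shift_range = shift_range, seed = seed)
}

fast_fit <- function(records, ...) {
  suppressMessages(fit_shifted_lognormal(
    records, regions = "critical1",
    random = c("participant", "item"),
    chains = 2, iter = 250, warmup = 250, adapt = 150, ...))
}
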