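# Shared fixtures: built in code, deterministic.

# random non-negative state in canonical order
random_state <- function() {
  setNames(runif(length(model_species()), 0, 3), model_species())
}

# parameters with the circadian feedback disabled: the dark attractor is a
# true fixed point, which several stationarity checks rely on
clockless_params <- function() {
  model_parameters(kph = 0, kpf = 0, kin_frq = 0)
}

# small noise-free dataset on a short protocol; cheap enough for fitting
# tests (few time points, single strain possible via subset_dataset)
tiny_dataset <- function(noise_cv = 0, seed = 42,
                         params = default_parameters(),
                         strains = c("wt", "vvd_null")) {
  generate_timecourse(
    params, strains = strains,
    protocol = light_protocol(c(0, 120), c(2, 20)),
    sample_times = seq(0, 240, by = 30),
    noise_cv = noise_cv, n_replicates = if (noise_cv > 0) 3 else 1,
    seed = seed)
}
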