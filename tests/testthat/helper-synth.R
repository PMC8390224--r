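# Shared fixtures: a noise-free generator configuration for exactness tests
# and a small standard block schedule.

quiet_config <- function(...) {
  synth_config(amp_jitter_sd = 0, duration_jitter_sd = 0,
               angle_noise_sd = 0, moment_noise_sd = 0, grf_noise_sd = 0,
               misc_noise_sd = 0, pref_noise_sd = 0, breath_noise_sd = 0,
               tenmwt_noise_sd = 0, ...)
}

block_schedule <- function(devs = c(-30, 15, 0, 30, -15), first = TRUE)
  trial_schedule(block_durations(first), stiffness_rel = devs)

one_subject <- function(seed = 1, config = synth_config())
  gen_subjects(1, seed = seed, config = config)[[1]]
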