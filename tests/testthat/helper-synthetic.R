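# Shared fixture builders. Everything is generated in code under fixed seeds.

# trials x time matrix of temporally smoothed Gaussian noise (box filter,
# circular), the stand-in for ongoing band-power fluctuations
smooth_noise_trials <- function(n_trials, n_time = 900, sd1 = 1, width = 20) {
  m <- t(vapply(seq_len(n_trials), function(i) {
    as.numeric(stats::filter(rnorm(n_time), rep(1 / width, width),
                             sides = 2, circular = TRUE))
  }, numeric(n_time)))
  m * sd1
}

# band-power fixture: a task design plus planted effects on named sites
make_bp_fixture <- function(n_sites = 8, images = 10, effects = list(),
                            seed = 1, noise_sd_db = 1) {
  design <- make_task_design(images, 2, seed = seed)
  layout <- make_electrode_layout(n_sites, seed = seed)
  simulate_band_power(design, layout, effects, seed = seed,
                      noise_sd_db = noise_sd_db)
}

# linear 0..1 ramp starting at t0_ms, full after rise_ms
ramp_shape <- function(times, t0_ms, rise_ms = 100) {
  pmin(pmax((times - t0_ms) / rise_ms, 0), 1)
}

EPOCH_TIMES <- -200:699
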