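# Shared fixtures, all built in code.

# A calibration fitted on a perfect session (actuals equal targets): the
# composed matrices are numerically the identity.
identity_calibration <- function() {
  layout <- target_layout()
  session <- data.frame(
    name = layout$name,
    target_u = layout$u, target_v = layout$v,
    actual_u = layout$u, actual_v = layout$v
  )
  calibrate_all(session, layout, normalizers = default_normalizers())
}

# Noise-free simulation config, optionally with a known distortion.
quiet_sim_config <- function(seed = 1L, distortions = NULL, repeats = 1L,
                             pixel_noise_sd = 0) {
  simulation_config(noise_sd = 0, pixel_noise_sd = pixel_noise_sd,
                    distortions = distortions, repeats = repeats, seed = seed)
}

# Steady-state amplitude of a filtered sinusoid (skips the transient).
steady_amplitude <- function(x, skip_frac = 0.5) {
  tail_part <- x[seq.int(floor(length(x) * skip_frac), length(x))]
  (max(tail_part) - min(tail_part)) / 2
}

random_geometry_params <- function() {
  geometry_params(
    tx = stats::runif(1, -500, 500), ty = stats::runif(1, -500, 500),
    theta = stats::runif(1, -pi / 2, pi / 2),
    m1 = stats::runif(1, -0.5, 0.5), m2 = stats::runif(1, -0.5, 0.5),
    s1 = stats::runif(1, 0.3, 2), s2 = stats::runif(1, 0.3, 2)
  )
}
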