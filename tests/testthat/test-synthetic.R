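test_that("synthetic pulses encode the requested normalized integral", {
  cfg <- quiet_sim_config(seed = 1)
  g <- cfg$gains
  fs <- cfg$sample_rate

  # generator/extractor round trip within 1% for several distances/directions
  cases <- list(c(1L, 180), c(1L, 360), c(1L, -180), c(2L, 255), c(2L, -510))
  for (cs in cases) {
    ch <- cs[[1]]
    d <- cs[[2]]
    pulse <- synthesize_pulse(d, ch, cfg)
    dirn <- if (ch == 1L) (if (d > 0) "up" else "down") else (if (d > 0) "right" else "left")
    expected_norm <- (d - g[[dirn]]["B"]) / g[[dirn]]["A"]
    seg <- segment_wave(pulse, cfg$thresholds, fs, cfg$hold_ms)
    got <- integrate_wave(pulse, seg, fs) /
      cfg$normalizers[[paste0("ch", ch)]][[dirn]]
    expect_lt(abs(got - expected_norm) / expected_norm, 0.01)
  }

  # norm_int = 0.5 specifically: the integral recovers half the normalizer
  d_half <- unname(0.5 * g$up["A"] + g$up["B"])  # 150 px
  pulse <- synthesize_pulse(d_half, 1L, cfg)
  seg <- segment_wave(pulse, cfg$thresholds, fs, cfg$hold_ms)
  expect_lt(abs(integrate_wave(pulse, seg, fs) - 0.5 * cfg$normalizers$ch1$up) /
              (0.5 * cfg$normalizers$ch1$up), 0.01)

  # monotone: larger distance, larger integral (fixed direction)
  ints <- vapply(c(120, 240, 360, 480), function(d) {
    p <- synthesize_pulse(d, 1L, cfg)
    integrate_wave(p, segment_wave(p, cfg$thresholds, fs, cfg$hold_ms), fs)
  }, 0)
  expect_true(all(diff(ints) > 0))

  # out of the linear range
  expect_error(synthesize_pulse(2000, 2L, cfg), class = "eogaze_out_of_range")
  expect_error(synthesize_pulse(0, 1L, cfg), class = "eogaze_invalid_input")
})

test_that("pulse polarities reproduce the quadrant table", {
  cfg <- quiet_sim_config(seed = 1)
  fs <- cfg$sample_rate
  pol <- function(d, ch) detect_polarity(synthesize_pulse(d, ch, cfg), cfg$thresholds)
  expect_identical(pol(180, 1L), "-")   # up
  expect_identical(pol(-180, 1L), "+")  # down
  expect_identical(pol(255, 2L), "-")   # right
  expect_identical(pol(-255, 2L), "+")  # left
  # the polarity pair of each quadrant's motion classifies back to it
  expect_identical(classify_area(pol(180, 1L), pol(255, 2L)), 1L)   # up-right
  expect_identical(classify_area(pol(-180, 1L), pol(255, 2L)), 2L)  # down-right
  expect_identical(classify_area(pol(-180, 1L), pol(-255, 2L)), 3L) # down-left
  expect_identical(classify_area(pol(180, 1L), pol(-255, 2L)), 4L)  # up-left
})

test_that("trace generation is labeled, schedule-checked and deterministic", {
  cfg <- simulation_config(seed = 5, repeats = 1)
  ev <- data.frame(u = c(255, -510), v = c(180, -360), onset = c(0.2, 1.0))
  g1 <- generate_eog_trace(ev, cfg)
  expect_identical(g1$labels$area, c(1L, 3L))

  # fixed seed: bit-identical on rerun
  g2 <- generate_eog_trace(ev, cfg)
  expect_identical(g1$trace$ch1, g2$trace$ch1)
  expect_identical(g1$trace$ch2, g2$trace$ch2)

  # overlapping schedule rejected
  bad <- data.frame(u = c(255, 255), v = c(180, 180), onset = c(0.2, 0.3))
  expect_error(generate_eog_trace(bad, cfg), class = "eogaze_invalid_schedule")

  # noise-only trace contains no events
  quiet <- generate_eog_trace(ev[0, ], cfg)
  expect_identical(nrow(detect_events(quiet$trace, cfg$thresholds)), 0L)

  # zero-noise single event: the feature pipeline recovers quadrant and pixel
  cfg0 <- quiet_sim_config(seed = 6)
  one <- generate_eog_trace(data.frame(u = 510, v = -360, onset = 0.2), cfg0)
  est <- estimate_actual_pixels(one$trace, cfg0$thresholds, cfg0$gains,
                                cfg0$normalizers)
  expect_identical(nrow(est), 1L)
  expect_identical(est$area, 2L)
  expect_lt(abs(est$actual_u - 510), 1)
  expect_lt(abs(est$actual_v + 360), 1)
})

test_that("training sessions invert the configured distortion", {
  # identity distortion, zero scatter: actuals equal targets
  cfg <- quiet_sim_config(seed = 2)
  ses <- generate_training_session(cfg)
  expect_equal(ses$actual_u, ses$target_u, tolerance = 1e-9)
  expect_equal(ses$actual_v, ses$target_v, tolerance = 1e-9)
  expect_identical(nrow(ses), 24L)

  # known distortion, zero scatter: calibrate_all reproduces every target
  cfg2 <- quiet_sim_config(seed = 3, distortions = default_distortions(3))
  ses2 <- generate_training_session(cfg2)
  cal <- calibrate_all(ses2)
  corr <- correct_pixels(cal, cbind(ses2$actual_u, ses2$actual_v), areas = ses2$area)
  expect_lt(max(sqrt(rowSums((corr - cbind(ses2$target_u, ses2$target_v))^2))), 0.5)

  # singular distortion rejected up front
  expect_error(
    simulation_config(distortions = replicate(4, geometry_params(s1 = 1e-12),
                                              simplify = FALSE)),
    class = "eogaze_invalid_config"
  )
})

test_that("calibration error shrinks as pixel scatter shrinks", {
  mean_err_at <- function(sd) {
    errs <- vapply(1:20, function(seed) {
      cfg <- simulation_config(distortions = default_distortions(seed),
                               pixel_noise_sd = sd, repeats = 3, seed = 500 + seed)
      ses <- generate_training_session(cfg)
      cal <- calibrate_all(ses)
      corr <- correct_pixels(cal, cbind(ses$actual_u, ses$actual_v), areas = ses$area)
      mean(sqrt(rowSums((corr - cbind(ses$target_u, ses$target_v))^2)))
    }, 0)
    mean(errs)
  }
  e1 <- mean_err_at(1)
  e4 <- mean_err_at(4)
  expect_lt(e1, e4)
})
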