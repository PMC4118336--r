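#' Default integral normalizers for the synthetic generator
#'
#' Per-channel, per-direction full-wave integral maxima (microvolt-seconds)
#' used to scale integrals into `[0, 1]`. In a live calibration these are
#' the largest integrals observed per direction during training; the
#' synthetic generator fixes them up front and writes them into the session
#' metadata so the extractor need not re-estimate them.
#'
#' @return A list `ch1 = list(up, down)`, `ch2 = list(right, left)`.
#' @export
default_normalizers <- function() {
  list(ch1 = list(up = 40, down = 40), ch2 = list(right = 40, left = 40))
}

#' Synthetic EOG simulation configuration
#'
#' Bundles everything the ground-truth generator needs: sampling, waveform
#' shape, noise levels, detection thresholds, the linear gain table, integral
#' normalizers, an optional per-area "true" distortion and the RNG seed. The
#' defaults describe a plausible recording: 1 kHz sampling, 150 ms saccade
#' lobes with a 1:0.5 biphasic amplitude ratio, a 2 uV noise floor against
#' +/-25 uV thresholds (so a resting channel stays inside the band, six
#' standard deviations clear of it) and 2 px of isotropic gaze scatter for
#' pixel-level sessions.
#'
#' @param sample_rate Sampling rate in Hz (> 120).
#' @param lobe_duration Duration of each half-sine lobe in seconds.
#' @param lobe_ratio Amplitude of the second lobe relative to the first.
#' @param noise_sd Additive white Gaussian noise, uV (trace-level).
#' @param pixel_noise_sd Isotropic actual-pixel scatter, px (session-level).
#' @param thresholds An [eog_thresholds()].
#' @param gains A [gain_table()].
#' @param normalizers Integral normalizers, see [default_normalizers()].
#' @param distortions `NULL` (identity) or a list of four
#'   [geometry_params()], the per-area true distortion.
#' @param repeats Gazes per training target.
#' @param event_gap Seconds between consecutive event onsets.
#' @param hold_ms Quiet hold time consistent with the analysis settings.
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(sample_rate = 1000, lobe_duration = 0.15,
                              lobe_ratio = 0.5, noise_sd = 2,
                              pixel_noise_sd = 2,
                              thresholds = eog_thresholds(25, -25),
                              gains = gain_table(),
                              normalizers = default_normalizers(),
                              distortions = NULL, repeats = 5,
                              event_gap = 0.6, hold_ms = 50, seed = 1L) {
  check_thresholds(thresholds)
  if (sample_rate <= 120) stop_invalid_config("sample_rate must exceed 120 Hz")
  if (lobe_duration <= 0 || lobe_ratio <= 0) {
    stop_invalid_config("lobe duration and ratio must be positive")
  }
  if (noise_sd < 0 || pixel_noise_sd < 0) stop_invalid_config("noise sds must be >= 0")
  band <- min(thresholds$positive, -thresholds$negative)
  if (6 * noise_sd >= band) {
    stop_invalid_config("noise sd too large: 6*sd must stay below the threshold band")
  }
  if (!is.null(distortions)) {
    if (length(distortions) != 4L ||
        !all(vapply(distortions, inherits, TRUE, "geometry_params"))) {
      stop_invalid_config("`distortions` must be a list of four geometry_params")
    }
    for (d in distortions) {
      if (abs(det(compose_homogeneous(d)[1:2, 1:2])) < 1e-9) {
        stop_invalid_config("a per-area distortion is singular")
      }
    }
  }
  if (event_gap < 2 * lobe_duration + 2 * hold_ms / 1000) {
    stop_invalid_config("event_gap too small: events would overlap")
  }
  structure(
    list(sample_rate = sample_rate, lobe_duration = lobe_duration,
         lobe_ratio = lobe_ratio, noise_sd = noise_sd,
         pixel_noise_sd = pixel_noise_sd, thresholds = thresholds,
         gains = gains, normalizers = normalizers, distortions = distortions,
         repeats = as.integer(repeats), event_gap = event_gap,
         hold_ms = hold_ms, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Analytic supra-threshold integral of the biphasic pulse: two half-sine
# lobes of duration T, amplitudes A and r*A with opposite signs. Each lobe
# contributes (2 A T / pi) * sqrt(1 - (th/A)^2) above its threshold.
pulse_integral_analytic <- function(A, th1, th2, T, r) {
  lobe <- function(amp, th) {
    if (amp <= th) 0 else (2 * T / pi) * sqrt(amp^2 - th^2)
  }
  lobe(A, th1) + lobe(r * A, th2)
}

# Invert the analytic integral for the first-lobe amplitude (monotone in A).
pulse_amplitude_for_integral <- function(I, th1, th2, T, r) {
  lo <- th1 * (1 + 1e-12)
  hi <- th1 * 2
  while (pulse_integral_analytic(hi, th1, th2, T, r) < I) hi <- hi * 2
  stats::uniroot(function(A) pulse_integral_analytic(A, th1, th2, T, r) - I,
                 c(lo, hi), tol = 1e-12)$root
}

channel_direction_for_distance <- function(channel, distance) {
  if (channel == 1L) {
    if (distance > 0) "up" else "down"
  } else {
    if (distance > 0) "right" else "left"
  }
}

#' Synthesize one EOG saccade pulse
#'
#' Emits a noiseless biphasic wave (two opposite-sign half-sine lobes) on
#' the requested channel whose polarity matches the quadrant table for the
#' implied direction and whose full-wave integral, after normalization,
#' equals the normalized integral that the linear gain model assigns to
#' `distance_px`. The first-lobe amplitude is solved from the analytic
#' supra-threshold integral of the waveform.
#'
#' @param distance_px Signed pixel displacement (v pixels for channel 1, u
#'   pixels for channel 2); must be non-zero and within the linear range of
#'   the direction's gains.
#' @param channel 1 (vertical) or 2 (horizontal).
#' @param cfg A [simulation_config()].
#' @return Numeric vector of samples in microvolts (two lobes of
#'   `lobe_duration` each at `sample_rate`).
#' @export
synthesize_pulse <- function(distance_px, channel, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  channel <- as.integer(channel)
  if (!channel %in% 1:2) stop_invalid_input("`channel` must be 1 or 2")
  if (distance_px == 0) {
    stop_invalid_input("a zero distance produces no wave on this channel")
  }
  direction <- channel_direction_for_distance(channel, distance_px)
  g <- cfg$gains[[direction]]
  norm <- (distance_px - g["B"]) / g["A"]
  if (norm <= 0 || norm > 1) {
    stop_runtime(
      sprintf("distance %.1f px (direction %s) needs a normalized integral of %.3f, outside (0, 1]",
              distance_px, direction, norm),
      "eogaze_out_of_range"
    )
  }
  normalizer <- cfg$normalizers[[paste0("ch", channel)]][[direction]]
  I <- unname(norm) * normalizer
  polarity <- direction_polarity(channel, direction)
  th <- cfg$thresholds
  th1 <- if (polarity == "+") th$positive else -th$negative
  th2 <- if (polarity == "+") -th$negative else th$positive
  A <- pulse_amplitude_for_integral(I, th1, th2, cfg$lobe_duration, cfg$lobe_ratio)

  n <- as.integer(round(cfg$lobe_duration * cfg$sample_rate))
  tt <- (seq_len(n) - 1) / cfg$sample_rate
  lobe <- sin(pi * tt / cfg$lobe_duration)
  sgn <- if (polarity == "+") 1 else -1
  sgn * c(A * lobe, -cfg$lobe_ratio * A * lobe)
}

#' Generate a labeled synthetic EOG trace
#'
#' Builds a two-channel trace containing one biphasic pulse pair per gaze
#' event plus additive white Gaussian noise. Each event encodes a gaze from
#' the screen center to `(u, v)`: channel 1 carries the vertical component,
#' channel 2 the horizontal one; a zero component leaves its channel at rest.
#'
#' @param events Data frame with columns `u`, `v` (signed pixels) and
#'   `onset` (seconds); onsets must be at least `2 * lobe_duration + 2 *
#'   hold_ms/1000` apart.
#' @param cfg A [simulation_config()]; `cfg$seed` fixes the noise.
#' @return A list with `trace` (an [eog_trace()]) and `labels` (a data frame
#'   with per-event ground truth: `onset`, `u`, `v`, `area` and the expected
#'   normalized integrals `norm_ch1`, `norm_ch2`).
#' @export
generate_eog_trace <- function(events, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!all(c("u", "v", "onset") %in% names(events))) {
    stop_invalid_input("`events` must have columns u, v, onset")
  }
  events <- events[order(events$onset), , drop = FALSE]
  min_gap <- 2 * cfg$lobe_duration + 2 * cfg$hold_ms / 1000
  if (nrow(events) > 1L && any(diff(events$onset) < min_gap)) {
    abort_eogaze("events overlap given the pulse duration and hold time",
                 "eogaze_invalid_schedule")
  }
  fs <- cfg$sample_rate
  duration <- (if (nrow(events) > 0L) max(events$onset) else 0) +
    2 * cfg$lobe_duration + 0.3
  n <- as.integer(ceiling(duration * fs)) + 1L
  set.seed(cfg$seed)
  ch1 <- stats::rnorm(n, 0, cfg$noise_sd)
  ch2 <- stats::rnorm(n, 0, cfg$noise_sd)

  norm_of <- function(d, channel) {
    if (d == 0) return(0)
    g <- cfg$gains[[channel_direction_for_distance(channel, d)]]
    unname((d - g["B"]) / g["A"])
  }

  labels <- events
  labels$area <- area_for_point(events$u, events$v)
  labels$norm_ch1 <- vapply(events$v, norm_of, 0, channel = 1L)
  labels$norm_ch2 <- vapply(events$u, norm_of, 0, channel = 2L)

  for (i in seq_len(nrow(events))) {
    i0 <- as.integer(round(events$onset[i] * fs)) + 1L
    if (events$v[i] != 0) {
      p <- synthesize_pulse(events$v[i], 1L, cfg)
      idx <- i0:(i0 + length(p) - 1L)
      ch1[idx] <- ch1[idx] + p
    }
    if (events$u[i] != 0) {
      p <- synthesize_pulse(events$u[i], 2L, cfg)
      idx <- i0:(i0 + length(p) - 1L)
      ch2[idx] <- ch2[idx] + p
    }
  }
  time <- (seq_len(n) - 1) / fs
  list(trace = eog_trace(time, ch1, ch2, sample_rate = fs), labels = labels)
}

#' Construct a recoverable per-quadrant distortion
#'
#' Builds "true" [geometry_params()] for one area from a rotation angle,
#' two dilatation factors and a single shear coefficient, arranged so that
#' the staged calibration fit ([fit_area_calibration()]) recovers the
#' transform exactly from noise-free data. Within the factored family this
#' requires (a) the shear component acting along the area's reference axis
#' to vanish (`m1 = 0` for Areas 1/3, `m2 = 0` for Areas 2/4 - the free
#' coefficient is the one the reference-line construction can absorb), and
#' (b) the rotation pivot to sit where the fit will place it: at the image
#' of the area's near anchor target under the inverse dilatation-shear,
#' which lies on the target axis.
#'
#' @param area Area 1..4.
#' @param theta_deg Rotation angle in degrees.
#' @param s1,s2 Dilatation factors (> 0).
#' @param shear The free shear coefficient of this area.
#' @param layout Target layout supplying the anchor targets.
#' @return A [geometry_params()] describing the forward (actual-to-target)
#'   transform.
#' @export
area_distortion <- function(area, theta_deg, s1, s2, shear = 0,
                            layout = target_layout()) {
  if (!area %in% 1:4) stop_invalid_input("`area` must be 1..4")
  m1 <- if (area %in% c(1L, 3L)) 0 else shear
  m2 <- if (area %in% c(1L, 3L)) shear else 0
  DSh <- (dilatation_matrix(s1, s2) %*% shear_matrix(m1, m2))[1:2, 1:2]
  anchor <- area_anchor_targets(layout, area)[1L, ]
  pivot <- solve(DSh, c(anchor$u, anchor$v))
  geometry_params(tx = -pivot[1L], ty = -pivot[2L], theta = deg2rad(theta_deg),
                  m1 = m1, m2 = m2, s1 = s1, s2 = s2)
}

#' Draw a default set of per-area distortions
#'
#' One [area_distortion()] per quadrant with rotation angles uniform in the
#' empirically observed 13.7-47.7 degree band, dilatation factors uniform in
#' `[0.6, 0.95]` (actual gaze excursions overshoot the targets) and shear
#' coefficients uniform in `[-0.15, 0.15]`.
#'
#' @param seed Integer seed.
#' @param layout Target layout.
#' @return A list of four [geometry_params()].
#' @export
default_distortions <- function(seed = 1L, layout = target_layout()) {
  set.seed(seed)
  lapply(1:4, function(a) {
    area_distortion(a,
                    theta_deg = stats::runif(1, 13.7, 47.7),
                    s1 = stats::runif(1, 0.6, 0.95),
                    s2 = stats::runif(1, 0.6, 0.95),
                    shear = stats::runif(1, -0.15, 0.15),
                    layout = layout)
  })
}

#' Generate a pixel-level training session
#'
#' Produces the (actual, target) pixel pairs a calibration session yields:
#' each target is hit `repeats` times at the image of the target under the
#' inverse of its area's true distortion, plus isotropic Gaussian pixel
#' scatter. With identity distortion and zero scatter the actuals equal the
#' targets.
#'
#' @param cfg A [simulation_config()]; `cfg$distortions` is the truth,
#'   `cfg$pixel_noise_sd` the scatter, `cfg$seed` the seed.
#' @param layout Target layout.
#' @return A data frame with columns `name`, `area`, `rep`, `target_u`,
#'   `target_v`, `actual_u`, `actual_v`, suitable for [calibrate_all()].
#' @export
generate_training_session <- function(cfg, layout = target_layout()) {
  stopifnot(inherits(cfg, "simulation_config"))
  inv <- lapply(1:4, function(a) {
    if (is.null(cfg$distortions)) diag(3) else {
      M <- compose_homogeneous(cfg$distortions[[a]])
      solve(M)
    }
  })
  set.seed(cfg$seed)
  out <- lapply(seq_len(nrow(layout)), function(i) {
    M <- inv[[layout$area[i]]]
    base <- apply_transform(M, c(layout$u[i], layout$v[i]))
    reps <- lapply(seq_len(cfg$repeats), function(r) {
      noisy <- base + stats::rnorm(2, 0, cfg$pixel_noise_sd)
      data.frame(name = layout$name[i], area = layout$area[i], rep = r,
                 target_u = layout$u[i], target_v = layout$v[i],
                 actual_u = noisy[1L], actual_v = noisy[2L])
    })
    do.call(rbind, reps)
  })
  do.call(rbind, out)
}

#' Generate a full synthetic session as an EOG trace
#'
#' Schedules one gaze event per training target (times `repeats`) and
#' renders them as a two-channel EOG trace. When a per-area distortion is
#' configured, the trace encodes the distorted gaze position (the "actual"
#' pixel) for each target, emulating an operator whose raw gaze estimates
#' are systematically off.
#'
#' @param cfg A [simulation_config()].
#' @param layout Target layout.
#' @return A list with `trace`, `labels` (per-event: target pixel, encoded
#'   actual pixel, area) and `ground_truth` (alias of `labels`).
#' @export
generate_session_trace <- function(cfg, layout = target_layout()) {
  stopifnot(inherits(cfg, "simulation_config"))
  inv <- lapply(1:4, function(a) {
    if (is.null(cfg$distortions)) diag(3) else solve(compose_homogeneous(cfg$distortions[[a]]))
  })
  reps <- rep(seq_len(cfg$repeats), each = nrow(layout))
  idx <- rep(seq_len(nrow(layout)), times = cfg$repeats)
  actual <- t(vapply(idx, function(i) {
    apply_transform(inv[[layout$area[i]]], c(layout$u[i], layout$v[i]))
  }, numeric(2)))
  events <- data.frame(
    u = actual[, 1L], v = actual[, 2L],
    onset = 0.2 + (seq_along(idx) - 1) * cfg$event_gap
  )
  gen <- generate_eog_trace(events, cfg)
  gen$labels$name <- layout$name[idx]
  gen$labels$rep <- reps
  gen$labels$target_u <- layout$u[idx]
  gen$labels$target_v <- layout$v[idx]
  gen$labels$area <- layout$area[idx]
  gen$ground_truth <- gen$labels
  gen
}

#' Write ground-truth labels to a sidecar file
#'
#' @param labels The `labels` element of [generate_eog_trace()] or
#'   [generate_session_trace()].
#' @param path File path (CSV).
#' @export
write_ground_truth <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
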