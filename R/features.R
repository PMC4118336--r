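#' Detection thresholds
#'
#' A pair of amplitude thresholds bracketing the resting EOG baseline.
#' Samples inside `[negative, positive]` are read as "eyes at rest"; the first
#' excursion outside the band defines the wave's polarity. Magnitudes are
#' operator- and setup-specific configuration (they must clear the noise
#' floor), so no physiological default is imposed here; the synthetic
#' generator documents thresholds consistent with its noise model.
#'
#' @param positive Positive threshold in microvolts (> 0).
#' @param negative Negative threshold in microvolts (< 0).
#' @return An object of class `eog_thresholds`.
#' @export
eog_thresholds <- function(positive, negative) {
  positive <- check_number(positive, "positive")
  negative <- check_number(negative, "negative")
  if (!(negative < 0 && 0 < positive)) {
    stop_invalid_config("thresholds must satisfy negative < 0 < positive")
  }
  structure(list(positive = positive, negative = negative), class = "eog_thresholds")
}

check_thresholds <- function(th) {
  if (!inherits(th, "eog_thresholds")) {
    stop_invalid_config("`thresholds` must be created with eog_thresholds()")
  }
  th
}

#' Polarity of an EOG wave
#'
#' The polarity is decided by which threshold the signal crosses first:
#' `"+"` if the earliest out-of-band sample exceeds the positive threshold,
#' `"-"` if it falls below the negative one, `"rest"` if the signal never
#' leaves the band.
#'
#' @param samples Numeric vector of EOG samples in microvolts.
#' @param thresholds An [eog_thresholds()].
#' @return One of `"+"`, `"-"`, `"rest"`.
#' @export
detect_polarity <- function(samples, thresholds) {
  check_thresholds(thresholds)
  if (length(samples) == 0L) stop_invalid_input("`samples` is empty")
  out <- which(samples > thresholds$positive | samples < thresholds$negative)
  if (length(out) == 0L) return("rest")
  if (samples[out[1L]] > thresholds$positive) "+" else "-"
}

#' Screen quadrant from the channel polarity pair
#'
#' The (Ch1, Ch2) polarity pair assigns a gaze motion to one of four screen
#' quadrants ("areas"): `(-,-)` is Area 1 (upper right), `(+,-)` Area 2
#' (lower right), `(+,+)` Area 3 (lower left) and `(-,+)` Area 4 (upper
#' left). Any `"rest"` polarity means no quadrant can be assigned.
#'
#' @param pol_ch1,pol_ch2 Polarities (`"+"`, `"-"`, `"rest"`) of the vertical
#'   and horizontal channels.
#' @return Integer area 1..4, or `NA_integer_` when either channel is at rest.
#' @export
classify_area <- function(pol_ch1, pol_ch2) {
  valid <- c("+", "-", "rest")
  if (!pol_ch1 %in% valid || !pol_ch2 %in% valid) {
    stop_invalid_input("polarities must be one of '+', '-', 'rest'")
  }
  if (pol_ch1 == "rest" || pol_ch2 == "rest") return(NA_integer_)
  key <- paste(pol_ch1, pol_ch2)
  switch(key,
    "- -" = 1L,
    "+ -" = 2L,
    "+ +" = 3L,
    "- +" = 4L
  )
}

# Per-channel gaze direction implied by an area, consistent with the
# polarity table: ch1 '-' <-> up, '+' <-> down; ch2 '-' <-> right, '+' <-> left.
channel_directions <- function(area) {
  if (is.na(area)) return(list(ch1 = NA_character_, ch2 = NA_character_))
  list(
    ch1 = if (area %in% c(1L, 4L)) "up" else "down",
    ch2 = if (area %in% c(1L, 2L)) "right" else "left"
  )
}

direction_polarity <- function(channel, direction) {
  if (channel == 1L) {
    switch(direction, up = "-", down = "+",
           stop_invalid_input("ch1 direction must be 'up' or 'down'"))
  } else {
    switch(direction, right = "-", left = "+",
           stop_invalid_input("ch2 direction must be 'right' or 'left'"))
  }
}

#' Segment a full EOG wave
#'
#' Locates the biphasic wave triggered by the first threshold crossing: the
#' segment starts at the zero crossing immediately preceding that crossing
#' and ends once the signal has re-entered the threshold band and stayed
#' there for `hold_ms` milliseconds (rejecting the brief in-band passage
#' between the two lobes). If no sample leaves the band a rest segment
#' covering nothing is returned.
#'
#' @param samples Numeric vector of EOG samples in microvolts.
#' @param thresholds An [eog_thresholds()].
#' @param sample_rate Sampling rate in Hz.
#' @param hold_ms Quiet time (ms) the signal must spend inside the band for
#'   the wave to be considered finished.
#' @return An object of class `wave_segment`: list with `start`, `end`
#'   (sample indices, `NA` for a rest segment), `polarity`, `crossed` and the
#'   thresholds used.
#' @export
segment_wave <- function(samples, thresholds, sample_rate, hold_ms = 50) {
  check_thresholds(thresholds)
  sample_rate <- check_number(sample_rate, "sample_rate")
  n <- length(samples)
  if (n == 0L) stop_invalid_input("`samples` is empty")
  outside <- samples > thresholds$positive | samples < thresholds$negative
  seg <- list(start = NA_integer_, end = NA_integer_, polarity = "rest",
              crossed = FALSE, thresholds = thresholds, hold_ms = hold_ms)
  class(seg) <- "wave_segment"
  if (!any(outside)) return(seg)

  i1 <- which(outside)[1L]
  pol <- if (samples[i1] > thresholds$positive) "+" else "-"

  # Backward to the zero crossing preceding the first threshold crossing:
  # start of the run of samples sharing the first lobe's sign.
  s <- sign(samples[i1])
  start <- i1
  while (start > 1L && sign(samples[start - 1L]) == s && samples[start - 1L] != 0) {
    start <- start - 1L
  }

  # Forward: wave ends at the first in-band run of at least hold_n samples
  # (or the end of the record).
  hold_n <- max(1L, as.integer(round(hold_ms / 1000 * sample_rate)))
  inband <- !outside
  end <- n
  j <- i1 + 1L
  while (j <= n) {
    if (inband[j]) {
      k <- j
      while (k < n && inband[k + 1L]) k <- k + 1L
      if ((k - j + 1L) >= hold_n || k == n) {
        end <- j
        break
      }
      j <- k + 1L
    } else {
      j <- j + 1L
    }
  }

  seg$start <- start
  seg$end <- end
  seg$polarity <- pol
  seg$crossed <- TRUE
  seg
}

# Trapezoidal integral of x over the region {x > th} within indices
# [from, to], with linearly interpolated sub-sample crossing endpoints (the
# integrand equals th at a crossing). Assumes a uniform grid of step dt.
integrate_above <- function(x, th, from, to, dt) {
  idx <- from:to
  xs <- x[idx]
  mask <- xs > th
  if (!any(mask)) return(0)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  total <- 0
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i <- starts[k]
    j <- ends[k]
    if (j > i) {
      total <- total + sum((xs[i:(j - 1L)] + xs[(i + 1L):j]) / 2) * dt
    }
    if (i > 1L) { # entry crossing between i-1 and i
      f <- (th - xs[i - 1L]) / (xs[i] - xs[i - 1L])
      total <- total + (th + xs[i]) / 2 * (1 - f) * dt
    }
    if (j < length(xs)) { # exit crossing between j and j+1
      f <- (th - xs[j]) / (xs[j + 1L] - xs[j])
      total <- total + (xs[j] + th) / 2 * f * dt
    }
  }
  total
}

#' Full-wave integral of an EOG wave
#'
#' Computes the sum of the absolute areas of the wave's supra-threshold
#' lobes, `|integral over {x > th+}| + |integral over {x < th-}|`, by
#' trapezoidal quadrature over the segment. Crossing points are located by
#' linear interpolation between samples so the quadrature error at the lobe
#' edges is second order in the sampling step. The result is non-negative and
#' invariant under a global sign flip of the signal when the thresholds are
#' symmetric.
#'
#' @param samples Numeric vector of EOG samples in microvolts.
#' @param segment A [segment_wave()] result.
#' @param sample_rate Sampling rate in Hz.
#' @return Integral in microvolt-seconds (>= 0); 0 for a rest segment.
#' @export
integrate_wave <- function(samples, segment, sample_rate) {
  if (!inherits(segment, "wave_segment")) {
    stop_invalid_input("`segment` must come from segment_wave()")
  }
  if (!segment$crossed) return(0)
  sample_rate <- check_number(sample_rate, "sample_rate")
  if (segment$start < 1L || segment$end > length(samples)) {
    stop_invalid_input("segment lies outside the sample sequence")
  }
  dt <- 1 / sample_rate
  th <- segment$thresholds
  pos <- integrate_above(samples, th$positive, segment$start, segment$end, dt)
  neg <- integrate_above(-samples, -th$negative, segment$start, segment$end, dt)
  abs(pos) + abs(neg)
}

#' Normalize a wave integral
#'
#' Scales a full-wave integral by the calibration maximum for its channel and
#' direction so that the feature lives in `[0, 1]` (values beyond the
#' calibrated maximum clamp to 1).
#'
#' @param value Integral in microvolt-seconds (>= 0).
#' @param calibration_max Maximum integral observed during calibration for
#'   the same channel and direction (> 0).
#' @return Dimensionless value in `[0, 1]`.
#' @export
normalize_integral <- function(value, calibration_max) {
  calibration_max <- check_number(calibration_max, "calibration_max")
  if (calibration_max <= 0) stop_invalid_config("`calibration_max` must be positive")
  pmin(pmax(value, 0) / calibration_max, 1)
}

#' Locate gaze events in a two-channel trace
#'
#' An event is a maximal stretch where either channel sits outside the
#' threshold band; in-band gaps shorter than `hold_ms` are bridged so that a
#' biphasic wave counts as one event. Returned windows are padded by the hold
#' time so that [segment_wave()] can find the flanking zero crossings.
#'
#' @param trace An [eog_trace()] (typically already low-pass filtered).
#' @param thresholds An [eog_thresholds()].
#' @param hold_ms Quiet time in milliseconds separating events.
#' @return A data frame with one row per event: `start`, `end` (sample
#'   indices of the padded window) and `onset` (seconds of the first
#'   out-of-band sample).
#' @export
detect_events <- function(trace, thresholds, hold_ms = 50) {
  stopifnot(inherits(trace, "eog_trace"))
  check_thresholds(thresholds)
  active <- trace$ch1 > thresholds$positive | trace$ch1 < thresholds$negative |
    trace$ch2 > thresholds$positive | trace$ch2 < thresholds$negative
  n <- length(active)
  empty <- data.frame(start = integer(), end = integer(), onset = numeric())
  if (!any(active)) return(empty)
  hold_n <- max(1L, as.integer(round(hold_ms / 1000 * trace$sample_rate)))
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  act <- which(r$values)
  # Merge active runs separated by quiet gaps shorter than hold_n.
  ev_start <- integer()
  ev_end <- integer()
  cur_s <- NA_integer_
  cur_e <- NA_integer_
  for (k in act) {
    if (is.na(cur_s)) {
      cur_s <- starts[k]
      cur_e <- ends[k]
    } else if (starts[k] - cur_e - 1L < hold_n) {
      cur_e <- ends[k]
    } else {
      ev_start <- c(ev_start, cur_s)
      ev_end <- c(ev_end, cur_e)
      cur_s <- starts[k]
      cur_e <- ends[k]
    }
  }
  ev_start <- c(ev_start, cur_s)
  ev_end <- c(ev_end, cur_e)
  data.frame(
    start = pmax(1L, ev_start - hold_n),
    end = pmin(n, ev_end + hold_n),
    onset = trace$time[ev_start]
  )
}

#' Extract per-event EOG features
#'
#' Runs polarity detection, wave segmentation and full-wave integration on
#' both channels for every event in the trace, and classifies the screen
#' quadrant from the polarity pair.
#'
#' @inheritParams detect_events
#' @return A data frame with one row per event: `onset`, `polarity_ch1`,
#'   `polarity_ch2`, `area` (1..4 or `NA`), `integral_ch1`, `integral_ch2`
#'   (microvolt-seconds).
#' @export
extract_features <- function(trace, thresholds, hold_ms = 50) {
  ev <- detect_events(trace, thresholds, hold_ms)
  out <- lapply(seq_len(nrow(ev)), function(i) {
    idx <- ev$start[i]:ev$end[i]
    feats <- lapply(list(trace$ch1[idx], trace$ch2[idx]), function(x) {
      seg <- segment_wave(x, thresholds, trace$sample_rate, hold_ms)
      list(polarity = seg$polarity,
           integral = integrate_wave(x, seg, trace$sample_rate))
    })
    data.frame(
      onset = ev$onset[i],
      polarity_ch1 = feats[[1L]]$polarity,
      polarity_ch2 = feats[[2L]]$polarity,
      area = classify_area(feats[[1L]]$polarity, feats[[2L]]$polarity),
      integral_ch1 = feats[[1L]]$integral,
      integral_ch2 = feats[[2L]]$integral
    )
  })
  if (length(out) == 0L) {
    return(data.frame(onset = numeric(), polarity_ch1 = character(),
                      polarity_ch2 = character(), area = integer(),
                      integral_ch1 = numeric(), integral_ch2 = numeric()))
  }
  do.call(rbind, out)
}
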