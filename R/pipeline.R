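polarity_direction <- function(channel, polarity) {
  if (polarity == "rest") return(NA_character_)
  if (channel == 1L) {
    if (polarity == "-") "up" else "down"
  } else {
    if (polarity == "-") "right" else "left"
  }
}

#' Track gaze events through the full pipeline
#'
#' Runs the complete analysis chain on a raw two-channel trace: low-pass
#' filtering, event detection, per-channel polarity / wave segmentation /
#' full-wave integration, quadrant classification from the polarity pair,
#' the linear integral-to-pixel model, the quadrant's affine correction,
#' pixel-to-cm conversion, the robot frame shift and inverse kinematics.
#'
#' Channels at rest contribute 0 px (the affine gain model is only applied
#' to detected waves). When one channel rests the quadrant cannot come from
#' the polarity pair and falls back to the sign-based rule
#' ([area_for_point()]), matching the layout's assignment of on-axis
#' targets. Unreachable or joint-limit targets are reported per event in
#' `status`; the run continues.
#'
#' @param trace A raw [eog_trace()].
#' @param cal A [calibrate_all()] result carrying gains and normalizers.
#' @param thresholds An [eog_thresholds()].
#' @param geometry A [display_geometry()].
#' @param robot A [robot_config()].
#' @param hold_ms Quiet hold time for segmentation, ms.
#' @param spec Low-pass [filter_spec()].
#' @return A data frame with one row per detected event: `onset`,
#'   `polarity_ch1`, `polarity_ch2`, `area`, `u`, `v` (actual pixels),
#'   `u_corr`, `v_corr` (calibrated pixels), `alpha`, `beta` (degrees, `NA`
#'   on failure) and `status` (`"ok"`, `"unreachable"`, `"joint_limit"`).
#' @export
track_trace <- function(trace, cal, thresholds, geometry = display_geometry(),
                        robot = robot_config(), hold_ms = 50,
                        spec = filter_spec()) {
  stopifnot(inherits(cal, "calibration_set"))
  if (is.null(cal$normalizers)) {
    stop_invalid_config("the calibration carries no integral normalizers")
  }
  filtered <- lowpass_filter(trace, spec)
  feats <- extract_features(filtered, thresholds, hold_ms)
  rows <- lapply(seq_len(nrow(feats)), function(i) {
    f <- feats[i, ]
    dir1 <- polarity_direction(1L, f$polarity_ch1)
    dir2 <- polarity_direction(2L, f$polarity_ch2)
    v <- if (is.na(dir1)) 0 else {
      nrm <- normalize_integral(f$integral_ch1, cal$normalizers$ch1[[dir1]])
      distance_from_eog(nrm, dir1, cal$gains)
    }
    u <- if (is.na(dir2)) 0 else {
      nrm <- normalize_integral(f$integral_ch2, cal$normalizers$ch2[[dir2]])
      distance_from_eog(nrm, dir2, cal$gains)
    }
    area_eff <- if (!is.na(f$area)) f$area else area_for_point(u, v)
    corr <- drop(correct_pixels(cal, c(u, v), areas = area_eff))
    ik <- tryCatch(
      c(inverse_kinematics(
        target_to_endeffector(pixels_to_cm(corr, geometry), robot), robot
      ), status = "ok"),
      eogaze_unreachable = function(e) list(alpha = NA_real_, beta = NA_real_,
                                            status = "unreachable"),
      eogaze_joint_limit = function(e) list(alpha = NA_real_, beta = NA_real_,
                                            status = "joint_limit")
    )
    data.frame(
      onset = f$onset, polarity_ch1 = f$polarity_ch1,
      polarity_ch2 = f$polarity_ch2, area = area_eff,
      u = u, v = v, u_corr = corr[1L], v_corr = corr[2L],
      alpha = ik$alpha, beta = ik$beta, status = ik$status
    )
  })
  if (length(rows) == 0L) {
    return(data.frame(
      onset = numeric(), polarity_ch1 = character(), polarity_ch2 = character(),
      area = integer(), u = numeric(), v = numeric(), u_corr = numeric(),
      v_corr = numeric(), alpha = numeric(), beta = numeric(), status = character()
    ))
  }
  do.call(rbind, rows)
}

#' Estimate actual gaze pixels for a calibration session trace
#'
#' Convenience wrapper used during calibration: extracts features from a
#' session trace and converts them to actual pixels with the gain table and
#' normalizers alone (no affine correction, which is what the session is
#' about to fit).
#'
#' @param trace A raw [eog_trace()].
#' @param thresholds An [eog_thresholds()].
#' @param gains A [gain_table()].
#' @param normalizers Integral normalizers ([default_normalizers()] shape).
#' @param hold_ms Hold time, ms.
#' @param spec Low-pass [filter_spec()].
#' @return A data frame per event: `onset`, `area`, `actual_u`, `actual_v`.
#' @export
estimate_actual_pixels <- function(trace, thresholds, gains = gain_table(),
                                   normalizers = default_normalizers(),
                                   hold_ms = 50, spec = filter_spec()) {
  filtered <- lowpass_filter(trace, spec)
  feats <- extract_features(filtered, thresholds, hold_ms)
  rows <- lapply(seq_len(nrow(feats)), function(i) {
    f <- feats[i, ]
    dir1 <- polarity_direction(1L, f$polarity_ch1)
    dir2 <- polarity_direction(2L, f$polarity_ch2)
    v <- if (is.na(dir1)) 0 else
      distance_from_eog(normalize_integral(f$integral_ch1, normalizers$ch1[[dir1]]),
                        dir1, gains)
    u <- if (is.na(dir2)) 0 else
      distance_from_eog(normalize_integral(f$integral_ch2, normalizers$ch2[[dir2]]),
                        dir2, gains)
    data.frame(onset = f$onset,
               area = if (!is.na(f$area)) f$area else area_for_point(u, v),
               actual_u = u, actual_v = v)
  })
  if (length(rows) == 0L) {
    return(data.frame(onset = numeric(), area = integer(),
                      actual_u = numeric(), actual_v = numeric()))
  }
  do.call(rbind, rows)
}
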