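#' Per-direction linear gain table
#'
#' Gaze distance in pixels is an affine function of the normalized full-wave
#' integral, `distance = A * norm_int + B`, with one `(A, B)` pair per basic
#' direction. The sign of `A` encodes the direction (up/right positive,
#' down/left negative on the screen axes). Defaults are the averages reported
#' for three operators on a 1020 x 720 px display; individual operators
#' should calibrate their own table.
#'
#' @param up,down,right,left Named numeric vectors `c(A = , B = )` in pixels.
#' @return An object of class `gain_table` (named list of `(A, B)` pairs).
#' @export
#' @examples
#' g <- gain_table()
#' distance_from_eog(1, "up", g)    # 600 px
#' distance_from_eog(0, "right", g) # -138 px (affine offset)
gain_table <- function(up = c(A = 900, B = -300),
                       down = c(A = -850, B = 200),
                       right = c(A = 1100, B = -138),
                       left = c(A = -1100, B = 130)) {
  tbl <- list(up = up, down = down, right = right, left = left)
  for (d in names(tbl)) {
    v <- tbl[[d]]
    if (!is.numeric(v) || length(v) != 2L || !all(c("A", "B") %in% names(v))) {
      stop_invalid_config(sprintf("gain for '%s' must be c(A = , B = )", d))
    }
    tbl[[d]] <- v[c("A", "B")]
  }
  if (tbl$up["A"] <= 0 || tbl$right["A"] <= 0 || tbl$down["A"] >= 0 || tbl$left["A"] >= 0) {
    stop_invalid_config("gain signs must be A_up > 0, A_down < 0, A_right > 0, A_left < 0")
  }
  structure(tbl, class = "gain_table")
}

#' Display geometry
#'
#' Monitor size in pixels and centimeters plus the fixed viewing distance;
#' anchors every pixel/cm/visual-angle conversion. Defaults describe the
#' 1020 x 720 px (34 x 27 cm) display viewed from 40 cm.
#'
#' @param width_px,height_px Screen size in pixels.
#' @param width_cm,height_cm Screen size in centimeters.
#' @param viewing_distance_cm Eye-to-screen distance in centimeters.
#' @return An object of class `display_geometry`.
#' @export
display_geometry <- function(width_px = 1020, height_px = 720,
                             width_cm = 34, height_cm = 27,
                             viewing_distance_cm = 40) {
  vals <- c(width_px = width_px, height_px = height_px, width_cm = width_cm,
            height_cm = height_cm, viewing_distance_cm = viewing_distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_invalid_config("all display geometry values must be positive and finite")
  }
  structure(as.list(vals), class = "display_geometry")
}

#' Pixel displacement from a normalized EOG integral
#'
#' Evaluates the per-direction linear model `A * norm_int + B`. Vertical
#' directions (`up`, `down`) yield the v (vertical) pixel coordinate,
#' horizontal directions the u coordinate. Note the model is affine: a zero
#' integral does not map to zero pixels; the tracking pipeline only applies
#' it to detected (non-rest) waves and reports 0 px for rest channels.
#'
#' @param norm_int Normalized integral in `[0, 1]` (vectorized).
#' @param direction One of `"up"`, `"down"`, `"right"`, `"left"`.
#' @param gains A [gain_table()].
#' @return Signed pixel displacement(s).
#' @export
distance_from_eog <- function(norm_int, direction, gains = gain_table()) {
  if (!inherits(gains, "gain_table")) stop_invalid_config("`gains` must be a gain_table()")
  if (length(direction) != 1L || !direction %in% names(gains)) {
    stop_invalid_input("`direction` must be one of 'up', 'down', 'right', 'left'")
  }
  if (any(norm_int < 0 | norm_int > 1)) {
    stop_invalid_input("`norm_int` must lie in [0, 1]")
  }
  g <- gains[[direction]]
  unname(g["A"] * norm_int + g["B"])
}

#' Convert between pixel and centimeter screen coordinates
#'
#' Pixel coordinates are signed displacements from the central reference
#' point of the screen, so `(u, v) -> (u * width_cm / width_px,
#' v * height_cm / height_px)` and back. The two functions are exact
#' inverses.
#'
#' @param p Pixel point: length-2 numeric `c(u, v)` or an n x 2 matrix.
#' @param xy Centimeter point, same shapes.
#' @param geometry A [display_geometry()].
#' @return The converted point(s), same shape as the input.
#' @export
#' @examples
#' pixels_to_cm(c(255, 180))   # 8.5, 6.75 cm
#' cm_to_pixels(c(34, 27))     # 1020, 720 px
pixels_to_cm <- function(p, geometry = display_geometry()) {
  m <- as_point_matrix(p)
  out <- cbind(m[, 1L] * geometry$width_cm / geometry$width_px,
               m[, 2L] * geometry$height_cm / geometry$height_px)
  restore_point_shape(out, p)
}

#' @rdname pixels_to_cm
#' @export
cm_to_pixels <- function(xy, geometry = display_geometry()) {
  m <- as_point_matrix(xy)
  out <- cbind(m[, 1L] * geometry$width_px / geometry$width_cm,
               m[, 2L] * geometry$height_px / geometry$height_cm)
  restore_point_shape(out, xy)
}

#' Visual angle subtended by a pixel extent
#'
#' Converts a signed on-screen pixel extent (measured from the screen
#' center) to the visual angle at the eye, `atan(extent_cm /
#' viewing_distance_cm)`, per axis on a flat screen. The function is odd and
#' strictly increasing in the pixel extent.
#'
#' @param pixels Signed pixel extent(s).
#' @param axis `"horizontal"` or `"vertical"`.
#' @param geometry A [display_geometry()].
#' @return Visual angle(s) in degrees.
#' @export
#' @examples
#' pixels_to_visual_angle(255, "horizontal")  # ~12 degrees
pixels_to_visual_angle <- function(pixels, axis = c("horizontal", "vertical"),
                                   geometry = display_geometry()) {
  axis <- match.arg(axis)
  pitch <- if (axis == "horizontal") {
    geometry$width_cm / geometry$width_px
  } else {
    geometry$height_cm / geometry$height_px
  }
  rad2deg(atan(pixels * pitch / geometry$viewing_distance_cm))
}

#' Screen quadrant of a pixel point
#'
#' Sign-based quadrant rule consistent with the calibration grid's
#' assignment of on-axis targets: upper right (including the positive v and
#' positive u half-axes' conventions) is Area 1, lower right Area 2, lower
#' left Area 3, upper left Area 4. Targets on the vertical axis belong to
#' Areas 1/3, targets on the horizontal axis to Areas 2/4; the origin
#' defaults to Area 1.
#'
#' @param u,v Signed pixel coordinates (vectorized).
#' @return Integer area(s) 1..4.
#' @export
area_for_point <- function(u, v) {
  mapply(function(ui, vi) {
    if (vi > 0) {
      if (ui >= 0) 1L else 4L
    } else if (vi < 0) {
      if (ui <= 0) 3L else 2L
    } else {
      if (ui > 0) 2L else if (ui < 0) 4L else 1L
    }
  }, u, v, USE.NAMES = FALSE)
}
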