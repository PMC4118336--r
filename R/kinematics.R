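#' Two-link planar robot configuration
#'
#' Geometry and joint limits of the gaze-indicating manipulator: two links
#' of 30 cm, shoulder angle `alpha` restricted to `[0, 180]` degrees and
#' elbow angle `beta` to `[0, 140]` degrees, and the fixed offset between
#' the screen-centered target frame and the robot base frame, applied as
#' `(Px, Py) = (x - 23, y + 27)` cm.
#'
#' @param L1,L2 Link lengths in cm.
#' @param alpha_range,beta_range Joint limits in degrees, `c(min, max)`.
#' @param frame_offset Offset `c(dx, dy)` in cm added to target-frame
#'   coordinates to obtain end-effector coordinates.
#' @return An object of class `robot_config`.
#' @export
robot_config <- function(L1 = 30, L2 = 30,
                         alpha_range = c(0, 180), beta_range = c(0, 140),
                         frame_offset = c(-23, 27)) {
  if (L1 <= 0 || L2 <= 0) stop_invalid_config("link lengths must be positive")
  if (diff(alpha_range) <= 0 || diff(beta_range) <= 0) {
    stop_invalid_config("joint ranges must be non-empty")
  }
  if (beta_range[1L] < 0 || beta_range[2L] > 180) {
    stop_invalid_config("the elbow range must lie within [0, 180] degrees")
  }
  structure(
    list(L1 = L1, L2 = L2, alpha_range = alpha_range, beta_range = beta_range,
         frame_offset = frame_offset),
    class = "robot_config"
  )
}

#' Screen target (cm) to end-effector position
#'
#' Applies the fixed frame offset between the target plate and the robot
#' base: `(Px, Py) = (x + dx, y + dy)` with the default offset
#' `(-23, +27)` cm.
#'
#' @param xy Target point in cm, `c(x, y)` or an n x 2 matrix.
#' @param robot A [robot_config()].
#' @return End-effector position(s) in cm, same shape as the input.
#' @export
#' @examples
#' target_to_endeffector(c(0, 0))  # (-23, 27)
target_to_endeffector <- function(xy, robot = robot_config()) {
  m <- as_point_matrix(xy)
  out <- cbind(m[, 1L] + robot$frame_offset[1L], m[, 2L] + robot$frame_offset[2L])
  restore_point_shape(out, xy)
}

#' Forward kinematics of the two-link planar arm
#'
#' `Px = L1 cos(alpha) + L2 cos(alpha + beta)`,
#' `Py = L1 sin(alpha) + L2 sin(alpha + beta)`; angles in degrees.
#'
#' @param alpha,beta Joint angles in degrees (vectorized).
#' @param robot A [robot_config()].
#' @return `c(Px, Py)` in cm, or an n x 2 matrix for vector input.
#' @export
#' @examples
#' forward_kinematics(0, 0)    # (60, 0)
#' forward_kinematics(90, 0)   # (0, 60)
forward_kinematics <- function(alpha, beta, robot = robot_config()) {
  a <- deg2rad(alpha)
  b <- deg2rad(beta)
  out <- cbind(robot$L1 * cos(a) + robot$L2 * cos(a + b),
               robot$L1 * sin(a) + robot$L2 * sin(a + b))
  if (length(alpha) == 1L) drop(out) else out
}

#' Inverse kinematics of the two-link planar arm
#'
#' Closed-form solution with the elbow on the principal (non-negative
#' arccosine) branch:
#' `beta = acos((Px^2 + Py^2 - L1^2 - L2^2) / (2 L1 L2))`,
#' `alpha = atan2(Py, Px) - atan2(L2 sin(beta), L1 + L2 cos(beta))`.
#' The mirrored elbow solution is rejected. Positions outside the annular
#' workspace raise an unreachable error; solutions outside the joint limits
#' raise a joint-limit error whose condition carries the unclamped angles
#' (fields `alpha`, `beta`).
#'
#' @param p End-effector position `c(Px, Py)` in cm.
#' @param robot A [robot_config()].
#' @return A list with `alpha` and `beta` in degrees, within the joint
#'   limits.
#' @export
#' @examples
#' inverse_kinematics(c(60, 0))             # alpha 0, beta 0
#' inverse_kinematics(c(0, 30 * sqrt(2)))   # alpha 45, beta 90
inverse_kinematics <- function(p, robot = robot_config()) {
  p <- drop(as_point_matrix(p, "p"))
  L1 <- robot$L1
  L2 <- robot$L2
  r2 <- sum(p^2)
  cb <- (r2 - L1^2 - L2^2) / (2 * L1 * L2)
  # Numerical guard at the workspace boundary only.
  if (cb > 1 && cb < 1 + 1e-12) cb <- 1
  # The annular workspace is bounded outside by the straight arm and inside
  # by the fully folded elbow at its configured limit.
  cb_min <- cos(deg2rad(robot$beta_range[2L]))
  if (cb > 1 || cb < cb_min - 1e-12) {
    stop_runtime(
      sprintf("position (%.2f, %.2f) is outside the arm's annular workspace", p[1L], p[2L]),
      "eogaze_unreachable", list(position = p)
    )
  }
  if (cb < cb_min) cb <- cb_min
  beta <- acos(cb)                # principal branch, in [0, pi)
  alpha <- atan2(p[2L], p[1L]) - atan2(L2 * sin(beta), L1 + L2 * cos(beta))
  alpha_deg <- rad2deg(alpha)
  beta_deg <- rad2deg(beta)
  # atan2 differences live on (-360, 360); pick the 360-degree branch that
  # can satisfy the shoulder limits before checking them.
  alpha_deg <- ((alpha_deg + 180) %% 360) - 180
  if (alpha_deg < robot$alpha_range[1L] && alpha_deg + 360 <= robot$alpha_range[2L] + 1e-9) {
    alpha_deg <- alpha_deg + 360
  }
  tol <- 1e-9
  if (alpha_deg < robot$alpha_range[1L] - tol || alpha_deg > robot$alpha_range[2L] + tol ||
      beta_deg < robot$beta_range[1L] - tol || beta_deg > robot$beta_range[2L] + tol) {
    stop_runtime(
      sprintf("solution (alpha=%.2f, beta=%.2f) violates the joint limits", alpha_deg, beta_deg),
      "eogaze_joint_limit", list(alpha = alpha_deg, beta = beta_deg, position = p)
    )
  }
  list(alpha = alpha_deg, beta = beta_deg)
}

#' Gaze pixel to robot joint angles
#'
#' The full output chain: correct the actual gaze pixel with the quadrant's
#' affine calibration, convert pixels to centimeters, shift into the robot
#' frame and solve the inverse kinematics. Unreachable or limit-violating
#' positions propagate their classed errors.
#'
#' @param p Actual gaze pixel `c(u, v)`.
#' @param cal A [calibrate_all()] result.
#' @param geometry A [display_geometry()].
#' @param robot A [robot_config()].
#' @param area Optional quadrant for the affine correction; defaults to the
#'   sign-based quadrant of `p`.
#' @return A list with `alpha` and `beta` in degrees.
#' @export
gaze_to_joint_angles <- function(p, cal, geometry = display_geometry(),
                                 robot = robot_config(), area = NULL) {
  corrected <- correct_pixels(cal, p, areas = area)
  inverse_kinematics(
    target_to_endeffector(pixels_to_cm(corrected, geometry), robot),
    robot
  )
}
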