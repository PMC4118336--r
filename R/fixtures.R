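#' Bundled per-operator reference-line coefficients
#'
#' Slope/intercept pairs of the four quadrant reference lines as estimated
#' for three human operators in the gaze-tracking study the shipped defaults
#' derive from. Useful as a realistic fixture: Areas 1 and 3 show positive
#' slopes, Areas 2 and 4 negative ones.
#'
#' @return A data frame with columns `area`, `operator`, `a` (slope,
#'   dimensionless) and `b` (intercept, pixels).
#' @export
#' @examples
#' lines <- operator_reference_lines()
#' max(lines$a)  # 2.44
operator_reference_lines <- function() {
  utils::read.csv(system.file("extdata", "operator-reference-lines.csv",
                              package = "eogaze"))
}

#' Bundled per-operator robot joint angles
#'
#' Shoulder/elbow angle pairs recorded while three operators steered the
#' two-link manipulator to six screen targets by gaze. The angles embed each
#' operator's residual gaze error, so they bracket (rather than equal) the
#' ideal-pipeline angles for the same targets.
#'
#' @return A data frame with columns `u`, `v` (target pixels), `operator`,
#'   `alpha` and `beta` (degrees).
#' @export
operator_joint_angles <- function() {
  utils::read.csv(system.file("extdata", "operator-joint-angles.csv",
                              package = "eogaze"))
}
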