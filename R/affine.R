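#' Elementary homogeneous transform matrices
#'
#' 3 x 3 homogeneous-coordinate building blocks of the quadrant calibration
#' transform: translation, rotation about the origin, shear and dilatation
#' (anisotropic axis-aligned scaling). All have bottom row `(0, 0, 1)`.
#'
#' @param tx,ty Translation in pixels.
#' @param theta Rotation angle in radians (counter-clockwise).
#' @param m1,m2 Dimensionless shear factors (row-1 and row-2 off-diagonals).
#' @param s1,s2 Positive scale factors for the u and v axes.
#' @return A 3 x 3 numeric matrix.
#' @export
#' @examples
#' translation_matrix(3, -2) %*% c(1, 1, 1)  # (4, -1, 1)
#' rotation_matrix(pi / 2) %*% c(1, 0, 1)    # (0, 1, 1)
translation_matrix <- function(tx, ty) {
  matrix(c(1, 0, 0, 0, 1, 0, tx, ty, 1), 3L, 3L)
}

#' @rdname translation_matrix
#' @export
rotation_matrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1), 3L, 3L)
}

#' @rdname translation_matrix
#' @export
shear_matrix <- function(m1, m2) {
  matrix(c(1, m2, 0, m1, 1, 0, 0, 0, 1), 3L, 3L)
}

#' @rdname translation_matrix
#' @export
dilatation_matrix <- function(s1, s2) {
  if (s1 <= 0 || s2 <= 0) stop_invalid_config("dilatation factors must be positive")
  diag(c(s1, s2, 1))
}

#' Factored affine transform parameters
#'
#' The seven parameters of a per-quadrant calibration transform: a
#' translation `(Tx, Ty)` that moves the rotation pivot to the origin, a
#' rotation `theta`, the reverse translation, a shear `(m1, m2)` and a
#' dilatation `(s1, s2)`. The rotation pivot is `(-Tx, -Ty)`.
#'
#' @param tx,ty Translation in pixels.
#' @param theta Rotation in radians.
#' @param m1,m2 Shear factors.
#' @param s1,s2 Positive dilatation factors.
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(tx = 0, ty = 0, theta = 0, m1 = 0, m2 = 0,
                            s1 = 1, s2 = 1) {
  for (nm in c("tx", "ty", "theta", "m1", "m2", "s1", "s2")) {
    check_number(get(nm), nm)
  }
  if (s1 <= 0 || s2 <= 0) stop_invalid_config("dilatation factors must be positive")
  structure(
    list(tx = tx, ty = ty, theta = theta, m1 = m1, m2 = m2, s1 = s1, s2 = s2),
    class = "geometry_params"
  )
}

#' @export
print.geometry_params <- function(x, ...) {
  cat(sprintf(
    "<geometry_params> T=(%.3f, %.3f) px, theta=%.3f deg, m=(%.4f, %.4f), s=(%.4f, %.4f)\n",
    x$tx, x$ty, rad2deg(x$theta), x$m1, x$m2, x$s1, x$s2
  ))
  invisible(x)
}

#' Compose the factored affine transform
#'
#' `compose_homogeneous()` returns the explicit five-matrix product
#' `Dilatation %*% Shear %*% Translation(-Tx,-Ty) %*% Rotation %*%
#' Translation(Tx,Ty)`. `closed_form_homogeneous()` builds the same matrix
#' from its algebraic entries, e.g. entry (1,1) is
#' `s1 (cos theta + m1 sin theta)` and the translation entry a1 is
#' `s1 ((Tx cos theta - Ty sin theta - Tx) + m1 (Tx sin theta + Ty cos theta
#' - Ty))`; entry (2,2) is `s2 (cos theta - m2 sin theta)` and a2 is
#' `s2 ((Tx sin theta + Ty cos theta - Ty) + m2 (Tx cos theta - Ty sin theta
#' - Tx))`, as direct multiplication dictates. The two forms agree to
#' machine precision; the numeric product is the reference.
#'
#' @param params A [geometry_params()].
#' @return A 3 x 3 homogeneous matrix with bottom row `(0, 0, 1)` and
#'   determinant `s1 * s2 * (1 - m1 * m2)`.
#' @export
compose_homogeneous <- function(params) {
  stopifnot(inherits(params, "geometry_params"))
  with(params,
    dilatation_matrix(s1, s2) %*% shear_matrix(m1, m2) %*%
      translation_matrix(-tx, -ty) %*% rotation_matrix(theta) %*%
      translation_matrix(tx, ty)
  )
}

#' @rdname compose_homogeneous
#' @export
closed_form_homogeneous <- function(params) {
  stopifnot(inherits(params, "geometry_params"))
  with(params, {
    ct <- cos(theta)
    st <- sin(theta)
    a1 <- s1 * ((tx * ct - ty * st - tx) + m1 * (tx * st + ty * ct - ty))
    a2 <- s2 * ((tx * st + ty * ct - ty) + m2 * (tx * ct - ty * st - tx))
    matrix(c(
      s1 * (ct + m1 * st), s1 * (-st + m1 * ct), a1,
      s2 * (st + m2 * ct), s2 * (ct - m2 * st), a2,
      0, 0, 1
    ), 3L, 3L, byrow = TRUE)
  })
}

check_affine_matrix <- function(M) {
  if (!is.matrix(M) || !all(dim(M) == c(3L, 3L)) ||
      !isTRUE(all.equal(M[3L, ], c(0, 0, 1)))) {
    stop_invalid_input("`M` must be a 3 x 3 homogeneous matrix with bottom row (0, 0, 1)")
  }
  M
}

#' Apply a homogeneous transform to pixel points
#'
#' @param M A 3 x 3 homogeneous matrix.
#' @param p A length-2 numeric `c(u, v)` or an n x 2 matrix of points.
#' @return Transformed point(s), same shape as the input.
#' @export
apply_transform <- function(M, p) {
  check_affine_matrix(M)
  m <- as_point_matrix(p)
  h <- cbind(m, 1) %*% t(M)
  restore_point_shape(h[, 1:2, drop = FALSE], p)
}
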