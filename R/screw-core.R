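# Screw-theory primitives: twists, wrenches, exponential maps on SE(3).
#
# Conventions: angles are radians everywhere inside this file; user-facing
# functions elsewhere in the package convert from degrees at the boundary.
# Lengths are mm, forces N, torques N.mm.

# tolerance for rotation-matrix validity checks (double-precision closed forms)
.ROT_TOL <- 1e-10

skew3 <- function(w) {
  matrix(c(0, w[3], -w[2],
           -w[3], 0, w[1],
           w[2], -w[1], 0), 3, 3)
}

#' Construct a twist (screw coordinates of a joint axis)
#'
#' A twist is the 6-vector \eqn{\xi = (\omega; v)} of instantaneous rigid
#' motion: `omega` is the (unit) rotation axis and `v` the linear part. For a
#' pure translation `omega` is the zero vector and `v` the translation
#' direction; for a revolute joint through a point `r`, `v = r x omega`.
#'
#' @param omega numeric length-3 angular part (dimensionless axis).
#' @param v numeric length-3 linear part (mm-scaled direction).
#' @return An object of class `"twist"` with fields `omega` and `v`.
#' @examples
#' twist(c(0, 0, 0), c(0, 0, 1))   # prismatic, along z
#' revolute_twist(c(1, 0, 0), c(0, 0, 150))
#' @export
twist <- function(omega, v) {
  omega <- as.numeric(omega); v <- as.numeric(v)
  stopifnot(length(omega) == 3, length(v) == 3)
  if (!all(is.finite(omega)) || !all(is.finite(v)))
    stop("twist components must be finite")
  structure(list(omega = omega, v = v), class = "twist")
}

#' @describeIn twist Revolute twist about unit axis `omega` through point `r`
#'   (mm): `v = r x omega`. `omega` must have unit norm; the rotation magnitude
#'   lives entirely in the angle passed to [exp_twist()].
#' @param r numeric length-3 point on the axis, mm.
#' @export
revolute_twist <- function(omega, r) {
  omega <- as.numeric(omega); r <- as.numeric(r)
  if (abs(sqrt(sum(omega^2)) - 1) > 1e-8)
    stop("revolute twists require a unit 'omega'; put the magnitude in theta")
  twist(omega, cross3(r, omega))
}

#' @describeIn twist Prismatic twist along unit direction `v` (zero angular
#'   part).
#' @export
prismatic_twist <- function(v) twist(c(0, 0, 0), v)

# 3-vector cross product
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.twist <- function(x, ...) {
  cat("<twist>  omega =", format(x$omega, digits = 6),
      " v =", format(x$v, digits = 6), "\n")
  invisible(x)
}

#' Pitch of a twist
#'
#' The ratio of translation to rotation along the screw axis,
#' \eqn{h = (\omega \cdot v) / |\omega|^2}; `Inf` for a pure translation
#' (zero angular part).
#'
#' @param xi a [twist()].
#' @return scalar pitch (mm per radian), `Inf` for prismatic twists.
#' @export
twist_pitch <- function(xi) {
  stopifnot(inherits(xi, "twist"))
  n2 <- sum(xi$omega^2)
  if (n2 == 0) return(Inf)
  sum(xi$omega * xi$v) / n2
}

#' Construct a wrench (generalized force)
#'
#' A wrench is the 6-vector \eqn{F = (f; \tau)} dual to a twist: `f` is the
#' pure-force component (N) and `tau` the pure-torque component (N.mm) acting
#' on a rigid body, expressed in a given frame.
#'
#' @param f numeric length-3 force, N.
#' @param tau numeric length-3 torque, N.mm.
#' @return An object of class `"wrench"`.
#' @export
wrench <- function(f, tau = c(0, 0, 0)) {
  f <- as.numeric(f); tau <- as.numeric(tau)
  stopifnot(length(f) == 3, length(tau) == 3)
  if (!all(is.finite(f)) || !all(is.finite(tau)))
    stop("wrench components must be finite")
  structure(list(f = f, tau = tau), class = "wrench")
}

#' @export
print.wrench <- function(x, ...) {
  cat("<wrench>  f =", format(x$f, digits = 6), "N",
      " tau =", format(x$tau, digits = 6), "N.mm\n")
  invisible(x)
}

#' Construct a homogeneous rigid-body transform
#'
#' A pose on SE(3): rotation `R` (3x3, orthogonal, det +1) and translation `t`
#' (mm). The implicit last row is (0, 0, 0, 1). Orthogonality and determinant
#' are checked to 1e-10.
#'
#' @param R 3x3 rotation matrix.
#' @param t numeric length-3 translation, mm.
#' @return An object of class `"hom_transform"` with fields `R` and `t`.
#' @export
hom_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R); t <- as.numeric(t)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > .ROT_TOL)
    stop("R is not orthogonal to tolerance ", .ROT_TOL)
  if (abs(det(R) - 1) > .ROT_TOL)
    stop("det(R) != 1 to tolerance ", .ROT_TOL)
  structure(list(R = R, t = t), class = "hom_transform")
}

#' @export
print.hom_transform <- function(x, ...) {
  cat("<hom_transform>\n")
  print(round(as_matrix4(x), 10))
  invisible(x)
}

#' Convert a transform to / from its 4x4 matrix form
#'
#' @param g a [hom_transform()] (`as_matrix4`) or a 4x4 matrix
#'   (`hom_transform_from_matrix`).
#' @return a 4x4 matrix, or a `hom_transform`.
#' @export
as_matrix4 <- function(g) {
  stopifnot(inherits(g, "hom_transform"))
  rbind(cbind(g$R, g$t), c(0, 0, 0, 1))
}

#' @rdname as_matrix4
#' @export
hom_transform_from_matrix <- function(g) {
  g <- as.matrix(g)
  stopifnot(all(dim(g) == c(4, 4)))
  hom_transform(g[1:3, 1:3], g[1:3, 4])
}

#' Compose rigid transforms
#'
#' `g1 %g% g2` is the transform applying `g2` first, then `g1` (matrix
#' product convention).
#'
#' @param g1,g2 [hom_transform()] objects.
#' @return a `hom_transform`.
#' @export
`%g%` <- function(g1, g2) {
  stopifnot(inherits(g1, "hom_transform"), inherits(g2, "hom_transform"))
  hom_transform(g1$R %*% g2$R, as.numeric(g1$R %*% g2$t) + g1$t)
}

#' Matrix (hat) representation of a twist
#'
#' Maps the 6-vector twist to its 4x4 Lie-algebra matrix: the upper-left 3x3
#' block is the skew-symmetric matrix of `omega`, the upper-right column is
#' `v`, and the bottom row is zero.
#'
#' @param xi a [twist()].
#' @return a 4x4 matrix.
#' @seealso [vee_twist()] for the inverse.
#' @export
hat_twist <- function(xi) {
  stopifnot(inherits(xi, "twist"))
  rbind(cbind(skew3(xi$omega), xi$v), rep(0, 4))
}

#' @rdname hat_twist
#' @param m a 4x4 matrix in the image of `hat_twist`.
#' @export
vee_twist <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(4, 4)))
  twist(c(m[3, 2], m[1, 3], m[2, 1]), m[1:3, 4])
}

#' Exponential map of a twist: closed-form rigid motion along a screw
#'
#' Returns the pose reached by moving an angle/distance `theta` along the
#' screw `xi`. For a prismatic twist (`omega = 0`) the result is the pure
#' translation `theta * v`. For a unit revolute twist the rotation is the
#' Rodrigues form of `theta * omega` and the translation is
#' \eqn{(I - e^{\theta\hat\omega})(\omega \times v) +
#' \theta\,\omega\,\omega^T v}.
#'
#' @param xi a [twist()]; a nonzero `omega` must be unit-norm.
#' @param theta rotation angle in radians (revolute) or translation in mm
#'   (prismatic).
#' @return a [hom_transform()].
#' @examples
#' exp_twist(prismatic_twist(c(0, 0, 1)), 5)          # translate 5 mm along z
#' exp_twist(revolute_twist(c(1, 0, 0), c(0, 0, 150)), pi / 6)
#' @export
exp_twist <- function(xi, theta) {
  stopifnot(inherits(xi, "twist"), is.numeric(theta), length(theta) == 1)
  w <- xi$omega; v <- xi$v
  nw <- sqrt(sum(w^2))
  if (nw == 0)
    return(hom_transform(diag(3), theta * v))
  if (abs(nw - 1) > 1e-8)
    stop("invalid screw normalization: nonzero 'omega' must be unit-norm ",
         "(|omega| = ", format(nw), ")")
  R <- rodrigues(w, theta)
  t <- as.numeric((diag(3) - R) %*% cross3(w, v)) +
    theta * w * sum(w * v)
  hom_transform(R, t)
}

# Rodrigues rotation formula for unit axis w, angle theta (radians)
rodrigues <- function(w, theta) {
  K <- skew3(w)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Rotation about the x axis
#'
#' The wrench/pose rotation used to carry rod-frame loads into the bone-end
#' frame of a one-degree hinge fixator.
#'
#' @param theta angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rot_x <- function(theta) {
  matrix(c(1, 0, 0,
           0, cos(theta), sin(theta),
           0, -sin(theta), cos(theta)), 3, 3)
}

#' Product-of-exponentials posture of the fixator
#'
#' Composes the prismatic rod twist \eqn{\xi_1 = (0,0,0; 0,0,1)} at
#' `delta_l` with the revolute hinge twist \eqn{\xi_2} (unit axis x, through
#' the point `(0, 0, l)`) at `theta`, optionally followed by the initial
#' posture `p(0)` whose translation is `(0, l, 0)`.
#'
#' The raw two-exponential product (`include_p0 = FALSE`) has rotation
#' `rot_x(theta)` and translation `(0, l sin(theta), delta_l + l (1 -
#' cos(theta)))`; with `include_p0 = TRUE` the initial offset is carried
#' through the rotation. Both are exposed because downstream uses differ:
#' the raw product is the hinge attitude, the full product the bone-end pose.
#'
#' @param delta_l rod lengthening, mm.
#' @param theta hinge angle, radians.
#' @param l rod length, mm (> 0).
#' @param include_p0 multiply by the initial posture `p(0)`? Default `FALSE`
#'   (raw product).
#' @return a [hom_transform()].
#' @export
pose_poe <- function(delta_l, theta, l, include_p0 = FALSE) {
  stopifnot(is.numeric(l), length(l) == 1)
  if (l <= 0) stop("rod length 'l' must be > 0")
  xi1 <- prismatic_twist(c(0, 0, 1))
  xi2 <- revolute_twist(c(1, 0, 0), c(0, 0, l))
  g <- exp_twist(xi1, delta_l) %g% exp_twist(xi2, theta)
  if (include_p0) g <- g %g% hom_transform(diag(3), c(0, l, 0))
  g
}

#' Rotate a wrench from the rod frame into the bone-end frame
#'
#' Applies the hinge rotation `rot_x(theta)` to both the force and torque
#' parts of the wrench. Being a rotation, it preserves the force and torque
#' magnitudes.
#'
#' @param F a [wrench()].
#' @param theta hinge angle, radians.
#' @return a `wrench` expressed in the rotated frame.
#' @export
rotate_wrench <- function(F, theta) {
  stopifnot(inherits(F, "wrench"))
  R <- rot_x(theta)
  wrench(as.numeric(R %*% F$f), as.numeric(R %*% F$tau))
}

#' Degree/radian conversion helpers
#'
#' All user-facing interfaces take degrees (clinical convention: the varus
#' angle is stated in degrees); the screw-theory core works in radians.
#'
#' @param x angle(s).
#' @return converted angle(s).
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(x) x * 180 / pi
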