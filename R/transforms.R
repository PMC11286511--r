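#' Rigid-body transforms and screw (helical) decomposition
#'
#' A filament is generated by repeated application of a single rigid-body
#' transform to a subunit. Any proper rigid transform is equivalent to a screw
#' operation: a rotation by a *twist* angle about an axis combined with a
#' translation (the *rise*) along that same axis (Chasles' theorem). These
#' functions convert between the matrix form and the helical (rise/twist)
#' parameterization used throughout the package.
#'
#' Sign convention: the twist follows the right-hand rule about
#' `axis_direction`, and `axis_direction` is chosen so that the rise is
#' non-negative (both axis and twist are flipped together if needed). With the
#' filament axis along +z and a positive rise, a *negative* twist is a
#' left-handed per-step rotation.
#'
#' @param rotation 3x3 orthonormal rotation matrix (determinant +1).
#' @param translation numeric length-3 translation vector, in Angstrom.
#' @return `rigid_transform()` returns an object of class `"rigid_transform"`
#'   with elements `rotation` and `translation`.
#' @examples
#' t <- rigid_transform(rot_z(-148.9), c(0, 0, 8.4))
#' p <- screw_decompose(t)
#' p$rise   # 8.4
#' p$twist  # -148.9
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!identical(dim(rotation), c(3L, 3L)))
    stopf("rotation must be a 3x3 matrix")
  if (length(translation) != 3L || any(!is.finite(translation)))
    stopf("translation must be a finite length-3 vector")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stopf("rotation matrix is not orthonormal (R'R != I beyond 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stopf("rotation matrix must be proper (det = +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param deg rotation angle in degrees.
#' @export
rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), -sin(a), 0,
           sin(a),  cos(a), 0,
           0,       0,      1), 3, 3, byrow = TRUE)
}

#' @rdname rigid_transform
#' @param axis unit length-3 axis vector.
#' @export
rot_axis <- function(axis, deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- deg2rad(deg)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n")
  cat("  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", paste(round(x$translation, 4), collapse = " "), "\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param t a `rigid_transform`.
#' @param coords n x 3 coordinate matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(t, coords) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(t$rotation), 2, t$translation, "+")
}

#' @rdname apply_transform
#' @param t1,t2 transforms; the composition applies `t2` first, then `t1`.
#' @export
compose_transform <- function(t1, t2) {
  rigid_transform(t1$rotation %*% t2$rotation,
                  as.numeric(t1$rotation %*% t2$translation) + t1$translation)
}

#' @rdname apply_transform
#' @param k non-negative integer power.
#' @export
transform_power <- function(t, k) {
  out <- rigid_transform(diag(3), c(0, 0, 0))
  for (i in seq_len(k)) out <- compose_transform(t, out)
  out
}

#' Decompose a rigid transform into helical (screw) parameters
#'
#' Recovers the rise (axial translation per step, Angstrom), twist (rotation
#' per step, degrees in (-180, 180]), and the screw axis (point + unit
#' direction). `screw_compose()` is the exact inverse; round-tripping
#' reproduces the action of the input transform to better than 1e-6 Angstrom.
#'
#' A pure translation is returned as twist 0 with the axis along the
#' translation. The identity transform has no defined axis and raises an
#' error.
#'
#' @param t a `rigid_transform`.
#' @return object of class `"helical_params"`: list with `rise`, `twist`,
#'   `axis_point`, `axis_direction`, `handedness`.
#' @export
screw_decompose <- function(t) {
  R <- t$rotation; tr <- t$translation
  cos_th <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  theta <- acos(cos_th)

  if (theta < 1e-9) {                       # pure translation (or identity)
    len <- sqrt(sum(tr^2))
    if (len < 1e-12)
      stopf("identity transform with zero translation: screw axis undefined")
    a <- tr / len
    return(new_helical_params(rise = len, twist = 0, axis_point = c(0, 0, 0),
                              axis_direction = a))
  }

  if (abs(theta - pi) < 1e-6) {
    # axis from the symmetric part: a a' = (R + I)/2
    B <- (R + diag(3)) / 2
    k <- which.max(diag(B))
    a <- B[, k] / sqrt(B[k, k])
    theta_signed <- pi                       # sign degenerate at 180 deg
  } else {
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    a <- v / (2 * sin(theta))
    theta_signed <- theta                    # positive about a by construction
  }
  a <- a / sqrt(sum(a^2))

  rise <- sum(tr * a)
  # orient axis so rise >= 0; flipping the axis negates the signed angle
  if (rise < 0) {
    a <- -a; rise <- -rise; theta_signed <- -theta_signed
  } else if (abs(rise) < 1e-12 && theta_signed < 0) {
    a <- -a; theta_signed <- -theta_signed
  }

  # point on the axis: solve (I - R) p = t_perp in the plane orthogonal to a
  t_perp <- tr - rise * a
  basis <- orthobasis(a)
  M <- t(basis) %*% (diag(3) - R) %*% basis
  p2 <- solve(M, as.numeric(t(basis) %*% t_perp))
  axis_point <- as.numeric(basis %*% p2)

  new_helical_params(rise = rise, twist = wrap_angle(rad2deg(theta_signed)),
                     axis_point = axis_point, axis_direction = a)
}

# Orthonormal basis of the plane orthogonal to unit vector a (3 x 2).
orthobasis <- function(a) {
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * a) * a
  u <- u / sqrt(sum(u^2))
  v <- c(a[2] * u[3] - a[3] * u[2],
         a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  cbind(u, v)
}

new_helical_params <- function(rise, twist, axis_point, axis_direction) {
  structure(list(rise = rise, twist = twist, axis_point = axis_point,
                 axis_direction = axis_direction,
                 handedness = sign(twist)),
            class = "helical_params")
}

#' @rdname screw_decompose
#' @param p a `helical_params` object.
#' @export
screw_compose <- function(p) {
  R <- rot_axis(p$axis_direction, p$twist)
  trans <- p$axis_point - as.numeric(R %*% p$axis_point) +
    p$rise * p$axis_direction
  rigid_transform(R, trans)
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf("helical_params: rise %.4f A, twist %.4f deg (%s-handed)\n",
              x$rise, x$twist,
              if (x$twist >= 0) "right" else "left"))
  cat("  axis point:", paste(round(x$axis_point, 4), collapse = " "), "\n")
  cat("  axis direction:", paste(round(x$axis_direction, 6), collapse = " "), "\n")
  invisible(x)
}
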