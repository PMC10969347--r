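#' Rigid transforms
#'
#' A rotation (internally parameterized as an axis-angle 3-vector mapped
#' through the exponential map, so gradient descent needs no orthogonality
#' constraints) plus a translation in mm.  Points transform as `R v + T`.
#'
#' @param axis_angle Numeric 3-vector `w`; the rotation is by `|w|` radians
#'   about `w / |w|` (zero vector = identity).
#' @param translation Numeric 3-vector in mm.
#' @return An object of class `rigid_transform` with components `axis_angle`,
#'   `translation`, and the 3 x 3 `rotation` matrix.
#' @export
rigid_transform <- function(axis_angle = c(0, 0, 0), translation = c(0, 0, 0)) {
  axis_angle <- as.numeric(axis_angle)
  translation <- as.numeric(translation)
  if (length(axis_angle) != 3L || length(translation) != 3L)
    stopf("axis_angle and translation must be 3-vectors")
  structure(list(axis_angle = axis_angle, translation = translation,
                 rotation = rotation_from_axis_angle(axis_angle)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: %.3f deg about (%.3f, %.3f, %.3f), T = (%.2f, %.2f, %.2f) mm\n",
              sqrt(sum(x$axis_angle^2)) * 180 / pi,
              x$axis_angle[1], x$axis_angle[2], x$axis_angle[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

# Rodrigues' formula.
rotation_from_axis_angle <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  K <- hat3(w / th)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# d(R)/d(w_k) for k = 1..3 (Gallego & Yezzi closed form); list of 3 matrices.
rotation_jacobian <- function(w) {
  th2 <- sum(w^2)
  R <- rotation_from_axis_angle(w)
  if (th2 < 1e-16) {
    return(lapply(1:3, function(k) {
      e <- numeric(3); e[k] <- 1; hat3(e)
    }))
  }
  lapply(1:3, function(k) {
    e <- numeric(3); e[k] <- 1
    v <- cross3(w, as.numeric((diag(3) - R) %*% e))
    ((w[k] * hat3(w) + hat3(v)) / th2) %*% R
  })
}

#' Apply a rigid transform to points
#' @param points N x 3 matrix.
#' @param transform A [rigid_transform()].
#' @param inverse Apply the inverse transform instead.
#' @return Transformed N x 3 matrix.
#' @export
apply_rigid <- function(points, transform, inverse = FALSE) {
  R <- transform$rotation
  t <- transform$translation
  if (inverse) {
    sweep(points, 2, t) %*% R            # R^T (p - t), as rows: (p-t) R
  } else {
    points %*% t(R) + matrix(t, nrow(points), 3, byrow = TRUE)
  }
}

# Angular difference between two rotations, degrees.
rotation_angle_between <- function(R1, R2) {
  tr <- sum(diag(t(R1) %*% R2))
  acos(pmin(pmax((tr - 1) / 2, -1), 1)) * 180 / pi
}

# Axis-angle (rotation vector) of a rotation matrix; inverse of Rodrigues.
axis_angle_from_rotation <- function(R) {
  tr <- (sum(diag(R)) - 1) / 2
  th <- acos(pmin(pmax(tr, -1), 1))
  if (th < 1e-12) return(c(0, 0, 0))
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (th > pi - 1e-6) {
    # near 180 degrees: extract axis from R + I
    M <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(M), 0))
    k <- which.max(ax)
    ax <- M[, k] / ax[k]
    ax <- ax / sqrt(sum(ax^2))
    return(ax * th)
  }
  v / (2 * sin(th)) * th
}
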