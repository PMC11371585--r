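#' Rigid (6-DOF) world-coordinate transform
#'
#' A rigid transform maps points from a moving image's world space into a
#' fixed image's world space as `y = R (x - c) + c + t`, where `R` is the
#' rotation built from three Euler angles (applied as Rz Ry Rx, angles in
#' degrees), `t` the translation in mm and `c` the rotation centre in world
#' mm. This is the 6-degree-of-freedom model used for head-motion correction
#' and for ASL-to-T1w alignment.
#'
#' @param rotation numeric length 3, rotation angles about x, y, z in degrees.
#' @param translation numeric length 3, translation in mm.
#' @param center numeric length 3, rotation centre in world mm.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3, length(translation) == 3, length(center) == 3)
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: rot (deg) [%s]  trans (mm) [%s]\n",
              paste(signif(x$rotation, 4), collapse = ", "),
              paste(signif(x$translation, 4), collapse = ", ")))
  invisible(x)
}

rot_matrix_deg <- function(rotation) {
  a <- rotation * pi / 180
  ca <- cos(a); sa <- sin(a)
  rx <- matrix(c(1, 0, 0, 0, ca[1], sa[1], 0, -sa[1], ca[1]), 3, 3)
  ry <- matrix(c(ca[2], 0, -sa[2], 0, 1, 0, sa[2], 0, ca[2]), 3, 3)
  rz <- matrix(c(ca[3], sa[3], 0, -sa[3], ca[3], 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

# Euler angles (deg, Rz Ry Rx convention) from a rotation matrix.
angles_from_rot <- function(R) {
  beta <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(beta)) > 1e-10) {
    alpha <- atan2(R[3, 2], R[3, 3])
    gamma <- atan2(R[2, 1], R[1, 1])
  } else {
    # gimbal lock: fold everything into alpha
    alpha <- atan2(-R[2, 3], R[2, 2])
    gamma <- 0
  }
  c(alpha, beta, gamma) * 180 / pi
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @param tf a `rigid_transform`.
#' @return 4x4 numeric matrix acting on homogeneous world coordinates.
#' @export
rt_matrix <- function(tf) {
  R <- rot_matrix_deg(tf$rotation)
  b <- tf$center + tf$translation - R %*% tf$center
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- b
  m
}

#' Rigid transform from a 4x4 matrix
#'
#' Recovers the 6 parameters of a rigid transform (rotation must be proper
#' orthonormal) for a chosen rotation centre.
#' @param m 4x4 homogeneous matrix.
#' @param center rotation centre to parameterise about.
#' @return `rigid_transform`.
#' @export
rt_from_matrix <- function(m, center = c(0, 0, 0)) {
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("matrix is not a proper rigid transform")
  b <- m[1:3, 4]
  trans <- as.numeric(b - center + R %*% center)
  rigid_transform(angles_from_rot(R), trans, center)
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` returns the transform applying `b` first, then `a`
#' (matrix product `A B`).
#' @param a,b `rigid_transform` objects.
#' @export
rt_compose <- function(a, b) {
  rt_from_matrix(rt_matrix(a) %*% rt_matrix(b), center = a$center)
}

#' Invert a rigid transform
#' @param tf a `rigid_transform`.
#' @export
rt_invert <- function(tf) {
  rt_from_matrix(solve(rt_matrix(tf)), center = tf$center)
}

#' Apply a rigid transform to points
#' @param tf a `rigid_transform` (or 4x4 matrix).
#' @param pts N x 3 matrix of world points (a length-3 vector is accepted).
#' @return N x 3 matrix of mapped points.
#' @export
rt_apply <- function(tf, pts) {
  m <- if (is.matrix(tf) && all(dim(tf) == c(4, 4))) tf else rt_matrix(tf)
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  stopifnot(ncol(pts) == 3)
  out <- pts %*% t(m[1:3, 1:3])
  sweep(out, 2, m[1:3, 4], "+")
}

#' Residual error between two rigid transforms
#'
#' Summarises the discrepancy `a` vs `b` as the translation difference (mm,
#' Euclidean norm of the displacement of the rotation centre) and the total
#' rotation angle (degrees) of the relative rotation.
#' @param a,b `rigid_transform` objects.
#' @return named numeric: `trans_mm`, `rot_deg`.
#' @export
rt_error <- function(a, b) {
  d <- rt_matrix(a) %*% solve(rt_matrix(b))
  R <- d[1:3, 1:3]
  ctr <- a$center
  disp <- rt_apply(d, matrix(ctr, 1)) - matrix(ctr, 1)
  cosang <- (sum(diag(R)) - 1) / 2
  c(trans_mm = sqrt(sum(disp^2)),
    rot_deg = acos(max(-1, min(1, cosang))) * 180 / pi)
}

#' Perturb a rigid transform by given offsets
#' @param tf base transform.
#' @param d_rot,d_trans numeric length 3, degree / mm offsets added to the
#'   transform's parameters.
#' @export
rt_perturb <- function(tf, d_rot = c(0, 0, 0), d_trans = c(0, 0, 0)) {
  rigid_transform(tf$rotation + d_rot, tf$translation + d_trans, tf$center)
}

#' Write / read a transform as a plain-text 4x4 matrix
#'
#' Row-major whitespace-separated text, one row per line, as produced by most
#' registration tools.
#' @param tf `rigid_transform`.
#' @param path file path.
#' @export
rt_write <- function(tf, path) {
  m <- rt_matrix(tf)
  writeLines(apply(m, 1, function(r) paste(formatC(r, format = "g", digits = 17),
                                           collapse = " ")), path)
  invisible(path)
}

#' @rdname rt_write
#' @param center rotation centre for the recovered parameterisation.
#' @export
rt_read <- function(path, center = c(0, 0, 0)) {
  m <- as.matrix(read.table(path))
  dimnames(m) <- NULL
  rt_from_matrix(m, center = center)
}

#' Draw a random rigid transform
#'
#' Uniform draws within symmetric ranges, the default head-position range of
#' +/- 5 mm translation and +/- 5 degrees rotation per axis.
#' @param max_trans,max_rot half-widths of the uniform ranges (mm, degrees).
#' @param center rotation centre.
#' @return `rigid_transform`.
#' @export
rt_random <- function(max_trans = 5, max_rot = 5, center = c(0, 0, 0)) {
  rigid_transform(runif(3, -max_rot, max_rot),
                  runif(3, -max_trans, max_trans), center)
}
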