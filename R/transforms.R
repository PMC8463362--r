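#' Rigid 3-D transform
#'
#' A 6-degree-of-freedom proper rigid transform: rotation angles (degrees)
#' about the world x, y, z axes (applied as `Rz %*% Ry %*% Rx`) followed by a
#' translation in millimetres. An optional rotation centre is supported so
#' registrations can rotate about the volume centre; the canonical world-axis
#' form has `center_mm = c(0, 0, 0)`.
#'
#' @param rotation_deg numeric 3-vector, rotations about x, y, z in degrees.
#' @param translation_mm numeric 3-vector, translation in mm.
#' @param center_mm numeric 3-vector, rotation centre in world mm.
#' @return an object of class `rigid_transform`.
#' @examples
#' tf <- rigid_transform(c(0, 0, 90), c(1, 0, 0))
#' apply_transform(tf, c(1, 0, 0))  # ~ (1, 1, 0)
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  check_num(rotation_deg, "rotation_deg", 3L)
  check_num(translation_mm, "translation_mm", 3L)
  check_num(center_mm, "center_mm", 3L)
  structure(
    list(rotation_deg = as.numeric(rotation_deg),
         translation_mm = as.numeric(translation_mm),
         center_mm = as.numeric(center_mm)),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: rot (deg) [%s]  trans (mm) [%s]\n",
              paste(signif(x$rotation_deg, 5), collapse = ", "),
              paste(signif(x$translation_mm, 5), collapse = ", ")))
  invisible(x)
}

#' Rotation matrix from axis angles
#'
#' @param deg rotations about x, y, z in degrees; composed as Rz Ry Rx.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_matrix <- function(deg) {
  a <- deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @param tf a `rigid_transform`.
#' @return 4x4 matrix mapping homogeneous points.
#' @export
transform_matrix <- function(tf) {
  r <- rotation_matrix(tf$rotation_deg)
  t_eff <- tf$center_mm + tf$translation_mm - as.numeric(r %*% tf$center_mm)
  m <- diag(4)
  m[1:3, 1:3] <- r
  m[1:3, 4] <- t_eff
  m
}

# Euler zyx extraction; valid away from the beta = +/-90 deg gimbal.
angles_from_rotation <- function(r) {
  beta <- asin(max(-1, min(1, -r[3, 1])))
  alpha <- atan2(r[3, 2], r[3, 3])
  gamma <- atan2(r[2, 1], r[1, 1])
  c(alpha, beta, gamma) * 180 / pi
}

#' Build a rigid transform from a 4x4 homogeneous matrix
#' @param m 4x4 matrix with orthonormal rotation block.
#' @return a `rigid_transform` with centre at the origin.
#' @export
transform_from_matrix <- function(m) {
  r <- m[1:3, 1:3]
  if (max(abs(crossprod(r) - diag(3))) > 1e-6 || det(r) < 0) {
    perv_error("matrix rotation block is not a proper rotation",
               "perv_input_error")
  }
  rigid_transform(angles_from_rotation(r), m[1:3, 4])
}

#' Apply a rigid transform to points
#' @param tf a `rigid_transform`.
#' @param pts 3-vector or n x 3 matrix of world points (mm).
#' @return transformed points, same shape as the input.
#' @export
apply_transform <- function(tf, pts) {
  single <- is.null(dim(pts))
  p <- if (single) matrix(pts, 1, 3) else as.matrix(pts)
  m <- transform_matrix(tf)
  out <- p %*% t(m[1:3, 1:3]) + matrix(m[1:3, 4], nrow(p), 3, byrow = TRUE)
  if (single) as.numeric(out) else out
}

#' Compose two rigid transforms
#' @param a,b `rigid_transform`s; the result applies `b` first, then `a`.
#' @return a `rigid_transform` (canonical, centre at origin).
#' @export
compose_transforms <- function(a, b) {
  transform_from_matrix(transform_matrix(a) %*% transform_matrix(b))
}

#' Invert a rigid transform
#' @param tf a `rigid_transform`.
#' @return the inverse `rigid_transform` (canonical, centre at origin).
#' @export
invert_transform <- function(tf) {
  m <- transform_matrix(tf)
  r <- t(m[1:3, 1:3])
  inv <- diag(4)
  inv[1:3, 1:3] <- r
  inv[1:3, 4] <- -as.numeric(r %*% m[1:3, 4])
  transform_from_matrix(inv)
}

# magnitude of a transform relative to identity: max |angle| (deg) and
# |translation| (mm); used for convergence/recovery checks
transform_magnitude <- function(tf) {
  c(rot_deg = max(abs(tf$rotation_deg)),
    trans_mm = sqrt(sum(tf$translation_mm^2)))
}
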