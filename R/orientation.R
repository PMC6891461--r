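# Joint angles from relative segment orientations via Euler decomposition.
# Orientations are unit quaternions (scalar-first rows of an n-by-4 matrix)
# or lists of 3x3 rotation matrices.

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

.as_rotation_list <- function(o, what, tol = 1e-6) {
  if (is.list(o)) {
    lapply(seq_along(o), function(i) {
      R <- o[[i]]
      if (!is.matrix(R) || !all(dim(R) == c(3L, 3L))) {
        stop(sprintf("%s[[%d]] is not a 3x3 rotation matrix", what, i))
      }
      if (max(abs(t(R) %*% R - diag(3))) > tol) {
        stop(sprintf("%s[[%d]] is not orthonormal within tolerance", what, i))
      }
      R
    })
  } else {
    q <- as.matrix(o)
    if (ncol(q) != 4L) stop(sprintf("%s must be an n-by-4 quaternion matrix or a list of 3x3 matrices", what))
    nrm <- sqrt(rowSums(q^2))
    if (any(abs(nrm - 1) > tol)) {
      stop(sprintf("%s contains non-unit quaternions (max |norm-1| = %.2e)", what,
                   max(abs(nrm - 1))))
    }
    lapply(seq_len(nrow(q)), function(i) quat_to_matrix(q[i, ] / nrm[i]))
  }
}

# Intrinsic Z-X-Y decomposition: R = Rz(flexion) Rx(abduction) Ry(rotation).
.euler_zxy <- function(R) {
  b <- asin(max(-1, min(1, R[3, 2])))
  a <- atan2(-R[1, 2], R[2, 2])
  c <- atan2(-R[3, 1], R[3, 3])
  c(a, b, c)
}

# Intrinsic Z-Y-X: R = Rz(flexion) Ry(abduction) Rx(rotation).
.euler_zyx <- function(R) {
  b <- -asin(max(-1, min(1, R[3, 1])))
  a <- atan2(R[2, 1], R[1, 1])
  c <- atan2(R[3, 2], R[3, 3])
  c(a, b, c)
}

#' Joint angles from parent and child segment orientations
#'
#' Computes the relative rotation (parent inverse composed with child) at
#' every sample and decomposes it with an intrinsic Euler sequence into
#' flexion, abduction and internal rotation, in degrees. The default `"ZXY"`
#' sequence (flexion about Z, abduction about X, rotation about Y) follows
#' the common lower-limb convention. Samples whose middle angle comes within
#' 1 degree of +/-90 degrees are flagged as gimbal-proximal.
#'
#' @param parent,child Equal-length orientation series: n-by-4 scalar-first
#'   unit-quaternion matrices, or lists of 3x3 rotation matrices.
#' @param sequence `"ZXY"` (default) or `"ZYX"`.
#' @param tol Unit-norm / orthonormality tolerance beyond which input is
#'   rejected.
#'
#' @return A `data.frame` with columns `flexion`, `abduction`, `rotation`
#'   (degrees) and `gimbal` (logical flag), with the sequence stored in
#'   `attr(, "sequence")`.
#' @export
joint_angles_from_orientations <- function(parent, child, sequence = c("ZXY", "ZYX"),
                                           tol = 1e-6) {
  sequence <- match.arg(sequence)
  Rp <- .as_rotation_list(parent, "parent", tol)
  Rc <- .as_rotation_list(child, "child", tol)
  if (length(Rp) != length(Rc)) stop("parent and child series must have equal length")
  dec <- if (sequence == "ZXY") .euler_zxy else .euler_zyx
  ang <- t(vapply(seq_along(Rp), function(i) dec(t(Rp[[i]]) %*% Rc[[i]]), numeric(3)))
  deg <- ang * 180 / pi
  out <- data.frame(flexion = deg[, 1], abduction = deg[, 2], rotation = deg[, 3],
                    gimbal = abs(abs(deg[, 2]) - 90) < 1)
  attr(out, "sequence") <- sequence
  out
}
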