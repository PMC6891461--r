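# Sensor-side calibration: gyroscope bias as sample means, accelerometer
# bias as the centre of a least-squares sphere fitted to static samples.

#' Estimate the gyroscope bias from static samples
#'
#' The bias of a resting gyroscope is the componentwise arithmetic mean of
#' its samples.
#'
#' @param samples n-by-3 matrix of gyroscope readings (rad/s).
#' @return rad/s 3-vector.
#' @export
estimate_gyro_bias <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 1L || ncol(samples) != 3L) {
    stop("need at least one 3-axis gyroscope sample")
  }
  colMeans(samples)
}

#' Estimate the accelerometer bias by sphere fitting
#'
#' Static accelerometer samples taken in several orientations lie on a
#' sphere of radius g centred at the bias. The centre and radius are fitted
#' jointly by the algebraic (Kasa) linear least-squares method, followed by
#' one Gauss-Newton refinement step of the geometric distance; the gravity
#' argument is only used to report how far the fitted radius is from the
#' local gravity magnitude.
#'
#' @param samples n-by-3 matrix of accelerometer readings (m/s^2) spanning at
#'   least four non-coplanar orientations.
#' @param gravity Nominal gravity magnitude (m/s^2), for reporting.
#' @param refine Apply one Gauss-Newton step of the geometric fit (default
#'   `TRUE`).
#'
#' @return An object of class `bias_estimate`: list with `accel_bias`
#'   (fitted centre, m/s^2), `radius` (fitted, m/s^2), `radius_minus_gravity`
#'   and `fit_residual` (RMS distance of the samples from the fitted sphere).
#' @export
estimate_accel_bias <- function(samples, gravity = 9.81, refine = TRUE) {
  A <- as.matrix(samples)
  if (nrow(A) < 4L || ncol(A) != 3L) {
    stop("need at least four 3-axis accelerometer samples")
  }
  # Kasa fit: |x - c|^2 = r^2  <=>  2 x.c + (r^2 - |c|^2) = |x|^2
  X <- cbind(2 * A, 1)
  y <- rowSums(A^2)
  sv <- svd(X)
  if (sv$d[4L] < 1e-8 * sv$d[1L]) {
    stop("degenerate sample geometry (coplanar or collinear): sphere centre unidentifiable")
  }
  beta <- sv$v %*% ((t(sv$u) %*% y) / sv$d)
  centre <- as.numeric(beta[1:3])
  r2 <- beta[4L] + sum(centre^2)
  if (r2 <= 0) stop("sphere fit failed: non-positive squared radius")
  radius <- sqrt(r2)

  if (refine) {
    # One Gauss-Newton step on sum_i (|x_i - c| - r)^2.
    d <- sqrt(rowSums(sweep(A, 2, centre)^2))
    ok <- d > 1e-12
    U <- sweep(A[ok, , drop = FALSE], 2, centre) / d[ok]  # unit directions
    J <- cbind(-U, -1)
    res <- d[ok] - radius
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 4))
    centre <- centre + step[1:3]
    radius <- radius + step[4L]
  }

  d <- sqrt(rowSums(sweep(A, 2, centre)^2))
  structure(list(
    accel_bias = centre,
    radius = radius,
    radius_minus_gravity = radius - gravity,
    fit_residual = sqrt(mean((d - radius)^2))
  ), class = "bias_estimate")
}

#' @export
print.bias_estimate <- function(x, ...) {
  cat(sprintf(
    "<bias_estimate> accel bias (%.4f, %.4f, %.4f) m/s^2, radius %.4f (g%+.4f), RMS residual %.2e\n",
    x$accel_bias[1], x$accel_bias[2], x$accel_bias[3],
    x$radius, x$radius_minus_gravity, x$fit_residual))
  invisible(x)
}

#' Estimate both sensor biases from a static calibration record
#'
#' Convenience wrapper over [estimate_gyro_bias()] and
#' [estimate_accel_bias()] for records shaped like the output of
#' [simulate_static_imu()].
#'
#' @param record List with matrices `gyro` and `accel`.
#' @param gravity Passed to [estimate_accel_bias()].
#' @return A `bias_estimate` with an additional `gyro_bias` element.
#' @export
estimate_imu_bias <- function(record, gravity = 9.81) {
  est <- estimate_accel_bias(record$accel, gravity = gravity)
  est$gyro_bias <- estimate_gyro_bias(record$gyro)
  est
}
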