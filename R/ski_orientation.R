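# Gravity-based absolute ski attitude and the herringbone orientation
# estimate.  With no magnetometer, yaw is unobservable; roll and pitch follow
# from the low-frequency accelerometer components, and herringbone is
# signalled by the product of the inter-ski roll split and the summed pitch
# (positive only when the skis are edged apart on an uphill).

#' Specific force produced by gravity at a given roll and pitch
#'
#' Forward model of the accelerometer reading for a static sensor at roll
#' `phi` and pitch `theta` (radians) in the body frame:
#' `f = g * (sin(theta), -cos(theta) sin(phi), -cos(theta) cos(phi))`.
#' Used by the synthetic generator and as the inverse-check of
#' [roll_pitch_estimate()].
#'
#' @param phi roll (rad).
#' @param theta pitch (rad).
#' @param g gravity magnitude (m/s^2).
#' @return length-3 vector, or an n x 3 matrix for vector inputs.
#' @export
gravity_forward <- function(phi, theta, g = STANDARD_GRAVITY) {
  f <- cbind(sin(theta), -cos(theta) * sin(phi), -cos(theta) * cos(phi)) * g
  if (nrow(f) == 1L) as.numeric(f) else f
}

#' Absolute ski roll and pitch from accelerometer data
#'
#' A centered moving average of window `dt_skiOri` removes the high-frequency
#' motion components of the specific force; roll and pitch then follow from
#' the gravity direction:
#' `phi = atan2(-f_y, -f_z)`, `theta = atan2(f_x, sqrt(f_y^2 + f_z^2))`.
#' Pitch is confined to (-pi/2, pi/2) because the second atan2 argument is
#' non-negative.
#'
#' @param accel n x 3 specific-force matrix (m/s^2) in body axes.
#' @param dt_skiOri moving-average window (s).
#' @param fs sampling frequency (samples/s).
#' @param g gravity magnitude, for the low-gravity flag only.
#' @return data frame with columns `phi`, `theta` (rad) and `low_gravity`
#'   (`TRUE` where the averaged specific force is below `0.1 * g`, i.e. the
#'   segment is too dynamic for a trustworthy gravity inversion; values are
#'   still emitted).
#' @export
roll_pitch_estimate <- function(accel, dt_skiOri, fs, g = STANDARD_GRAVITY) {
  accel <- as.matrix(accel)
  if (ncol(accel) != 3L) stop("accel must have 3 columns")
  ff <- vapply(1:3, function(j) as.numeric(sliding_mean(accel[, j], dt_skiOri, fs)),
               numeric(nrow(accel)))
  mag <- sqrt(rowSums(ff^2))
  data.frame(phi = atan2(-ff[, 2], -ff[, 3]),
             theta = atan2(ff[, 1], sqrt(ff[, 2]^2 + ff[, 3]^2)),
             low_gravity = mag < 0.1 * g)
}

#' Herringbone ski-orientation estimate
#'
#' Pointwise product of the inter-ski roll difference and the summed ski
#' pitch, `(phi_L - phi_R) * (theta_L + theta_R)` (rad^2).  The estimate is
#' positive only when a roll split (skis edged apart) co-occurs with uphill
#' pitch; turning or skating downhill produces negative values, so a positive
#' tolerance restricts herringbone to uphill terrain.
#'
#' @param phi_L,phi_R,theta_L,theta_R time-aligned attitude series (rad).
#' @return signed series (rad^2).
#' @export
hrb_estimate <- function(phi_L, phi_R, theta_L, theta_R) {
  n <- length(phi_L)
  if (length(phi_R) != n || length(theta_L) != n || length(theta_R) != n)
    stop("attitude series must have equal length")
  (phi_L - phi_R) * (theta_L + theta_R)
}

#' Lateral distance between the legs implied by the ski roll split
#'
#' Under parallel skis, straight legs and small angles, the roll difference
#' maps to the distance between the skis:
#' `hipWidth + (phi_L - phi_R) * legHeight`.  Useful as a physical aid when
#' choosing the herringbone tolerance `tol_epsi`.
#'
#' @param hipWidth hip width (m).
#' @param phi_L,phi_R ski roll angles (rad).
#' @param legHeight leg length (m), > 0.
#' @return distance in metres.
#' @export
leg_lateral_distance <- function(hipWidth, phi_L, phi_R, legHeight) {
  if (any(legHeight <= 0)) stop("legHeight must be > 0")
  hipWidth + (phi_L - phi_R) * legHeight
}
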