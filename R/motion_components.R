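# Motion-component estimators.  Each classification sample carries the
# component vector (legMoS, legMoST, armMo, armCorr, kickRot, epsi): windowed
# statistics of the arm and ski angular rates plus the gravity-based
# herringbone ski-orientation estimate.

#' Windowed arm-synchronization correlation
#'
#' Pearson correlation of the left and right arm lateral-axis angular rates
#' over the centered analysis window, per time stamp.  Windows in which
#' either arm's variance is below `1e-12` return 0 (such samples can only be
#' classified through the arm-motion threshold anyway).
#'
#' @param Aleft,Aright lateral-axis gyro series (deg/s), equal length.
#' @param dt window length (s).
#' @param fs sampling frequency (samples/s).
#' @return series in \[-1, 1\] with attribute `edge`.
#' @export
arm_correlation <- function(Aleft, Aright, dt, fs) {
  sliding_correlation(Aleft, Aright, dt, fs)
}

#' Windowed arm motion energy
#'
#' Sum of the windowed variances of the two arms' lateral-axis angular rates,
#' in (deg/s)^2.
#'
#' @inheritParams arm_correlation
#' @return non-negative series with attribute `edge`.
#' @export
arm_motion <- function(Aleft, Aright, dt, fs) {
  if (length(Aleft) != length(Aright)) stop("series must have equal length")
  vl <- sliding_variance(Aleft, dt, fs)
  vr <- sliding_variance(Aright, dt, fs)
  structure(as.numeric(vl) + as.numeric(vr), edge = attr(vl, "edge"))
}

#' Independent leg angle differences
#'
#' For the lateral (theta, sagittal-plane) and vertical (psi,
#' transversal-plane) axes of the two ski/leg gyros: band-pass filter the
#' angular rate, integrate with bias removal, and subtract right from left.
#'
#' @param gyro_left,gyro_right n x 3 gyro matrices (deg/s) in body axes
#'   (columns vertical, lateral, longitudinal).
#' @param params a [ski_tolerances] supplying `lowB`, `highB`, `fs`.
#' @return list with `theta` and `psi` angle-difference series (deg).
#' @export
leg_angle_differences <- function(gyro_left, gyro_right, params) {
  if (nrow(gyro_left) != nrow(gyro_right)) stop("gyro streams differ in length")
  ang <- function(rate) {
    integrate_debias(bandpass(rate, params$lowB, params$highB, params$fs),
                     params$fs)
  }
  list(theta = ang(gyro_left[, 2]) - ang(gyro_right[, 2]),
       psi   = ang(gyro_left[, 1]) - ang(gyro_right[, 1]))
}

#' Windowed independent leg motion
#'
#' `legMoS` is the windowed variance of the sagittal (lateral-axis) leg-angle
#' difference; `legMoST` adds the variance of the transversal (vertical-axis)
#' difference, so `legMoST >= legMoS` pointwise.
#'
#' @param angDiff_theta,angDiff_psi angle-difference series (deg).
#' @param dt,fs window length (s) and sampling frequency (samples/s).
#' @return list with `legMoS`, `legMoST` (deg^2) and `edge`.
#' @export
leg_motion <- function(angDiff_theta, angDiff_psi, dt, fs) {
  vt <- sliding_variance(angDiff_theta, dt, fs)
  vp <- sliding_variance(angDiff_psi, dt, fs)
  list(legMoS = as.numeric(vt),
       legMoST = as.numeric(vt) + as.numeric(vp),
       edge = attr(vt, "edge"))
}

#' Windowed kick-rotation ratio
#'
#' Ratio of the windowed standard deviations of the vertical-axis and
#' lateral-axis leg-angle differences.  Comparing the two rotation strengths
#' makes the measure invariant to overall motion amplitude.  Where the
#' lateral-axis deviation vanishes the ratio is capped at `cap`; such samples
#' cannot be classified as rotational kicks anyway because the leg-motion
#' thresholds also fail.
#'
#' @inheritParams leg_motion
#' @param cap finite value substituted where the denominator is ~0.
#' @return non-negative series.
#' @export
kick_rotation <- function(angDiff_theta, angDiff_psi, dt, fs, cap = 1e3) {
  st <- sqrt(as.numeric(sliding_variance(angDiff_theta, dt, fs)))
  sp <- sqrt(as.numeric(sliding_variance(angDiff_psi, dt, fs)))
  r <- numeric(length(st))
  small <- st < 1e-9
  r[!small] <- sp[!small] / st[!small]
  r[small] <- ifelse(sp[small] < 1e-9, 0, cap)
  pmin(r, cap)
}

#' Assemble the motion-component series for a session
#'
#' Runs all estimators on a preprocessed session (common rate, aligned ski
#' sensors) and returns one row per sample of the common clock: `legMoS`,
#' `legMoST` (deg^2), `armMo` ((deg/s)^2), `armCorr`, `kickRot`, `epsi`
#' (rad^2, the herringbone ski-orientation estimate), and an `edge` flag for
#' samples whose analysis window was truncated.
#'
#' @param session a preprocessed [ski_session] containing `left_arm`,
#'   `right_arm`, `left_ski`, `right_ski`.
#' @param params a [ski_tolerances].
#' @return data frame of class `ski_components`.
#' @export
assemble_components <- function(session, params = ski_tolerances()) {
  stopifnot(inherits(session, "ski_session"))
  need <- PLACEMENTS[1:4]
  miss <- setdiff(need, names(session$recordings))
  if (length(miss))
    stop("missing sensor(s): ", paste(miss, collapse = ", "))
  la <- session$recordings$left_arm
  ra <- session$recordings$right_arm
  ls <- session$recordings$left_ski
  rs <- session$recordings$right_ski
  n <- length(la$t)
  if (length(ra$t) != n || length(ls$t) != n || length(rs$t) != n)
    stop("recordings differ in length; run preprocess_session() first")
  dt <- params$dt; fs <- params$fs

  armCorr <- arm_correlation(la$gyro[, 2], ra$gyro[, 2], dt, fs)
  armMo <- arm_motion(la$gyro[, 2], ra$gyro[, 2], dt, fs)
  ad <- leg_angle_differences(ls$gyro, rs$gyro, params)
  lm <- leg_motion(ad$theta, ad$psi, dt, fs)
  kickRot <- kick_rotation(ad$theta, ad$psi, dt, fs)

  att_l <- roll_pitch_estimate(ls$accel, params$dt_skiOri, fs)
  att_r <- roll_pitch_estimate(rs$accel, params$dt_skiOri, fs)
  epsi <- hrb_estimate(att_l$phi, att_r$phi, att_l$theta, att_r$theta)

  h_ori <- window_half(params$dt_skiOri, fs)
  i <- seq_len(n)
  edge <- attr(armCorr, "edge") | (i - h_ori < 1L) | (i + h_ori > n)

  structure(data.frame(t = la$t,
                       legMoS = lm$legMoS, legMoST = lm$legMoST,
                       armMo = as.numeric(armMo),
                       armCorr = as.numeric(armCorr),
                       kickRot = kickRot, epsi = epsi, edge = edge),
            class = c("ski_components", "data.frame"),
            params = params)
}

#' @export
summary.ski_components <- function(object, ...) {
  int <- object[!object$edge, c("legMoS", "legMoST", "armMo", "armCorr",
                                "kickRot", "epsi")]
  cat("<ski_components>", nrow(object), "samples (",
      sum(!object$edge), "interior )\n")
  print(apply(int, 2, stats::quantile, probs = c(0, .25, .5, .75, 1)))
  invisible(object)
}

#' Plot the motion-component series
#'
#' One panel per component with the corresponding decision tolerance drawn as
#' a horizontal line, mirroring the way the estimators are usually inspected
#' against their thresholds.
#'
#' @param x a `ski_components` data frame.
#' @param params tolerances to draw; defaults to the ones stored on `x`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ski_components <- function(x, params = attr(x, "params"), ...) {
  if (is.null(params)) params <- ski_tolerances()
  comps <- c("armCorr", "armMo", "legMoS", "legMoST", "kickRot", "epsi")
  tols <- list(armCorr = c(params$tol_armPole, params$tol_armDiagHrb,
                           params$tol_armDiagD),
               armMo = params$tol_armMo, legMoS = params$tol_legMoS,
               legMoST = params$tol_legMoST, kickRot = params$tol_kickRot,
               epsi = params$tol_epsi)
  op <- graphics::par(mfrow = c(length(comps), 1),
                      mar = c(2, 4, 0.5, 0.5))
  on.exit(graphics::par(op))
  for (cc in comps) {
    graphics::plot(x$t, x[[cc]], type = "l", xlab = "", ylab = cc, ...)
    graphics::abline(h = tols[[cc]], lty = 2)
  }
  invisible(x)
}
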