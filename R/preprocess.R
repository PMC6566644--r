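# Signal preprocessing: zero-phase Butterworth filtering, resampling,
# integration with bias removal, gravity alignment of ski sensors, stream
# synchronization, and the sliding-window statistics every estimator uses.
#
# No DSP package is available in the target environment, so the 2nd-order
# Butterworth biquad (bilinear transform) and forward-backward filtering are
# implemented here directly; both are standard textbook constructions.

# Biquad coefficients for a 2nd-order Butterworth low- or high-pass.
# Returns list(b, a) with a[1] == 1.
butter2 <- function(fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (fc <= 0 || fc >= fs / 2) stop("corner frequency must be in (0, fs/2)")
  K <- tan(pi * fc / fs)
  norm <- 1 / (1 + sqrt(2) * K + K^2)
  a <- c(1, 2 * (K^2 - 1) * norm, (1 - sqrt(2) * K + K^2) * norm)
  b <- if (type == "low") c(K^2, 2 * K^2, K^2) * norm
       else c(1, -2, 1) * norm
  list(b = b, a = a)
}

# Direct-form IIR filter with zero initial conditions (vectorized via
# stats::filter for the recursive part).
iir_filter <- function(b, a, x) {
  n <- length(x)
  if (!n) return(x)
  xp <- c(0, 0, x)
  fir <- b[1] * xp[3:(n + 2)] + b[2] * xp[2:(n + 1)] + b[3] * xp[1:n]
  as.numeric(stats::filter(fir, -a[2:3], method = "recursive"))
}

# Zero-phase filtering: odd-reflection padding, filter forward and backward.
filtfilt2 <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (n < 4L) return(iir_filter(b, a, x))
  if (is.null(padlen)) padlen <- min(n - 1L, 3L * 10L)
  padlen <- min(padlen, n - 1L)
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  xe <- c(pre, x, post)
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Zero-phase band-pass filter
#'
#' Applies a 2nd-order Butterworth high-pass at `lowB` followed by a
#' 2nd-order Butterworth low-pass at `highB`, each forward and backward
#' (zero phase).  Passband gain is ~1; DC is rejected exactly.
#'
#' @param x numeric series.
#' @param lowB,highB band corners in /s, `0 < lowB < highB < fs/2`.
#' @param fs sampling frequency (samples/s).
#' @return filtered series, same length as `x`.
#' @export
bandpass <- function(x, lowB, highB, fs) {
  if (!(lowB > 0 && lowB < highB && highB < fs / 2))
    stop("band invalid: need 0 < lowB < highB < fs/2")
  if (!length(x)) return(numeric(0))
  padlen <- min(length(x) - 1L, ceiling(2 * fs / lowB))
  hp <- butter2(lowB, fs, "high")
  lp <- butter2(highB, fs, "low")
  y <- filtfilt2(hp$b, hp$a, x, padlen = padlen)
  filtfilt2(lp$b, lp$a, y, padlen = padlen)
}

# Zero-phase low-pass used as anti-alias filter (two cascaded biquads).
lowpass4 <- function(x, fc, fs) {
  lp <- butter2(fc, fs, "low")
  padlen <- min(length(x) - 1L, ceiling(4 * fs / fc))
  y <- filtfilt2(lp$b, lp$a, x, padlen = padlen)
  filtfilt2(lp$b, lp$a, y, padlen = padlen)
}

#' Resample a recording to a lower rate
#'
#' Anti-alias low-pass filtering (zero-phase 4th-order Butterworth at
#' 0.4 x target rate) followed by linear interpolation onto a uniform grid
#' at the target rate.  Upsampling is refused.
#'
#' @param rec a [ski_recording].
#' @param target_rate new sampling rate (samples/s), `<= rec$rate`.
#' @return a [ski_recording] at `target_rate`.
#' @export
resample <- function(rec, target_rate) {
  stopifnot(inherits(rec, "ski_recording"))
  if (target_rate > rec$rate + 1e-9)
    stop("upsampling refused: target_rate ", target_rate, " > rate ", rec$rate)
  if (abs(target_rate - rec$rate) < 1e-9) return(rec)
  t0 <- rec$t[1L]
  span <- rec$t[length(rec$t)] - t0
  tn <- t0 + seq(0, span, by = 1 / target_rate)
  fc <- 0.4 * target_rate
  chan <- function(x) {
    xf <- lowpass4(x, fc, rec$rate)
    stats::approx(rec$t, xf, xout = tn)$y
  }
  gyro <- vapply(1:3, function(j) chan(rec$gyro[, j]), numeric(length(tn)))
  accel <- vapply(1:3, function(j) chan(rec$accel[, j]), numeric(length(tn)))
  ski_recording(rec$placement, tn, gyro, accel, target_rate)
}

#' Integrate an angular rate with bias removal
#'
#' Cumulative trapezoidal integration of a rate signal, then subtraction of
#' the mean of the integrated angle over the whole segment, so the returned
#' angle series has zero mean.
#'
#' @param rate angular-rate series (deg/s) sampled at `fs`.
#' @param fs sampling frequency (samples/s).
#' @return angle series (deg), same length, zero mean.
#' @export
integrate_debias <- function(rate, fs) {
  n <- length(rate)
  if (!n) return(numeric(0))
  if (any(!is.finite(rate))) stop("non-finite values in rate series")
  theta <- c(0, cumsum((rate[-1L] + rate[-n]) / 2)) / fs
  theta - mean(theta)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Align a ski-mounted sensor using the session-mean specific force
#'
#' Assuming zero average horizontal acceleration over the activity, the mean
#' accelerometer vector must point along the negative vertical body axis
#' (gravity reaction).  The recording is rotated (gyro and accel by the same
#' minimal rotation) so that this holds; yaw about the vertical axis is
#' unobservable from gravity and left unchanged.
#'
#' @param rec a [ski_recording].
#' @param g gravity magnitude (m/s^2), used only for plausibility checks.
#' @return the rotated [ski_recording]; idempotent.
#' @export
align_ski_sensor <- function(rec, g = STANDARD_GRAVITY) {
  stopifnot(inherits(rec, "ski_recording"))
  m <- colMeans(rec$accel)
  nm <- sqrt(sum(m^2))
  if (nm < 1e-3)
    stop("alignment impossible: mean specific force is ~zero")
  if (abs(nm - g) / g > 0.2)
    warning(sprintf("mean specific force %.2f m/s^2 deviates >20%% from g", nm))
  u <- m / nm
  e <- c(0, 0, -1)
  ax <- cross3(u, e)
  s <- sqrt(sum(ax^2))
  co <- sum(u * e)
  if (s < 1e-12) {
    if (co > 0) return(rec)                      # already aligned
    R <- diag(c(-1, 1, -1))                      # pi about the lateral axis
  } else {
    k <- ax / s
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
                3L, 3L, byrow = TRUE)
    ang <- atan2(s, co)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  }
  ski_recording(rec$placement, rec$t,
                rec$gyro %*% t(R), rec$accel %*% t(R), rec$rate)
}

#' Time lag between two streams by high-pass cross-correlation
#'
#' High-pass filters both series (zero-phase 2nd-order Butterworth) and
#' returns the lag, in seconds, at which the cross-correlation peaks:
#' positive when `b` is delayed relative to `a`.  Resolution is one sample.
#'
#' @param a,b numeric series sampled at `fs`.
#' @param fs sampling frequency (samples/s).
#' @param highpass_cut high-pass corner (/s).
#' @return lag in seconds, with attributes `peak_correlation` (normalized
#'   peak) and `low_confidence` (`TRUE` when the peak is below 0.2).
#' @export
sync_lag <- function(a, b, fs, highpass_cut = 0.1) {
  n <- length(a)
  if (length(b) != n) stop("series must have equal length")
  hp <- butter2(highpass_cut, fs, "high")
  padlen <- min(n - 1L, ceiling(2 * fs / highpass_cut))
  af <- filtfilt2(hp$b, hp$a, a, padlen = padlen)
  bf <- filtfilt2(hp$b, hp$a, b, padlen = padlen)
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12 ||
      stats::sd(af) < 1e-6 * stats::sd(a) ||
      stats::sd(bf) < 1e-6 * stats::sd(b))
    stop("flat input: zero variance after high-pass filtering")
  z <- stats::convolve(rev(af), rev(bf), type = "open") # z[n+k] = sum af[i] bf[i+k]
  k <- which.max(z) - n
  peak <- max(z) / sqrt(sum(af^2) * sum(bf^2))
  structure(k / fs, peak_correlation = peak, low_confidence = peak < 0.2)
}

# --- sliding-window statistics -------------------------------------------
# Centered windows [t - dt/2, t + dt/2], truncated at the series boundaries;
# variances are divided by the sample count in the window (biased
# convention, matching the n = fr*dt normalization of the estimators).
# All are O(n) via cumulative sums; inputs are pre-centered for accuracy.

window_half <- function(dt, fs, min_n = 2L) {
  h <- floor(dt * fs / 2)
  if (2L * h + 1L < min_n) stop("window too short: need dt*fs >= 2 samples")
  h
}

window_bounds <- function(n, h) {
  i <- seq_len(n)
  i1 <- pmax(1L, i - h)
  i2 <- pmin(n, i + h)
  list(i1 = i1, i2 = i2, cnt = i2 - i1 + 1L, edge = (i - h < 1L) | (i + h > n))
}

window_sum <- function(x, i1, i2) {
  cs <- cumsum(x)
  cs[i2] - ifelse(i1 > 1L, cs[pmax(i1 - 1L, 1L)], 0)
}

#' Sliding-window variance
#'
#' Variance over the centered window `[t - dt/2, t + dt/2]`, truncated at the
#' boundaries, divided by the number of samples in the window.  The attribute
#' `edge` flags samples whose window was truncated.
#'
#' @param x numeric series.
#' @param dt window length (s).
#' @param fs sampling frequency (samples/s).
#' @return non-negative series of the same length, attribute `edge` logical.
#' @export
sliding_variance <- function(x, dt, fs) {
  n <- length(x)
  h <- window_half(dt, fs)
  if (2L * h + 1L > n) stop("window longer than series")
  w <- window_bounds(n, h)
  xc <- x - mean(x)
  S <- window_sum(xc, w$i1, w$i2)
  S2 <- window_sum(xc^2, w$i1, w$i2)
  v <- pmax(S2 / w$cnt - (S / w$cnt)^2, 0)
  structure(v, edge = w$edge)
}

# Sliding mean with the same centered/truncated window convention; a
# one-sample window is allowed and reduces to the identity.
sliding_mean <- function(x, dt, fs) {
  n <- length(x)
  h <- window_half(dt, fs, min_n = 1L)
  if (2L * h + 1L > n) stop("window longer than series")
  w <- window_bounds(n, h)
  structure(window_sum(x, w$i1, w$i2) / w$cnt, edge = w$edge)
}

# Sliding Pearson correlation; 0 where either windowed variance < eps.
sliding_correlation <- function(x, y, dt, fs, eps = 1e-12) {
  n <- length(x)
  if (length(y) != n) stop("series must have equal length")
  h <- window_half(dt, fs)
  if (2L * h + 1L > n) stop("window longer than series")
  w <- window_bounds(n, h)
  xc <- x - mean(x); yc <- y - mean(y)
  Sx <- window_sum(xc, w$i1, w$i2);  Sy <- window_sum(yc, w$i1, w$i2)
  Sxx <- window_sum(xc^2, w$i1, w$i2); Syy <- window_sum(yc^2, w$i1, w$i2)
  Sxy <- window_sum(xc * yc, w$i1, w$i2)
  ssxx <- Sxx - Sx^2 / w$cnt
  ssyy <- Syy - Sy^2 / w$cnt
  ssxy <- Sxy - Sx * Sy / w$cnt
  r <- numeric(n)
  ok <- (ssxx / w$cnt) >= eps & (ssyy / w$cnt) >= eps
  r[ok] <- ssxy[ok] / sqrt(ssxx[ok] * ssyy[ok])
  structure(pmin(1, pmax(-1, r)), edge = w$edge)
}

#' Preprocess a session for classification
#'
#' Resamples every recording to the working rate, gravity-aligns the
#' ski-mounted sensors, and trims all streams to the common time span so the
#' session satisfies the classification preconditions.
#'
#' @param session a [ski_session].
#' @param params a [ski_tolerances] (uses `fs`).
#' @param align_skis gravity-align ski sensors (default `TRUE`).
#' @return a preprocessed [ski_session].
#' @export
preprocess_session <- function(session, params = ski_tolerances(),
                               align_skis = TRUE) {
  stopifnot(inherits(session, "ski_session"))
  recs <- lapply(session$recordings, function(r) {
    r <- resample(r, min(params$fs, r$rate))
    if (align_skis && r$placement %in% c("left_ski", "right_ski"))
      r <- align_ski_sensor(r)
    r
  })
  t0 <- max(vapply(recs, function(r) r$t[1L], numeric(1L)))
  t1 <- min(vapply(recs, function(r) r$t[length(r$t)], numeric(1L)))
  if (t1 <= t0) stop("recordings do not overlap in time")
  recs <- lapply(recs, function(r) {
    keep <- r$t >= t0 - 1e-9 & r$t <= t1 + 1e-9
    ski_recording(r$placement, r$t[keep], r$gyro[keep, , drop = FALSE],
                  r$accel[keep, , drop = FALSE], r$rate)
  })
  ski_session(recs, meta = session$meta, require_all = FALSE)
}
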