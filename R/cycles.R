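# Cycle segmentation and aggregation.  A technique cycle starts and stops
# when the left arm reaches full backward extension; on the signal side this
# is realized as successive maxima of the band-passed, integrated left-arm
# lateral angle.

# Local maxima of x with minimum value and minimum spacing (in samples);
# when two peaks are closer than min_gap the higher one is kept.
find_peaks <- function(x, min_height = -Inf, min_gap = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (p in cand)
    if (!length(keep) || all(abs(keep - p) >= min_gap)) keep <- c(keep, p)
  sort(keep)
}

#' Segment technique cycles from the left-arm angular rate
#'
#' Band-passes and integrates (with bias removal) the left-arm lateral-axis
#' angular rate and places cycle boundaries at successive maxima of the
#' resulting angle -- the instants of maximal backward arm extension.  Peaks
#' must reach 20% of the local angle amplitude (sliding RMS envelope over
#' `env_window` seconds, so quiet and vigorous parts of a session are
#' segmented on their own scale) and be at least `min_period` apart (half of
#' the shortest plausible technique cycle).
#'
#' @param left_arm_lateral_gyro deg/s series.
#' @param fs sampling frequency (samples/s).
#' @param band band-pass corners `(lowB, highB)` in /s.
#' @param t optional timestamps; defaults to `(0:(n-1))/fs`.
#' @param min_period minimum landmark spacing in seconds (default 0.33).
#' @param env_window envelope window (s) for the local amplitude estimate.
#' @return data frame with columns `start`, `stop` (s) partitioning the span
#'   between the first and last landmark.  With no usable landmarks a single
#'   whole-series interval is returned with a warning.
#' @export
segment_cycles <- function(left_arm_lateral_gyro, fs, band = c(0.3, 3),
                           t = NULL, min_period = 0.33, env_window = 5) {
  x <- left_arm_lateral_gyro
  n <- length(x)
  if (is.null(t)) t <- (seq_len(n) - 1L) / fs
  theta <- integrate_debias(bandpass(x, band[1L], band[2L], fs), fs)
  amp <- max(abs(theta))
  pk <- if (amp > 0) {
    env <- sqrt(2 * as.numeric(sliding_variance(theta, min(env_window, n / fs), fs)))
    cand <- find_peaks(theta, min_gap = max(1L, round(min_period * fs)))
    cand[theta[cand] >= 0.2 * env[cand]]
  } else integer(0)
  if (length(pk) < 2L) {
    warning("no cycle landmarks found; returning the whole span as one interval")
    return(data.frame(start = t[1L], stop = t[n]))
  }
  data.frame(start = t[pk[-length(pk)]], stop = t[pk[-1L]])
}

#' Majority label per cycle
#'
#' Aggregates per-sample classification labels to one label per cycle
#' interval: the sub-technique with the highest sample count within the
#' cycle wins, which low-pass filters out isolated sample flips.  Ties are
#' broken deterministically in favour of the label that occurs earliest
#' within the cycle.
#'
#' @param labels a `ski_labels` data frame (`t`, `label`).
#' @param intervals data frame with `start`, `stop` (s).
#' @return data frame of class `ski_cycles` with columns `start`, `stop`,
#'   `label`, `duration` and `frequency` (= 1/duration, cycles/s; values
#'   outside (0.1, 3) are flagged in column `freq_ok`).
#' @export
cycle_majority_label <- function(labels, intervals) {
  stopifnot(all(c("t", "label") %in% names(labels)),
            all(c("start", "stop") %in% names(intervals)))
  lab <- vapply(seq_len(nrow(intervals)), function(i) {
    inb <- labels$t >= intervals$start[i] & labels$t < intervals$stop[i]
    if (!any(inb)) stop("empty cycle interval [", intervals$start[i], ", ",
                        intervals$stop[i], ")")
    l <- as.character(labels$label[inb])
    cnt <- table(l)
    top <- names(cnt)[cnt == max(cnt)]
    if (length(top) == 1L) top else l[l %in% top][1L]   # earliest-in-cycle tie-break
  }, character(1L))
  dur <- intervals$stop - intervals$start
  freq <- 1 / dur
  structure(data.frame(start = intervals$start, stop = intervals$stop,
                       label = factor(lab, levels = TECH_LEVELS),
                       duration = dur, frequency = freq,
                       freq_ok = freq > 0.1 & freq < 3),
            class = c("ski_cycles", "data.frame"))
}

# First autocorrelation peak of a centered series within a lag range;
# returns the period in seconds or NA when no peak reaches `min_corr`.
dominant_period <- function(x, fs, lag_range = c(0.33, 10), min_corr = 0.3) {
  n <- length(x)
  lmax <- min(n - 1L, ceiling(lag_range[2L] * fs))
  ac <- stats::acf(x, lag.max = lmax, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lo <- max(2L, floor(lag_range[1L] * fs))
  pk <- find_peaks(ac, min_height = min_corr)
  pk <- pk[pk >= lo + 1L]                    # acf index 1 is lag 0
  if (!length(pk)) return(NA_real_)
  (pk[1L] - 1L) / fs
}

#' Arm cycle frequency from autocorrelation
#'
#' Estimates the dominant cycle frequency of each arm's lateral-axis angular
#' rate as the inverse of the first significant autocorrelation peak (lag
#' range 0.33--10 s, peak height >= 0.3), and averages the two arms.
#' Signals with no significant periodicity give `NA`.
#'
#' @param Aleft,Aright deg/s series.
#' @param fs sampling frequency (samples/s).
#' @param lag_range period search range in seconds.
#' @param min_corr significance threshold on the autocorrelation peak.
#' @return frequency in cycles/s, or `NA` when neither arm shows a
#'   significant peak.
#' @export
arm_frequency <- function(Aleft, Aright, fs, lag_range = c(0.33, 10),
                          min_corr = 0.3) {
  p <- c(dominant_period(Aleft, fs, lag_range, min_corr),
         dominant_period(Aright, fs, lag_range, min_corr))
  f <- 1 / p
  if (all(is.na(f))) NA_real_ else mean(f, na.rm = TRUE)
}
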