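# Brute-force O(n*w) oracles for the windowed statistics, written as direct
# summations over the centered, boundary-truncated window; deliberately
# independent of the cumulative-sum implementation they check.

bf_window_bounds <- function(n, dt, fs) {
  h <- floor(dt * fs / 2)
  lapply(seq_len(n), function(i) seq(max(1L, i - h), min(n, i + h)))
}

bf_sliding_variance <- function(x, dt, fs) {
  idx <- bf_window_bounds(length(x), dt, fs)
  vapply(idx, function(j) {
    w <- x[j]
    sum((w - sum(w) / length(w))^2) / length(w)
  }, numeric(1L))
}

bf_sliding_correlation <- function(x, y, dt, fs, eps = 1e-12) {
  idx <- bf_window_bounds(length(x), dt, fs)
  vapply(idx, function(j) {
    xi <- x[j]; yi <- y[j]
    ssxx <- sum((xi - mean(xi))^2)
    ssyy <- sum((yi - mean(yi))^2)
    if (ssxx / length(j) < eps || ssyy / length(j) < eps) return(0)
    sum((xi - mean(xi)) * (yi - mean(yi))) / sqrt(ssxx * ssyy)
  }, numeric(1L))
}

# interior-sample mask for a window of dt at fs over n samples
interior <- function(n, dt, fs, extra = 0L) {
  h <- floor(dt * fs / 2) + extra
  i <- seq_len(n)
  i - h >= 1L & i + h <= n
}

# a component row that the decision layer sees; defaults are inert (noTech)
comp_row <- function(legMoS = 0, legMoST = legMoS, armMo = 0, armCorr = 0,
                     kickRot = 0, epsi = 0) {
  data.frame(legMoS = legMoS, legMoST = legMoST, armMo = armMo,
             armCorr = armCorr, kickRot = kickRot, epsi = epsi)
}

# write a minimal 4-sensor session to disk and return the manifest path
write_tiny_session <- function(dir, n = 50, rate = 20, drop = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t <- (seq_len(n) - 1L) / rate
  sensors <- list()
  for (pl in setdiff(c("left_arm", "right_arm", "left_ski", "right_ski"), drop)) {
    d <- data.frame(time = t, gx = sin(t), gy = cos(t), gz = 0,
                    ax = 0, ay = 0, az = -9.81)
    fn <- paste0(pl, ".csv")
    write.csv(d, file.path(dir, fn), row.names = FALSE, quote = FALSE)
    sensors[[length(sensors) + 1L]] <- list(placement = pl, file = fn)
  }
  man <- list(rate = rate, units = list(gyro = "deg/s", accel = "m/s^2"),
              sensors = sensors)
  path <- file.path(dir, "session.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  path
}
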