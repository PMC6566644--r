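#' Construct a single-sensor IMU recording
#'
#' A recording holds uniformly sampled tri-axial angular rate and specific
#' force from one sensor, expressed in the athlete body frame: x = vertical,
#' y = lateral, z = longitudinal.
#'
#' @param placement one of `"left_arm"`, `"right_arm"`, `"left_ski"`,
#'   `"right_ski"`, `"chest"`; unique within a session.
#' @param t numeric vector of timestamps in seconds, strictly increasing and
#'   uniform to within 1e-6 s of `1/rate`.
#' @param gyro n x 3 numeric matrix of angular rate (deg/s), columns
#'   `gx, gy, gz` (vertical, lateral, longitudinal axes).
#' @param accel n x 3 numeric matrix of specific force (m/s^2), same axes.
#' @param rate sampling rate in samples/s (> 0).
#' @return an object of class `ski_recording`.
#' @export
ski_recording <- function(placement, t, gyro, accel, rate) {
  placement <- match.arg(placement, PLACEMENTS)
  t <- as.numeric(t)
  gyro <- as.matrix(gyro)
  accel <- as.matrix(accel)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("'rate' must be a single positive number")
  n <- length(t)
  if (nrow(gyro) != n || nrow(accel) != n)
    stop("'t', 'gyro' and 'accel' must have the same number of samples")
  if (ncol(gyro) != 3L || ncol(accel) != 3L)
    stop("'gyro' and 'accel' must have 3 columns (x, y, z)")
  if (n > 1L) {
    d <- diff(t)
    bad <- which(d <= 0)
    if (length(bad))
      stop(sprintf("timestamps not strictly increasing at index %d (placement %s)",
                   bad[1L] + 1L, placement))
    off <- which(abs(d - 1 / rate) > 1e-6)
    if (length(off))
      stop(sprintf("timestamps not uniform at 1/rate: first offending index %d",
                   off[1L] + 1L))
  }
  colnames(gyro) <- c("gx", "gy", "gz")
  colnames(accel) <- c("ax", "ay", "az")
  structure(list(placement = placement, rate = rate, t = t,
                 gyro = gyro, accel = accel),
            class = "ski_recording")
}

#' Construct a multi-sensor session
#'
#' @param recordings list of [ski_recording] objects with distinct placements.
#' @param meta free-form named list (athlete id, lap markers, ...).
#' @param require_all if `TRUE` (default) the four extremity sensors
#'   (`left_arm`, `right_arm`, `left_ski`, `right_ski`) must all be present.
#' @return an object of class `ski_session`; recordings are named by placement.
#' @export
ski_session <- function(recordings, meta = list(), require_all = TRUE) {
  if (!length(recordings)) stop("empty session: no recordings supplied")
  ok <- vapply(recordings, inherits, logical(1L), what = "ski_recording")
  if (!all(ok)) stop("all elements of 'recordings' must be ski_recording objects")
  pl <- vapply(recordings, `[[`, character(1L), "placement")
  if (anyDuplicated(pl))
    stop("duplicate placement in session: ", pl[duplicated(pl)][1L])
  names(recordings) <- pl
  if (require_all) {
    need <- PLACEMENTS[1:4]
    miss <- setdiff(need, pl)
    if (length(miss))
      stop(sprintf("required placement %s absent", paste(miss, collapse = ", ")))
  }
  structure(list(recordings = recordings, meta = meta), class = "ski_session")
}

#' @export
print.ski_session <- function(x, ...) {
  cat("<ski_session> with", length(x$recordings), "recordings\n")
  for (r in x$recordings) {
    cat(sprintf("  %-10s rate %g /s, %d samples, %.1f s\n", r$placement,
                r$rate, length(r$t),
                if (length(r$t) > 1) diff(range(r$t)) else 0))
  }
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Decision tolerances and window/filter parameters
#'
#' Returns the tolerance set used by the decision functions together with the
#' windowing and band-pass parameters of the estimators.  Defaults are the
#' published values; any argument can be overridden.  Correlation tolerances
#' are dimensionless in \[-1, 1\]; `tol_legMoS`/`tol_legMoST` are variances of
#' leg-angle differences in deg^2; `tol_armMo` is a summed angular-rate
#' variance in (deg/s)^2; `tol_kickRot` a standard-deviation ratio; `tol_epsi`
#' is in rad^2 (ski roll/pitch are estimated in radians).
#'
#' @param tol_armDiagD arm-correlation upper bound for DIA (stricter than HRB).
#' @param tol_armDiag legacy diagonal arm-correlation bound (kept for
#'   reference; the decision layer uses `tol_armDiagHrb`).
#' @param tol_armPole arm-correlation lower bound for the poling super-class.
#' @param tol_legMoST threshold on sagittal+transversal leg motion (deg^2).
#' @param tol_legMoS threshold on sagittal leg motion (deg^2).
#' @param tol_armMo threshold on summed arm angular-rate variance ((deg/s)^2).
#' @param tol_kickRot threshold on the vertical/lateral rotation ratio.
#' @param tol_epsi threshold on the herringbone ski-orientation estimate (rad^2).
#' @param tol_armDiagHrb arm-correlation upper bound for the HRB/DIA super-class;
#'   must satisfy `tol_armDiagD < tol_armDiagHrb`.
#' @param dt analysis window length (s) for the sliding statistics.
#' @param dt_skiOri moving-average window (s) for the gravity-based ski attitude.
#' @param fs working sampling frequency (samples/s).
#' @param lowB,highB band-pass corner frequencies (/s), `0 < lowB < highB < fs/2`.
#' @return a classed list (`ski_tolerances`).
#' @export
ski_tolerances <- function(tol_armDiagD = -0.4, tol_armDiag = -0.3,
                           tol_armPole = 0.4, tol_legMoST = 81,
                           tol_legMoS = 2.25, tol_armMo = 1e4,
                           tol_kickRot = 2, tol_epsi = 0.06,
                           tol_armDiagHrb = -0.3,
                           dt = 1.3, dt_skiOri = 2.5, fs = 20,
                           lowB = 0.3, highB = 3) {
  tol <- list(tol_armDiagD = tol_armDiagD, tol_armDiag = tol_armDiag,
              tol_armPole = tol_armPole, tol_legMoST = tol_legMoST,
              tol_legMoS = tol_legMoS, tol_armMo = tol_armMo,
              tol_kickRot = tol_kickRot, tol_epsi = tol_epsi,
              tol_armDiagHrb = tol_armDiagHrb,
              dt = dt, dt_skiOri = dt_skiOri, fs = fs,
              lowB = lowB, highB = highB)
  validate_tolerances(tol)
  structure(tol, class = "ski_tolerances")
}

validate_tolerances <- function(tol) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(tol))
    if (!num1(tol[[nm]])) stop("tolerance '", nm, "' must be a finite number")
  if (tol$tol_armDiagD >= tol$tol_armDiagHrb)
    stop("configuration error: tol_armDiagD must be < tol_armDiagHrb (got ",
         tol$tol_armDiagD, " >= ", tol$tol_armDiagHrb, ")")
  for (nm in c("tol_armDiagD", "tol_armDiag", "tol_armPole", "tol_armDiagHrb"))
    if (abs(tol[[nm]]) > 1)
      stop("correlation tolerance '", nm, "' outside [-1, 1]")
  for (nm in c("tol_legMoST", "tol_legMoS", "tol_armMo", "tol_kickRot"))
    if (tol[[nm]] < 0) stop("tolerance '", nm, "' must be non-negative")
  if (tol$dt <= 0) stop("analysis window dt must be > 0")
  if (tol$dt_skiOri <= 0) stop("dt_skiOri must be > 0")
  if (tol$fs <= 0) stop("fs must be > 0")
  if (!(tol$lowB > 0 && tol$lowB < tol$highB && tol$highB < tol$fs / 2))
    stop("band invalid: need 0 < lowB < highB < fs/2")
  invisible(tol)
}

#' @export
print.ski_tolerances <- function(x, ...) {
  cat("<ski_tolerances>\n")
  cat(sprintf("  decision: armDiagD %g | armDiagHrb %g | armPole %g | legMoS %g | legMoST %g\n",
              x$tol_armDiagD, x$tol_armDiagHrb, x$tol_armPole,
              x$tol_legMoS, x$tol_legMoST))
  cat(sprintf("            armMo %g | kickRot %g | epsi %g\n",
              x$tol_armMo, x$tol_kickRot, x$tol_epsi))
  cat(sprintf("  sampling: fs %g /s | dt %g s | dt_skiOri %g s | band [%g, %g] /s\n",
              x$fs, x$dt, x$dt_skiOri, x$lowB, x$highB))
  invisible(x)
}

#' Load tolerances from a JSON configuration file
#'
#' Absent file (or `NULL`) returns the defaults of [ski_tolerances()].  Keys
#' present in the file override the defaults; unknown keys are an error.
#' Invariants (e.g. `tol_armDiagD < tol_armDiagHrb`) are enforced.
#'
#' @param config_path path to a flat JSON object of parameter overrides, or
#'   `NULL` for the defaults.
#' @return a `ski_tolerances` object.
#' @export
load_tolerances <- function(config_path = NULL) {
  if (is.null(config_path)) return(ski_tolerances())
  if (!file.exists(config_path)) stop("config file not found: ", config_path)
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  known <- names(formals(ski_tolerances))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown tolerance key(s): ", paste(bad, collapse = ", "))
  do.call(ski_tolerances, cfg)
}

read_sensor_csv <- function(path, placement, rate, axes = NULL) {
  if (!file.exists(path)) stop("sensor file not found: ", path)
  d <- utils::read.csv(path)
  need <- c("time", "gx", "gy", "gz", "ax", "ay", "az")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("sensor file ", basename(path), " missing column(s): ",
         paste(miss, collapse = ", "))
  gyro <- as.matrix(d[, c("gx", "gy", "gz")])
  accel <- as.matrix(d[, c("ax", "ay", "az")])
  if (!is.null(axes)) {
    R <- matrix(as.numeric(axes), 3L, 3L, byrow = TRUE)
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      stop("axes matrix for ", placement, " is not a rotation")
    gyro <- gyro %*% t(R)
    accel <- accel %*% t(R)
  }
  ski_recording(placement, d$time, gyro, accel, rate)
}

#' Read a multi-sensor session from a manifest
#'
#' The manifest is a JSON object with fields `rate` (samples/s), `units`
#' (must be `gyro: "deg/s"`, `accel: "m/s^2"`), and `sensors`, an array of
#' `{placement, file}` entries (paths relative to the manifest).  An optional
#' per-sensor `axes` entry (row-major 3x3 rotation) maps sensor-local axes to
#' the body frame.  Each sensor file is a headered CSV with columns
#' `time, gx, gy, gz, ax, ay, az`.
#'
#' @param manifest_path path to the session manifest.
#' @param require_all require the four extremity sensors (default `TRUE`).
#' @return a [ski_session] object.
#' @export
read_session <- function(manifest_path, require_all = TRUE) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  if (is.null(man$rate)) stop("manifest missing 'rate'")
  rate <- as.numeric(man$rate)
  if (!is.null(man$units)) {
    if (!is.null(man$units$gyro) && man$units$gyro != "deg/s")
      stop("unsupported gyro units: ", man$units$gyro, " (expected deg/s)")
    if (!is.null(man$units$accel) && !man$units$accel %in% c("m/s^2", "m/s2"))
      stop("unsupported accel units: ", man$units$accel, " (expected m/s^2)")
  }
  if (!length(man$sensors)) stop("manifest lists no sensors")
  base <- dirname(manifest_path)
  recs <- lapply(man$sensors, function(s) {
    if (is.null(s$placement) || is.null(s$file))
      stop("each sensor entry needs 'placement' and 'file'")
    read_sensor_csv(file.path(base, s$file), s$placement, rate,
                    axes = if (!is.null(s$axes)) unlist(s$axes))
  })
  meta <- if (!is.null(man$meta)) man$meta else list()
  ski_session(recs, meta = meta, require_all = require_all)
}

#' Write a session as manifest + per-sensor CSV files
#'
#' Inverse of [read_session()]: numeric content round-trips to better than
#' 1e-9 (values are written with 15 significant digits).
#'
#' @param session a [ski_session].
#' @param dir output directory (created if needed).
#' @param name stem for the manifest file name.
#' @return the manifest path, invisibly.
#' @export
write_session <- function(session, dir, name = "session") {
  stopifnot(inherits(session, "ski_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sensors <- lapply(session$recordings, function(r) {
    fn <- paste0(r$placement, ".csv")
    d <- data.frame(time = r$t, r$gyro, r$accel, check.names = FALSE)
    utils::write.table(format(d, digits = 15, scientific = FALSE, trim = TRUE),
                       file.path(dir, fn), sep = ",", row.names = FALSE,
                       quote = FALSE)
    list(placement = r$placement, file = fn)
  })
  rate <- session$recordings[[1L]]$rate
  man <- list(rate = rate,
              units = list(gyro = "deg/s", accel = "m/s^2"),
              sensors = unname(sensors),
              meta = session$meta)
  path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read expert reference cycle labels
#'
#' Reads a CSV with columns `start, stop, label` (seconds; label one of
#' DIA, DP, DK, HRB, TRN, TCK, tDIA, fDIA).  Intervals must be ordered and
#' non-overlapping; skating-style or other unknown labels are rejected.
#'
#' @param path CSV file path.
#' @return a data frame of class `ski_reference` with columns
#'   `start`, `stop`, `label` (factor over the reference levels).
#' @export
read_reference_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("start", "stop", "label"), names(d))
  if (length(miss)) stop("label file missing column(s): ", paste(miss, collapse = ", "))
  reference_cycles(d$start, d$stop, d$label)
}

#' Construct a validated reference cycle set
#'
#' @param start,stop interval bounds in seconds.
#' @param label character vector of reference labels.
#' @return data frame of class `ski_reference`.
#' @export
reference_cycles <- function(start, stop, label) {
  start <- as.numeric(start); stop <- as.numeric(stop)
  label <- as.character(label)
  if (length(start) != length(stop) || length(start) != length(label))
    stop("start, stop, label must have equal length")
  unknown <- setdiff(unique(label), REF_LEVELS)
  if (length(unknown))
    stop("unknown reference label(s): ", paste(unknown, collapse = ", "),
         " (valid: ", paste(REF_LEVELS, collapse = ", "), ")")
  o <- order(start)
  start <- start[o]; stop <- stop[o]; label <- label[o]
  if (any(stop <= start)) stop("reference intervals must have stop > start")
  if (length(start) > 1L && any(start[-1L] < stop[-length(stop)] - 1e-9))
    stop("reference intervals overlap")
  structure(data.frame(start = start, stop = stop,
                       label = factor(label, levels = REF_LEVELS)),
            class = c("ski_reference", "data.frame"))
}
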